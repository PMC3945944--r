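# End-to-end orchestration: simulate (or read) raw series, process each
# individual, pool, aggregate at every temporal scale, select/average
# models, cross-validate, and write per-stage artifacts.

#' Process one individual's raw series into a dive table
#'
#' Surface-offset correction, dive detection and segmentation, feature
#' extraction, prey-capture detection and per-dive counts.
#'
#' @param depth Tibble `time_s, depth_m` (1 Hz).
#' @param accel Tibble `time_s, ax, ...` (16 Hz), or `NULL` to skip event
#'   detection (counts set to `NA`).
#' @param individual_id Identifier.
#' @param config A [forage_config()].
#' @param sensor Sensor kind for [detect_pca()].
#' @return List: `dives` (metrics + features + `pca_count`), `events`,
#'   `surface_events`, `series` (corrected depth).
#' @export
process_individual <- function(depth, accel, individual_id = "ind01",
                               config = forage_config(),
                               sensor = "accelerometer") {
  series <- correct_surface_offset(depth, config$dive_threshold_m)
  dives <- dive_metrics(series, individual_id, config)
  dives <- dive_features(series, dives, config)
  if (!is.null(accel) && nrow(dives)) {
    pca <- detect_pca(accel, dives, config, sensor)
    dives <- dplyr::left_join(dives, pca$counts, by = "dive_id")
  } else {
    pca <- list(events = NULL, surface_events = numeric())
    dives$pca_count <- NA_integer_
  }
  list(dives = dives, events = pca$events,
       surface_events = pca$surface_events, series = series)
}

#' Build all scale tables from a pooled dive table
#'
#' @param all_dives Pooled per-dive tibble (all individuals, with bout and
#'   inclusion columns).
#' @param nights Night boundaries tibble (`individual_id`, `night_id`,
#'   `start_s`, `end_s`, `complete`).
#' @param config A [forage_config()].
#' @return Named list of `ScaleTable` tibbles for `config$scales`.
#' @export
build_scale_tables <- function(all_dives, nights, config = forage_config()) {
  dive_tab <- build_dive_table(all_dives, config)
  out <- list()
  for (sc in config$scales) {
    out[[sc]] <- switch(sc,
      dive = dive_tab,
      bout = build_bout_table(dive_tab, all_dives, config),
      win30 = build_window_table(dive_tab, all_dives, 1800, config),
      win60 = build_window_table(dive_tab, all_dives, 3600, config),
      win120 = build_window_table(dive_tab, all_dives, 7200, config),
      night = build_night_table(dive_tab, all_dives, nights, config),
      stopf("unknown scale '%s'", sc))
  }
  out
}

#' Run the full pipeline on a simulated dataset
#'
#' Simulates `sim$n_individuals` trips, processes each, fits the per-
#' individual bout-ending criterion, applies the inclusion rules, builds
#' the scale tables, runs all-subsets AICc selection and model averaging at
#' every scale (mixed models everywhere except the night scale, whose
#' sample size only supports a plain GLM), optionally cross-validates, and
#' writes every per-stage product plus a deterministic run manifest to
#' `out_dir`.
#'
#' The per-scale enumeration cap is the configured cap further limited by
#' the 10-rows-per-variable rule.
#'
#' @param sim An [sim_config()].
#' @param config A [forage_config()].
#' @param out_dir Output directory (created; pass `NULL` to skip writing).
#' @param evaluate Run leave-one-individual-out validation per scale.
#' @return Invisible list: `dives`, `tables`, `bec`, `averaged` (per
#'   scale), `rankings`, `cv` (per scale or `NULL`), `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), config = forage_config(),
                         out_dir = NULL, evaluate = TRUE) {
  trips <- simulate_dataset(sim)
  nights <- dplyr::bind_rows(lapply(trips, function(tr)
    dplyr::mutate(tr$truth$nights,
                  individual_id = tr$truth$individual_id)))

  processed <- lapply(names(trips), function(id)
    process_individual(trips[[id]]$depth, trips[[id]]$accel, id, config))
  names(processed) <- names(trips)

  # bout-ending criterion fitted per individual
  per_ind <- lapply(names(processed), function(id) {
    d <- processed[[id]]$dives
    b <- fit_bout_criterion(bec_intervals(d, config$bec_variable))
    list(dives = assign_bouts(d, b$bec_s),
         bec = list(individual_id = id, bec_s = b$bec_s, p = b$p,
                    mean_fast = b$mean_fast, mean_slow = b$mean_slow))
  })
  all_dives <- dplyr::bind_rows(lapply(per_ind, `[[`, "dives"))
  becs <- lapply(per_ind, `[[`, "bec")
  all_dives <- apply_inclusion_rules(all_dives)

  tables <- build_scale_tables(all_dives, nights, config)

  rankings <- list(); averaged <- list(); cv <- list()
  for (sc in config$scales) {
    tab <- tables[[sc]]
    cand <- intersect(scale_predictors(sc), names(tab))
    sds <- vapply(tab[cand], function(x) sd(x), numeric(1))
    cand <- cand[is.finite(sds) & sds > 0]
    cap <- min(config$max_vars[[sc]], length(cand), floor(nrow(tab) / 10))
    if (cap < 1 || nrow(tab) < 12) {
      message(sprintf("scale %s: too few rows (%d) to model; skipped",
                      sc, nrow(tab)))
      next
    }
    use_re <- sc != "night" && length(unique(tab$individual_id)) >= 2
    std <- standardize(tab, cols = cand)
    rk <- enumerate_and_rank(std, cand, cap, use_re, config$quadrature_nodes)
    rankings[[sc]] <- rk
    averaged[[sc]] <- model_average(rk, config$weight_threshold)
    if (evaluate && length(unique(tab$individual_id)) >= 3) {
      cv[[sc]] <- loocv(tab, cand, cap, use_re, config$weight_threshold,
                        config$quadrature_nodes)
    }
  }

  result <- list(dives = all_dives, tables = tables, bec = becs,
                 rankings = rankings, averaged = averaged, cv = cv)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    readr::write_csv(all_dives, file.path(out_dir, "dives.csv"))
    jsonlite::write_json(becs, file.path(out_dir, "bouts.json"),
                         auto_unbox = TRUE, digits = NA)
    for (sc in names(tables))
      readr::write_csv(tables[[sc]],
                       file.path(out_dir, sprintf("table_%s.csv", sc)))
    for (sc in names(rankings)) {
      m <- rankings[[sc]]$models
      m$terms <- vapply(m$terms, function(s)
        if (length(s)) paste(s, collapse = "+") else "(null)", "")
      readr::write_csv(m, file.path(out_dir, sprintf("ranking_%s.csv", sc)))
    }
    coefs <- dplyr::bind_rows(lapply(names(averaged), function(sc)
      dplyr::mutate(averaged[[sc]]$coefficients, scale = sc)))
    readr::write_csv(coefs, file.path(out_dir, "averaged_coefficients.csv"))
    if (length(cv)) {
      cvrep <- dplyr::bind_rows(lapply(names(cv), function(sc)
        dplyr::mutate(tidy(cv[[sc]]), scale = sc,
                      c_index_pooled = cv[[sc]]$c_index_pooled,
                      c_index_full = cv[[sc]]$c_index_full)))
      readr::write_csv(cvrep, file.path(out_dir, "cv_report.csv"))
      scatter <- dplyr::bind_rows(lapply(names(cv), function(sc)
        dplyr::mutate(cv[[sc]]$predictions, scale = sc)))
      readr::write_csv(scatter, file.path(out_dir, "cv_predictions.csv"))
    }
    files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("foragedive")),
      seed = sim$seed,
      n_individuals = sim$n_individuals,
      files = lapply(setNames(files, files), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}
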