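# Scale tables: one row per dive / bout / fixed window / night, response =
# prey-capture-attempt count, predictors = the eleven dive covariates
# (means at super-dive scales) plus n_dives and pct_time_deep above the
# dive scale.

#' Build the dive-scale table
#'
#' One row per modeled dive: deeper than the deep threshold, inside a bout
#' of at least 3 dives, not the terminal dive of its bout, and with valid
#' phase metrics.
#'
#' @param dives Dive tibble with metrics, features, `bout_id`, `included`,
#'   and `pca_count` columns.
#' @param config A [forage_config()].
#' @return A `ScaleTable` tibble (attribute `scale = "dive"`).
#' @export
build_dive_table <- function(dives, config = forage_config()) {
  filters <- c(
    "not deep enough" = sum(!dives$deep),
    "degenerate segmentation" = sum(dives$deep & dives$degenerate),
    "bout inclusion rules" = sum(dives$deep & !dives$degenerate & !dives$included)
  )
  keep <- dives$deep & !dives$degenerate & dives$included &
    is.finite(dives$post_dive_interval)
  if (!any(keep))
    stopf("dive table is empty after filtering (%s)",
          paste(sprintf("%s: %d", names(filters), filters), collapse = "; "))
  out <- dives[keep, ] |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      dive_id = .data$dive_id,
      bout_id = .data$bout_id,
      start_s = .data$start_s,
      dive_duration = .data$dive_duration,
      pca_count = as.integer(.data$pca_count),
      max_depth = .data$max_depth,
      surface_duration = .data$post_dive_interval,
      descent_rate = .data$descent_rate,
      ascent_rate = .data$ascent_rate,
      bottom_duration = .data$bottom_duration,
      depth_variation_bottom = .data$depth_variation_bottom,
      steps_descent = as.numeric(.data$steps_descent),
      steps_ascent = as.numeric(.data$steps_ascent),
      steps_descending_bottom = as.numeric(.data$steps_descending_bottom),
      steps_ascending_bottom = as.numeric(.data$steps_ascending_bottom),
      wiggles = as.numeric(.data$wiggles))
  structure(out, scale = "dive")
}

# Deep-dive cycle coverage of a [lo, hi) span: summed intersection of each
# deep dive's cycle (dive + following surface interval) with the span,
# divided by the span length. `all_dives` must carry start_s, dive_duration,
# post_dive_interval, deep.
span_coverage <- function(all_dives, lo, hi) {
  cyc_start <- all_dives$start_s
  cyc_end <- all_dives$start_s + all_dives$dive_duration +
    dplyr::coalesce(all_dives$post_dive_interval, 0)
  ok <- all_dives$deep
  inter <- pmax(0, pmin(cyc_end[ok], hi) - pmax(cyc_start[ok], lo))
  sum(inter) / (hi - lo)
}

aggregate_rows <- function(tab) {
  preds <- dive_predictors()
  out <- tab |>
    dplyr::summarise(
      pca_count = as.integer(sum(.data$pca_count)),
      dplyr::across(dplyr::all_of(preds), mean),
      n_dives = dplyr::n(),
      .groups = "drop")
  out
}

#' Build the bout-scale table
#'
#' One row per dive bout: summed attempt counts, mean dive predictors, the
#' number of dives, and the fraction of the bout span covered by deep-dive
#' cycles (`pct_time_deep`). Bouts whose coverage does not exceed
#' `config$coverage_min` are dropped, mirroring the fixed-window rule.
#'
#' @param dive_table Output of [build_dive_table()].
#' @param all_dives The unfiltered dive tibble (used for span coverage).
#' @param config A [forage_config()].
#' @return A `ScaleTable` tibble (attribute `scale = "bout"`).
#' @export
build_bout_table <- function(dive_table, all_dives, config = forage_config()) {
  spans <- all_dives |>
    dplyr::group_by(.data$individual_id, .data$bout_id) |>
    dplyr::summarise(
      lo = min(.data$start_s),
      hi = max(.data$start_s + .data$dive_duration +
                 dplyr::coalesce(.data$post_dive_interval, 0)),
      .groups = "drop")
  spans$pct_time_deep <- vapply(seq_len(nrow(spans)), function(i) {
    d <- all_dives[all_dives$individual_id == spans$individual_id[i] &
                     all_dives$bout_id == spans$bout_id[i], ]
    span_coverage(d, spans$lo[i], spans$hi[i])
  }, numeric(1))
  out <- dive_table |>
    dplyr::group_by(.data$individual_id, .data$bout_id) |>
    aggregate_rows() |>
    dplyr::inner_join(spans, by = c("individual_id", "bout_id")) |>
    dplyr::filter(.data$pct_time_deep > config$coverage_min) |>
    dplyr::select(-"lo", -"hi")
  structure(out, scale = "bout")
}

#' Build a fixed-window table
#'
#' Non-overlapping windows of `window_s` seconds are tiled from the start of
#' each bout; partial trailing windows are dropped. A window is kept when
#' the cumulated deep-dive cycle durations overlapping it exceed
#' `config$coverage_min` of the window; kept windows aggregate the dives
#' starting inside them like the bout table, plus `pct_time_deep`.
#'
#' @param dive_table Output of [build_dive_table()].
#' @param all_dives The unfiltered dive tibble.
#' @param window_s Window length: 1800, 3600 or 7200 s.
#' @param config A [forage_config()].
#' @return A `ScaleTable` tibble (attribute `scale = "win<minutes>"`).
#' @export
build_window_table <- function(dive_table, all_dives, window_s,
                               config = forage_config()) {
  scale <- paste0("win", window_s / 60)
  bouts <- all_dives |>
    dplyr::group_by(.data$individual_id, .data$bout_id) |>
    dplyr::summarise(
      lo = min(.data$start_s),
      hi = max(.data$start_s + .data$dive_duration +
                 dplyr::coalesce(.data$post_dive_interval, 0)),
      .groups = "drop")
  rows <- list()
  for (i in seq_len(nrow(bouts))) {
    n_win <- floor((bouts$hi[i] - bouts$lo[i]) / window_s)
    if (n_win < 1) next
    bd <- all_dives[all_dives$individual_id == bouts$individual_id[i] &
                      all_dives$bout_id == bouts$bout_id[i], ]
    for (k in seq_len(n_win)) {
      w0 <- bouts$lo[i] + (k - 1) * window_s
      w1 <- w0 + window_s
      cov <- span_coverage(bd, w0, w1)
      if (cov <= config$coverage_min) next
      sub <- dive_table[dive_table$individual_id == bouts$individual_id[i] &
                          dive_table$bout_id == bouts$bout_id[i] &
                          dive_table$start_s >= w0 & dive_table$start_s < w1, ]
      if (!nrow(sub)) next
      agg <- sub |>
        dplyr::group_by(.data$individual_id, .data$bout_id) |>
        aggregate_rows()
      agg$window_id <- paste0(bouts$individual_id[i], "_b", bouts$bout_id[i],
                              "_w", k)
      agg$pct_time_deep <- cov
      rows[[length(rows) + 1L]] <- agg
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(individual_id = character(), bout_id = integer(),
                   pca_count = integer(), n_dives = integer(),
                   window_id = character(), pct_time_deep = numeric())
  structure(out, scale = scale)
}

#' Build the night-scale table
#'
#' One row per complete night (nights with recording gaps are excluded):
#' summed attempt counts, mean dive predictors, number of dives, and the
#' deep-dive time coverage of the night window.
#'
#' @param dive_table Output of [build_dive_table()].
#' @param all_dives The unfiltered dive tibble.
#' @param nights Tibble `individual_id`, `night_id`, `start_s`, `end_s`,
#'   `complete`.
#' @param config A [forage_config()].
#' @return A `ScaleTable` tibble (attribute `scale = "night"`).
#' @export
build_night_table <- function(dive_table, all_dives, nights,
                              config = forage_config()) {
  nights <- nights[nights$complete, ]
  rows <- list()
  for (i in seq_len(nrow(nights))) {
    nd <- all_dives[all_dives$individual_id == nights$individual_id[i] &
                      all_dives$start_s >= nights$start_s[i] &
                      all_dives$start_s < nights$end_s[i], ]
    sub <- dive_table[dive_table$individual_id == nights$individual_id[i] &
                        dive_table$start_s >= nights$start_s[i] &
                        dive_table$start_s < nights$end_s[i], ]
    if (!nrow(sub)) next
    agg <- sub |>
      dplyr::group_by(.data$individual_id) |>
      aggregate_rows()
    agg$night_id <- nights$night_id[i]
    agg$pct_time_deep <- span_coverage(nd, nights$start_s[i], nights$end_s[i])
    rows[[length(rows) + 1L]] <- agg
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(individual_id = character(), pca_count = integer(),
                   n_dives = integer(), night_id = integer(),
                   pct_time_deep = numeric())
  structure(out, scale = "night")
}

#' Standardize predictor columns
#'
#' Centers and scales the predictors (response and identifiers untouched).
#' When `stats` is supplied (a tibble `column`, `mean`, `sd`, typically from
#' a training set), those statistics are applied; otherwise they are
#' computed from the table and stored as attribute `"std_stats"`.
#'
#' @param table A `ScaleTable` tibble.
#' @param stats Optional fitted statistics to apply.
#' @param cols Columns to standardize; defaults to all predictor columns
#'   present.
#' @return The standardized table with attribute `"std_stats"`.
#' @export
standardize <- function(table, stats = NULL, cols = NULL) {
  cols <- cols %||% intersect(scale_predictors(attr(table, "scale") %||% "x"),
                              names(table))
  if (is.null(stats)) {
    mu <- vapply(table[cols], mean, numeric(1))
    sg <- vapply(table[cols], sd, numeric(1))
    bad <- cols[!is.finite(sg) | sg == 0]
    if (length(bad))
      stopf("cannot standardize zero-variance column(s): %s",
            paste(bad, collapse = ", "))
    stats <- tibble::tibble(column = cols, mean = mu, sd = sg)
  } else {
    stats <- stats[stats$column %in% cols, ]
    cols <- stats$column
  }
  out <- table
  for (i in seq_along(cols))
    out[[cols[i]]] <- (table[[cols[i]]] - stats$mean[i]) / stats$sd[i]
  attr(out, "std_stats") <- stats
  attr(out, "scale") <- attr(table, "scale")
  out
}

#' Undo a standardization
#'
#' @param table Standardized table carrying attribute `"std_stats"` (or
#'   `stats` supplied explicitly).
#' @param stats Optional statistics tibble.
#' @return Table on the original scale.
#' @export
destandardize <- function(table, stats = NULL) {
  stats <- stats %||% attr(table, "std_stats")
  if (is.null(stats)) stopf("no standardization statistics found")
  out <- table
  for (i in seq_len(nrow(stats))) {
    cc <- stats$column[i]
    out[[cc]] <- table[[cc]] * stats$sd[i] + stats$mean[i]
  }
  attr(out, "std_stats") <- NULL
  out
}
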