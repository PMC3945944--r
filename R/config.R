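#' Analysis configuration
#'
#' Collects every tunable threshold of the dive-analysis pipeline in one
#' validated list. Defaults are the values the method was developed with:
#' a dive is any excursion beyond 3 m, phase metrics and models use only
#' dives deeper than 15 m, descent/ascent terminate at a vertical rate of
#' 0.4 m/s, transit and bottom steps last less than 8 s, transit steps must
#' occur before 60\% of the maximum dive depth, wiggles pair an ascending and
#' a descending bottom step separated by less than 3 s, fixed windows are
#' kept when deep-dive cycles cover more than 85\% of them, the candidate
#' model set accumulates 0.95 of the Akaike weight, and jaw-acceleration
#' events are found on a 3-Hz high-passed signal with a 1.5-s (accelerometer)
#' or 5-s (Hall sensor) moving-variance window.
#'
#' @param dive_threshold_m Depth (m) beyond which an excursion is a dive.
#' @param deep_threshold_m Depth (m) separating shallow from deep dives;
#'   only deeper dives carry phase metrics and enter the models.
#' @param rate_threshold_ms Vertical rate (m/s) delimiting descent/ascent.
#' @param step_max_s Maximum duration (s, exclusive) of a step.
#' @param depth_fraction Fraction of maximum depth before which transit
#'   steps may occur.
#' @param wiggle_gap_s Maximum separation (s, exclusive) between the
#'   ascending and descending step of a wiggle.
#' @param wiggle_either_order Count descending-then-ascending successions as
#'   wiggles too (off by default; the definition is ascending first).
#' @param coverage_min Minimum fraction of a bout/window/night covered by
#'   deep-dive cycles for the row to enter the aggregate tables.
#' @param weight_threshold Cumulative Akaike weight defining the candidate
#'   model set.
#' @param max_vars Named per-scale caps on the number of predictors
#'   enumerated together.
#' @param filter_cutoff_hz High-pass cutoff (Hz) for jaw acceleration.
#' @param variance_window_s Named moving-variance windows (s) per sensor.
#' @param threshold_k Variance threshold multiplier.
#' @param threshold_rule Per-individual threshold rule: `"robust"`
#'   (median + k * MAD) or `"moment"` (mean + k * sd; self-calibrating when
#'   events are present, and the rule under which detection recall and
#'   precision are characterised).
#' @param event_merge_s Super-threshold runs closer than this (s) merge.
#' @param bec_variable Variable the bout-ending criterion is fitted to:
#'   absolute successive differences of post-dive intervals (`"diffs"`) or
#'   the raw intervals (`"raw_intervals"`).
#' @param quadrature_nodes Gauss-Hermite nodes for the mixed-model marginal
#'   likelihood.
#' @param seed Integer seed used by simulation-driven stages.
#' @param scales Temporal scales the pipeline builds and models.
#'
#' @return A list of class `forage_config`.
#' @export
forage_config <- function(dive_threshold_m = 3,
                          deep_threshold_m = 15,
                          rate_threshold_ms = 0.4,
                          step_max_s = 8,
                          depth_fraction = 0.6,
                          wiggle_gap_s = 3,
                          wiggle_either_order = FALSE,
                          coverage_min = 0.85,
                          weight_threshold = 0.95,
                          max_vars = c(dive = 11, bout = 7, win30 = 13,
                                       win60 = 13, win120 = 4, night = 2),
                          filter_cutoff_hz = 3,
                          variance_window_s = c(accelerometer = 1.5, hall = 5),
                          threshold_k = 6,
                          threshold_rule = c("robust", "moment"),
                          event_merge_s = 0.5,
                          bec_variable = c("diffs", "raw_intervals"),
                          quadrature_nodes = 15,
                          seed = 1L,
                          scales = c("dive", "bout", "win30", "win60",
                                     "win120", "night")) {
  cfg <- list(
    dive_threshold_m = dive_threshold_m,
    deep_threshold_m = deep_threshold_m,
    rate_threshold_ms = rate_threshold_ms,
    step_max_s = step_max_s,
    depth_fraction = depth_fraction,
    wiggle_gap_s = wiggle_gap_s,
    wiggle_either_order = wiggle_either_order,
    coverage_min = coverage_min,
    weight_threshold = weight_threshold,
    max_vars = as.list(max_vars),
    filter_cutoff_hz = filter_cutoff_hz,
    variance_window_s = as.list(variance_window_s),
    threshold_k = threshold_k,
    threshold_rule = match.arg(threshold_rule),
    event_merge_s = event_merge_s,
    bec_variable = match.arg(bec_variable),
    quadrature_nodes = as.integer(quadrature_nodes),
    seed = as.integer(seed),
    scales = scales
  )
  validate_config(cfg)
  structure(cfg, class = "forage_config")
}

validate_config <- function(cfg) {
  num_pos <- c("dive_threshold_m", "deep_threshold_m", "rate_threshold_ms",
               "step_max_s", "wiggle_gap_s", "filter_cutoff_hz",
               "threshold_k", "event_merge_s")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stopf("config field '%s' must be a positive number", f)
  for (f in c("depth_fraction", "coverage_min", "weight_threshold"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stopf("config field '%s' must lie in (0, 1)", f)
  if (cfg$deep_threshold_m < cfg$dive_threshold_m)
    stopf("deep_threshold_m must be at least dive_threshold_m")
  if (cfg$quadrature_nodes < 1) stopf("quadrature_nodes must be >= 1")
  invisible(cfg)
}

#' Write / read a configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param config A `forage_config` list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `forage_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(forage_config, c(
    raw[setdiff(names(raw), c("max_vars", "variance_window_s", "scales"))],
    list(max_vars = unlist(raw$max_vars),
         variance_window_s = unlist(raw$variance_window_s),
         scales = unlist(raw$scales))
  ))
  cfg
}

#' @export
print.forage_config <- function(x, ...) {
  cat("<forage_config>\n")
  cat(sprintf("  dive > %g m, deep > %g m, rate %g m/s, step < %g s\n",
              x$dive_threshold_m, x$deep_threshold_m, x$rate_threshold_ms,
              x$step_max_s))
  cat(sprintf("  wiggle gap < %g s, coverage > %g, weight threshold %g\n",
              x$wiggle_gap_s, x$coverage_min, x$weight_threshold))
  cat(sprintf("  scales: %s\n", paste(x$scales, collapse = ", ")))
  invisible(x)
}
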