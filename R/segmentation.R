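#' Correct the pressure-transducer surface offset
#'
#' Pressure transducers drift over a trip, so the apparent depth of surface
#' records (the minimum depth between two dives) wanders away from zero. A
#' smooth trend fitted through the inter-dive minima is subtracted from the
#' whole series: a robust linear fit when fewer than 10 surface records are
#' available, otherwise a smoothing spline. Negative residual depths are
#' preserved (not clipped) so the correction can be inspected.
#'
#' @param series Tibble with `time_s` (uniform 1-s grid) and `depth_m`
#'   (positive downward).
#' @param dive_threshold_m Depth used to find dives (and hence inter-dive
#'   surface records) in the uncorrected series.
#' @return The series with corrected `depth_m` and the fitted trend attached
#'   as column `surface_offset_m`.
#' @export
correct_surface_offset <- function(series, dive_threshold_m = 3) {
  stopifnot(all(c("time_s", "depth_m") %in% names(series)))
  assert_uniform_grid(series$time_s, 1, "depth series")
  if (any(!is.finite(series$depth_m))) stopf("depth series contains non-finite values")

  runs <- logical_runs(series$depth_m > dive_threshold_m)
  # surface stretches: before the first, between, and after the last dive
  starts <- c(1L, runs$end + 1L)
  ends <- c(runs$start - 1L, nrow(series))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    stopf(paste("no surface records found between dives; review the dive",
                "threshold before correcting the offset"))
  # surface record = minimum of the inter-dive segment, taken on a lightly
  # smoothed (5-s mean) trace so sensor noise does not bias the minima low
  sf_t <- numeric(length(starts)); sf_d <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- starts[i]:ends[i]
    x <- series$depth_m[seg]
    if (length(x) >= 5) {
      cs <- cumsum(c(0, x))
      x <- (cs[seq_len(length(x) - 4L) + 5L] - cs[seq_len(length(x) - 4L)]) / 5
      seg <- seg[seq_len(length(x)) + 2L]
    }
    j <- which.min(x)
    sf_t[i] <- series$time_s[seg[j]]
    sf_d[i] <- x[j]
  }

  if (length(sf_t) < 10) {
    # robust linear trend (iterated reweighting, Huber-type)
    w <- rep(1, length(sf_t))
    for (it in 1:5) {
      fit <- lm(sf_d ~ sf_t, weights = w)
      r <- sf_d - fitted(fit)
      s <- median(abs(r)) / 0.6745
      if (!is.finite(s) || s < 1e-8) break
      w <- pmin(1, 1.345 * s / pmax(abs(r), 1e-12))
    }
    trend <- coef(fit)[1] + coef(fit)[2] * series$time_s
  } else {
    fit <- smooth.spline(sf_t, sf_d, df = min(6, length(sf_t) - 1))
    trend <- predict(fit, x = series$time_s)$y
  }
  out <- series
  out$surface_offset_m <- as.numeric(trend)
  out$depth_m <- series$depth_m - out$surface_offset_m
  out
}

#' Detect dives in a depth series
#'
#' A dive is a maximal contiguous run of samples deeper than
#' `dive_threshold_m`, extended by one sample on each side to the adjacent
#' surface crossings.
#'
#' @param series Offset-corrected depth tibble (`time_s`, `depth_m`).
#' @param dive_threshold_m Dive definition depth (m).
#' @return Tibble, one row per dive: `dive_id`, `start_idx`, `end_idx`
#'   (1-based, inclusive), `start_s`, `end_s`, `max_depth`,
#'   `post_dive_interval` (s, `NA` for the last dive).
#' @export
detect_dives <- function(series, dive_threshold_m = 3) {
  runs <- logical_runs(series$depth_m > dive_threshold_m)
  if (!nrow(runs))
    return(tibble::tibble(dive_id = integer(), start_idx = integer(),
                          end_idx = integer(), start_s = numeric(),
                          end_s = numeric(), max_depth = numeric(),
                          post_dive_interval = numeric()))
  s <- pmax(runs$start - 1L, 1L)
  e <- pmin(runs$end + 1L, nrow(series))
  md <- vapply(seq_len(nrow(runs)),
               function(i) max(series$depth_m[runs$start[i]:runs$end[i]]),
               numeric(1))
  out <- tibble::tibble(
    dive_id = seq_len(nrow(runs)),
    start_idx = s, end_idx = e,
    start_s = series$time_s[s], end_s = series$time_s[e],
    max_depth = md)
  out$post_dive_interval <- c(out$start_s[-1] - out$end_s[-nrow(out)], NA)
  out
}

# Forward scan for the end of a continuous descent. diffs[t] is the 1-s
# depth increment from sample t to t+1; a "slowdown" is a maximal run of
# increments below the rate threshold. Slowdowns shorter than step_max_s and
# lying before depth_fraction of the maximum depth are tolerated (they are
# descent steps); the first disqualifying slowdown ends the descent.
# Returns the 1-based sample index at which the bottom phase starts.
scan_descent_end <- function(depth, rate_threshold_ms, step_max_s,
                             depth_fraction, max_depth) {
  diffs <- diff(depth)
  slow <- diffs < rate_threshold_ms
  runs <- logical_runs(slow)
  if (!nrow(runs)) return(length(depth))   # monotone to the end
  for (i in seq_len(nrow(runs))) {
    mean_d <- mean(depth[runs$start[i]:(runs$end[i] + 1L)])
    tolerated <- runs$length[i] < step_max_s &&
      mean_d < depth_fraction * max_depth &&
      runs$end[i] < length(diffs)          # a trailing slowdown ends descent
    if (!tolerated) return(runs$start[i])
  }
  length(depth)
}

#' Segment a dive into descent, bottom and ascent
#'
#' Scanning forward from the dive start, the descent continues while the
#' 1-s depth increment stays at or above `rate_threshold_ms`; slowdown runs
#' shorter than `step_max_s` occurring before `depth_fraction` of the
#' maximum depth are tolerated as descent steps, and the first disqualifying
#' slowdown ends the descent. The ascent is segmented symmetrically scanning
#' backward from the dive end. The bottom phase spans the two boundaries.
#'
#' @param depth Numeric vector of 1-Hz depths for one dive (surface to
#'   surface).
#' @param rate_threshold_ms Phase rate threshold (m/s).
#' @param step_max_s Step duration cap (s).
#' @param depth_fraction Maximum-depth fraction before which steps may occur.
#' @return List: `descent_end_idx`, `ascent_start_idx` (1-based sample
#'   indices into `depth`), `degenerate` flag (dive too short to hold three
#'   phases).
#' @export
segment_phases <- function(depth, rate_threshold_ms = 0.4, step_max_s = 8,
                           depth_fraction = 0.6) {
  n <- length(depth)
  if (n < 5)
    return(list(descent_end_idx = NA_integer_, ascent_start_idx = NA_integer_,
                degenerate = TRUE))
  md <- max(depth)
  de <- scan_descent_end(depth, rate_threshold_ms, step_max_s, depth_fraction, md)
  as_rev <- scan_descent_end(rev(depth), rate_threshold_ms, step_max_s,
                             depth_fraction, md)
  as_idx <- n + 1L - as_rev
  if (is.na(de) || is.na(as_idx) || de >= as_idx + 1L || de < 2L || as_idx > n - 1L)
    return(list(descent_end_idx = de, ascent_start_idx = as_idx,
                degenerate = TRUE))
  list(descent_end_idx = de, ascent_start_idx = as_idx, degenerate = FALSE)
}

#' Per-dive metrics for a corrected depth series
#'
#' Runs [detect_dives()] and [segment_phases()] and assembles the standard
#' dive record: phase durations, maximum depth, post-dive surface interval,
#' and descent/ascent rates (depth at the bottom boundary divided by the
#' transit duration). Dives at or below `deep_threshold_m` are detected but
#' carry no phase metrics (their dive durations are too short for the phase
#' thresholds to be meaningful) and are flagged `deep = FALSE`.
#'
#' @param series Offset-corrected depth tibble.
#' @param individual_id Identifier copied into the output.
#' @param config A [forage_config()].
#' @return Tibble, one row per dive (a `DiveRecord`).
#' @export
dive_metrics <- function(series, individual_id = "ind01",
                         config = forage_config()) {
  dv <- detect_dives(series, config$dive_threshold_m)
  n <- nrow(dv)
  out <- dv
  out$individual_id <- individual_id
  out$deep <- dv$max_depth > config$deep_threshold_m
  out$dive_duration <- dv$end_s - dv$start_s
  cols <- c("descent_duration", "bottom_duration", "ascent_duration",
            "descent_rate", "ascent_rate", "depth_bottom_start",
            "depth_bottom_end", "descent_end_s", "ascent_start_s")
  for (cc in cols) out[[cc]] <- NA_real_
  out$degenerate <- FALSE
  for (i in seq_len(n)) {
    if (!out$deep[i]) next
    dpt <- series$depth_m[dv$start_idx[i]:dv$end_idx[i]]
    seg <- segment_phases(dpt, config$rate_threshold_ms, config$step_max_s,
                          config$depth_fraction)
    if (seg$degenerate) { out$degenerate[i] <- TRUE; next }
    de <- seg$descent_end_idx; as_ <- seg$ascent_start_idx
    out$descent_end_s[i] <- dv$start_s[i] + de - 1L
    out$ascent_start_s[i] <- dv$start_s[i] + as_ - 1L
    out$descent_duration[i] <- de - 1L
    out$bottom_duration[i] <- as_ - de
    out$ascent_duration[i] <- length(dpt) - as_
    out$depth_bottom_start[i] <- dpt[de]
    out$depth_bottom_end[i] <- dpt[as_]
    out$descent_rate[i] <- dpt[de] / out$descent_duration[i]
    out$ascent_rate[i] <- dpt[as_] / out$ascent_duration[i]
  }
  out
}
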