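#' Detect steps in the descent or ascent of a dive
#'
#' A transit step is a maximal run of 1-s depth increments whose magnitude
#' stays below the rate threshold, lasting less than `step_max_s` seconds
#' and whose mean depth lies before (shallower than) `depth_fraction` of the
#' maximum dive depth. Slowdowns at greater depth fractions belong to the
#' bottom phase instead and are not steps.
#'
#' @param depth 1-Hz depth vector of one phase (descent or ascent),
#'   boundary samples included.
#' @param max_depth Maximum depth of the dive (m).
#' @param rate_threshold_ms,step_max_s,depth_fraction See [forage_config()].
#' @return Tibble of step intervals (`start`, `end` sample indices into
#'   `depth`, inclusive; `duration` in s).
#' @export
detect_transit_steps <- function(depth, max_depth, rate_threshold_ms = 0.4,
                                 step_max_s = 8, depth_fraction = 0.6) {
  if (length(depth) < 2) return(step_tibble())
  diffs <- abs(diff(depth))
  runs <- logical_runs(diffs < rate_threshold_ms)
  if (!nrow(runs)) return(step_tibble())
  mean_d <- vapply(seq_len(nrow(runs)), function(i)
    mean(depth[runs$start[i]:(runs$end[i] + 1L)]), numeric(1))
  keep <- runs$length >= 1 & runs$length < step_max_s &
    mean_d < depth_fraction * max_depth &
    runs$start > 1L & runs$end < length(diffs)   # interior slowdowns only
  tibble::tibble(start = runs$start[keep], end = runs$end[keep] + 1L,
                 duration = runs$length[keep])
}

step_tibble <- function() {
  tibble::tibble(start = integer(), end = integer(), duration = integer())
}

#' Detect descending and ascending steps in the bottom phase
#'
#' Bottom steps are maximal runs of 1-s depth changes whose magnitude
#' exceeds the rate threshold and that last less than `step_max_s` seconds;
#' a run moving deeper is a descending step, one moving shallower an
#' ascending step (depth is positive downward).
#'
#' @param depth 1-Hz depth vector of the bottom phase.
#' @param rate_threshold_ms,step_max_s See [forage_config()].
#' @return List of two step tibbles, `descending` and `ascending` (indices
#'   into `depth`).
#' @export
detect_bottom_steps <- function(depth, rate_threshold_ms = 0.4, step_max_s = 8) {
  if (length(depth) < 2)
    return(list(descending = step_tibble(), ascending = step_tibble()))
  diffs <- diff(depth)
  pick <- function(flag) {
    runs <- logical_runs(flag)
    keep <- runs$length < step_max_s
    tibble::tibble(start = runs$start[keep], end = runs$end[keep] + 1L,
                   duration = runs$length[keep])
  }
  list(descending = pick(diffs > rate_threshold_ms),
       ascending = pick(diffs < -rate_threshold_ms))
}

#' Count wiggles from bottom-step intervals
#'
#' A wiggle is the succession of an ascending and a descending bottom step
#' separated by less than `wiggle_gap_s` seconds (end of the ascending step
#' to start of the descending step). Pairs are formed greedily in time
#' order and each step participates in at most one wiggle. With
#' `either_order = TRUE`, descending-then-ascending successions count too.
#'
#' @param ascending,descending Step tibbles from [detect_bottom_steps()]
#'   (indices on a common time base).
#' @param wiggle_gap_s Maximum separation (s, exclusive).
#' @param either_order Accept either step order (off by default).
#' @return Integer wiggle count.
#' @export
detect_wiggles <- function(ascending, descending, wiggle_gap_s = 3,
                           either_order = FALSE) {
  pair_count <- function(first, second) {
    used <- rep(FALSE, nrow(second))
    n <- 0L
    for (i in seq_len(nrow(first))) {
      j <- which(!used & second$start >= first$end[i] &
                   second$start - first$end[i] < wiggle_gap_s)
      if (length(j)) { used[j[1]] <- TRUE; n <- n + 1L }
    }
    n
  }
  n <- pair_count(ascending, descending)
  if (either_order) n <- n + pair_count(descending, ascending)
  n
}

#' Bottom depth-variation index
#'
#' The difference between the maximum dive depth and the depth at the start
#' of the bottom phase. Staircases of descending bottom steps make it large;
#' it is negative only when the maximum depth occurs before the bottom phase
#' starts (such dives are flagged, not dropped).
#'
#' @param max_depth Maximum dive depth (m).
#' @param depth_bottom_start Depth at the start of the bottom phase (m).
#' @return Numeric (m).
#' @export
bottom_depth_variation <- function(max_depth, depth_bottom_start) {
  max_depth - depth_bottom_start
}

#' Per-dive feature counts
#'
#' Applies the step, wiggle and depth-variation detectors to every deep,
#' non-degenerate dive in a metrics table and appends the feature columns.
#'
#' @param series Offset-corrected depth tibble.
#' @param dives Output of [dive_metrics()].
#' @param config A [forage_config()].
#' @return `dives` with columns `steps_descent`, `steps_ascent`,
#'   `steps_descending_bottom`, `steps_ascending_bottom`, `wiggles`,
#'   `depth_variation_bottom`.
#' @export
dive_features <- function(series, dives, config = forage_config()) {
  n <- nrow(dives)
  out <- dives
  for (cc in c("steps_descent", "steps_ascent", "steps_descending_bottom",
               "steps_ascending_bottom", "wiggles"))
    out[[cc]] <- NA_integer_
  out$depth_variation_bottom <- NA_real_
  for (i in seq_len(n)) {
    if (!isTRUE(out$deep[i]) || isTRUE(out$degenerate[i])) next
    dpt <- series$depth_m[dives$start_idx[i]:dives$end_idx[i]]
    de <- dives$descent_end_s[i] - dives$start_s[i] + 1L
    as_ <- dives$ascent_start_s[i] - dives$start_s[i] + 1L
    md <- dives$max_depth[i]
    out$steps_descent[i] <- nrow(detect_transit_steps(
      dpt[1:de], md, config$rate_threshold_ms, config$step_max_s,
      config$depth_fraction))
    out$steps_ascent[i] <- nrow(detect_transit_steps(
      dpt[as_:length(dpt)], md, config$rate_threshold_ms, config$step_max_s,
      config$depth_fraction))
    bs <- detect_bottom_steps(dpt[de:as_], config$rate_threshold_ms,
                              config$step_max_s)
    out$steps_descending_bottom[i] <- nrow(bs$descending)
    out$steps_ascending_bottom[i] <- nrow(bs$ascending)
    out$wiggles[i] <- detect_wiggles(bs$ascending, bs$descending,
                                     config$wiggle_gap_s,
                                     config$wiggle_either_order)
    out$depth_variation_bottom[i] <- bottom_depth_variation(
      md, dives$depth_bottom_start[i])
  }
  out
}
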