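#' Zero-phase high-pass filter for jaw acceleration
#'
#' Removes low-frequency head and body acceleration so that the brief,
#' high-frequency transients produced by mouth openings stand out. A
#' 4th-order Butterworth high-pass is applied forward and backward
#' (zero phase).
#'
#' @param x Numeric signal.
#' @param rate_hz Sample rate (Hz).
#' @param cutoff_hz Cutoff (Hz); must be below the Nyquist frequency.
#' @return Filtered signal, same length.
#' @export
highpass_filter <- function(x, rate_hz = 16, cutoff_hz = 3) {
  if (cutoff_hz >= rate_hz / 2)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff_hz, rate_hz / 2)
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "high")
  # centering first makes DC removal exact and shrinks the forward-backward
  # filter's edge transients
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Centered moving variance
#'
#' Sliding-window sample variance with truncated windows at the edges, the
#' same length as the input. The window is `window_s * rate_hz` samples
#' (1.5 s at 16 Hz = 24 samples for accelerometers; 5 s for Hall sensors).
#'
#' @param x Numeric signal.
#' @param window_s Window length (s).
#' @param rate_hz Sample rate (Hz).
#' @return Numeric variance series.
#' @export
moving_variance <- function(x, window_s = 1.5, rate_hz = 16) {
  w <- as.integer(round(window_s * rate_hz))
  if (w < 3) stopf("variance window must span at least 3 samples")
  moving_variance_cpp(as.numeric(x), w = w)
}

#' Threshold the variance series into mouth-opening events
#'
#' Contiguous super-threshold runs are merged into single events (runs
#' closer than `merge_s` coalesce). Two per-individual threshold rules are
#' available: `"robust"` (median + k * MAD of the variance series) and
#' `"moment"` (mean + k * sd; the event transients themselves inflate the
#' sd, so this rule self-calibrates upward when events are present and is
#' the rule under which the detector's recall/precision performance is
#' characterised). An absolute threshold can be supplied instead.
#'
#' @param variance Variance series from [moving_variance()].
#' @param time_s Time stamps of the series.
#' @param k Threshold multiplier.
#' @param rule `"robust"` or `"moment"`.
#' @param absolute Optional absolute threshold overriding the rule.
#' @param merge_s Runs separated by less than this (s) merge into one event.
#' @param signal Optional raw (filtered) signal: when given, each event is
#'   timed at the peak of `|signal|` inside its run, which localises the
#'   transient much more sharply than the variance peak (the moving window
#'   smears the variance by up to half a window length).
#' @return Tibble: `time_s` (run peak), `start_s`, `end_s`, `peak_var`,
#'   with the threshold attached as attribute `"threshold"`.
#' @export
threshold_events <- function(variance, time_s, k = 6,
                             rule = c("robust", "moment"), absolute = NULL,
                             merge_s = 0.5, signal = NULL) {
  if (any(!is.finite(variance))) stopf("variance series must be finite")
  rule <- match.arg(rule)
  thr <- absolute %||% switch(rule,
    robust = median(variance) + k * mad(variance),
    moment = mean(variance) + k * sd(variance))
  runs <- logical_runs(variance > thr)
  empty <- tibble::tibble(time_s = numeric(), start_s = numeric(),
                          end_s = numeric(), peak_var = numeric())
  if (!nrow(runs)) return(structure(empty, threshold = thr))
  # merge runs separated by less than merge_s
  if (nrow(runs) > 1) {
    gap <- time_s[runs$start[-1]] - time_s[runs$end[-nrow(runs)]]
    grp <- cumsum(c(0, gap >= merge_s)) + 1L
    runs <- tibble::tibble(
      start = tapply(runs$start, grp, min)[as.character(seq_len(max(grp)))],
      end = tapply(runs$end, grp, max)[as.character(seq_len(max(grp)))])
  }
  out <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    pk <- if (is.null(signal)) idx[which.max(variance[idx])]
          else idx[which.max(abs(signal[idx]))]
    tibble::tibble(time_s = time_s[pk], start_s = time_s[runs$start[i]],
                   end_s = time_s[runs$end[i]],
                   peak_var = variance[idx[which.max(variance[idx])]])
  })
  structure(out, threshold = thr)
}

#' Assign detected events to dives
#'
#' Each event is mapped to the dive whose span contains it; events outside
#' any dive are flagged as surface events and excluded from the per-dive
#' counts (they do not enter the models).
#'
#' @param event_times Numeric event times (s).
#' @param dives Dive metrics tibble (`dive_id`, `start_s`, `end_s`).
#' @return List: `counts` (tibble `dive_id`, `pca_count` covering every
#'   dive) and `surface_events` (times outside any dive).
#' @export
assign_events_to_dives <- function(event_times, dives) {
  counts <- tibble::tibble(dive_id = dives$dive_id,
                           pca_count = 0L)
  if (!length(event_times))
    return(list(counts = counts, surface_events = numeric()))
  dive_of <- vapply(event_times, function(te) {
    i <- which(dives$start_s <= te & te <= dives$end_s)
    if (length(i)) dives$dive_id[i[1]] else NA_integer_
  }, integer(1))
  tab <- table(dive_of[!is.na(dive_of)])
  counts$pca_count <- as.integer(tab[as.character(counts$dive_id)])
  counts$pca_count[is.na(counts$pca_count)] <- 0L
  list(counts = counts, surface_events = event_times[is.na(dive_of)])
}

#' Detect prey capture attempts on a full trip
#'
#' Runs the sensor-appropriate pipeline: 3-Hz zero-phase high-pass (skipped
#' for Hall sensors, whose signal is already a slow baseline plus event
#' deflections), moving variance (1.5 s accelerometer / 5 s Hall), robust
#' thresholding with run merging, and per-dive assignment.
#'
#' @param accel Acceleration tibble (`time_s`, `ax`, ...); the first channel
#'   after `time_s` is analysed.
#' @param dives Dive metrics tibble.
#' @param config A [forage_config()].
#' @param sensor `"accelerometer"` or `"hall"`.
#' @return List: `events` tibble, `counts` tibble (`dive_id`, `pca_count`),
#'   `surface_events`, `threshold`.
#' @export
detect_pca <- function(accel, dives, config = forage_config(),
                       sensor = c("accelerometer", "hall")) {
  sensor <- match.arg(sensor)
  rate <- 1 / median(diff(accel$time_s))
  x <- accel[[setdiff(names(accel), "time_s")[1]]]
  if (sensor == "accelerometer")
    x <- highpass_filter(x, rate_hz = rate, cutoff_hz = config$filter_cutoff_hz)
  v <- moving_variance(x, window_s = config$variance_window_s[[sensor]],
                       rate_hz = rate)
  ev <- threshold_events(v, accel$time_s, k = config$threshold_k,
                         rule = config$threshold_rule,
                         merge_s = config$event_merge_s, signal = x)
  asg <- assign_events_to_dives(ev$time_s, dives)
  list(events = ev, counts = asg$counts, surface_events = asg$surface_events,
       threshold = attr(ev, "threshold"))
}
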