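test_that("the high-pass filter removes DC and passes the band", {
  fs <- 16
  t <- seq(0, 60, by = 1 / fs)
  # constant signal is annihilated
  expect_lt(max(abs(highpass_filter(rep(3, length(t)), fs))), 1e-6 * 3)
  # 0.5-Hz tone strongly attenuated, 6-Hz tone passed
  lo <- sin(2 * pi * 0.5 * t)
  hi <- sin(2 * pi * 6 * t)
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(5 * fs, length(t) - 5 * fs)  # ignore filter edge transients
  expect_lt(rms(highpass_filter(lo, fs)[mid]), 0.1 * rms(lo[mid]))
  expect_gt(rms(highpass_filter(hi, fs)[mid]), 0.9 * rms(hi[mid]))
  expect_lt(rms(highpass_filter(hi, fs)[mid]), 1.1 * rms(hi[mid]))
  # cutoff above Nyquist is rejected
  expect_error(highpass_filter(hi, rate_hz = 16, cutoff_hz = 9), "Nyquist")
})

test_that("moving variance matches a rolling oracle and is consistent", {
  # constant signal: all zeros
  expect_equal(moving_variance(rep(2, 100), 1.5, 16), rep(0, 100))
  # 1.5 s at 16 Hz is a 24-sample window; matches a literal rolling oracle
  set.seed(3)
  x <- rnorm(400)
  got <- moving_variance(x, 1.5, 16)
  want <- vapply(seq_along(x), function(t) {
    a <- max(1, t - 12); b <- min(length(x), t - 12 + 23)
    var(x[a:b])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(length(x[max(1, 200 - 12):(200 - 12 + 23)]), 24)
  # odd windows agree with zoo::rollapply
  got5 <- moving_variance(x, 5 / 16, 16)      # 5-sample window
  want5 <- zoo::rollapply(x, width = 5, FUN = var, partial = TRUE,
                          align = "center")
  expect_equal(got5, as.numeric(want5), tolerance = 1e-10)
  # unbiased for white noise
  set.seed(4)
  x <- rnorm(1e5, 0, 2)
  v <- moving_variance(x, 1.5, 16)
  expect_gt(mean(v), 0.9 * 4)
  expect_lt(mean(v), 1.1 * 4)
  # sub-3-sample windows are refused
  expect_error(moving_variance(x, 0.1, 16), "3 samples")
})

test_that("thresholding merges close runs and finds no events in silence", {
  t <- seq(0, 100, by = 1 / 16)
  expect_equal(nrow(threshold_events(rep(0, length(t)), t, absolute = 1)), 0)
  v <- rep(0, length(t))
  v[1000:1005] <- 5
  v[1009:1012] <- 4   # 0.1875 s later: merges
  v[1200:1204] <- 3   # far away: separate event
  ev <- threshold_events(v, t, absolute = 1, merge_s = 0.5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$time_s[1], t[1000])  # run peak
})

test_that("events map to the dives containing them", {
  dives <- tibble::tibble(dive_id = 1:2, start_s = c(100, 300),
                          end_s = c(200, 400))
  got <- assign_events_to_dives(c(150, 160, 170, 250, 350), dives)
  expect_equal(got$counts$pca_count, c(3L, 1L))
  expect_equal(got$surface_events, 250)
  empty <- assign_events_to_dives(numeric(), dives)
  expect_equal(empty$counts$pca_count, c(0L, 0L))
})

test_that("injected bursts are recovered with high recall and precision", {
  cfg <- tiny_sim(seed = 41, night_hours = 3)
  tr <- simulate_trip(cfg, "ind01")
  co <- forage_config()
  p <- process_individual(tr$depth, tr$accel, "ind01", co)
  evt <- tr$truth$events$time_s
  evd <- p$events$time_s
  expect_gt(length(evt), 20)
  recall <- mean(vapply(evt, function(s) any(abs(evd - s) <= 0.5), TRUE))
  precision <- mean(vapply(evd, function(s) any(abs(evt - s) <= 0.5), TRUE))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # conservation: dive counts plus surface events equal total detections
  expect_equal(sum(p$dives$pca_count) + length(p$surface_events),
               nrow(p$events))
})

test_that("detection is deterministic given signal and config", {
  cfg <- tiny_sim(seed = 43)
  tr <- simulate_trip(cfg, "ind01")
  co <- forage_config()
  d <- dive_metrics(correct_surface_offset(tr$depth), "ind01", co)
  a <- detect_pca(tr$accel, d, co)
  b <- detect_pca(tr$accel, d, co)
  expect_identical(a$events, b$events)
  expect_identical(a$counts, b$counts)
})

test_that("hall-sensor mode uses the 5-s window without the high-pass", {
  cfg <- tiny_sim(seed = 47, night_hours = 2)
  tr <- simulate_trip(cfg, "ind01")
  co <- forage_config()
  d <- dive_metrics(correct_surface_offset(tr$depth), "ind01", co)
  out <- detect_pca(tr$accel, d, co, sensor = "hall")
  expect_true(nrow(out$events) > 0)
})
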