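test_that("a fixed seed reproduces the full trip bit for bit", {
  cfg <- tiny_sim(seed = 7)
  a <- simulate_trip(cfg, "ind01")
  b <- simulate_trip(cfg, "ind01")
  expect_identical(a$depth, b$depth)
  expect_identical(a$accel, b$accel)
  expect_identical(a$truth$dives, b$truth$dives)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("noise-free construction reproduces the sampled dive geometry", {
  cfg <- tiny_sim(seed = 3, noise = 0, drift = 0)
  tr <- simulate_trip(cfg, "ind01")
  tt <- tr$truth$dives
  expect_gt(nrow(tt), 5)
  for (i in seq_len(nrow(tt))) {
    dd <- tr$depth$depth_m[tr$depth$time_s >= tt$start_s[i] &
                             tr$depth$time_s <= tt$end_s[i]]
    expect_equal(max(dd), tt$max_depth[i], tolerance = 1e-10)
  }
  # series is a clean 1-s / 16-Hz grid with no gaps
  expect_equal(unique(diff(tr$depth$time_s)), 1)
  expect_equal(diff(range(diff(tr$accel$time_s))), 0, tolerance = 1e-9)
})

test_that("with no dives the depth series is exactly the drift trend", {
  cfg <- tiny_sim(seed = 2, noise = 0, drift = 1,
                  bout_structure = list(mean_dives = 0, surface_mean_s = 45,
                                        gap_mean_s = 3600))
  tr <- simulate_trip(cfg, "ind01")
  s <- (tr$depth$time_s - tr$depth$time_s[1]) /
    diff(range(tr$depth$time_s))
  expect_equal(tr$depth$depth_m, 1 * s, tolerance = 1e-12)
})

test_that("injected event counts are conserved and lie inside their dives", {
  cfg <- tiny_sim(seed = 9, night_hours = 3)
  tr <- simulate_trip(cfg, "ind01")
  tt <- tr$truth$dives
  ev <- tr$truth$events
  expect_equal(nrow(ev), sum(tt$pca_count))
  counts <- table(factor(ev$dive_id, levels = tt$dive_id))
  expect_equal(as.integer(counts), tt$pca_count)
  inside <- ev$time_s >= tt$start_s[ev$dive_id] &
    ev$time_s <= tt$end_s[ev$dive_id]
  expect_true(all(inside))
})

test_that("degenerate simulation configs are rejected", {
  expect_error(sim_config(night_window = c(1000, 1000)), "zero")
  expect_error(sim_config(dive_shape = list(max_depth_mean = 45,
                                            max_depth_sd = 12,
                                            descent_speed = 0.3,
                                            ascent_speed = 1.1,
                                            bottom_mean_s = 40,
                                            shallow_prob = 0)),
               "0.4 m/s")
  expect_error(sim_config(accel = list(rate_hz = 16, baseline_sd = 1,
                                       event_amp = 0.5, event_dur_s = 0.3,
                                       body_amp = 3, body_freq_hz = 0.4)),
               "amplitude")
})

test_that("simulate_pca_counts follows the Poisson log-link law", {
  # beta = 0, intercept = 0, sd = 0: i.i.d. Poisson(1)
  tab <- tibble::tibble(x = rnorm(1e5))
  y <- simulate_pca_counts(tab, list(intercept = 0, beta = c(x = 0), sd = 0),
                           seed = 1)
  expect_lt(abs(mean(y) - 1), 0.02)

  # slope recovered by a Poisson GLM oracle
  tab <- tibble::tibble(x = rnorm(1e4))
  y <- simulate_pca_counts(tab, list(intercept = 0, beta = c(x = 1), sd = 0),
                           seed = 2)
  slope <- unname(coef(glm(y ~ tab$x, family = poisson))[2])
  expect_lt(abs(slope - 1), 0.05)

  # a hugely negative intercept yields all-zero counts
  y <- simulate_pca_counts(tab, list(intercept = -50, beta = c(x = 1), sd = 0),
                           seed = 3)
  expect_true(all(y == 0))

  # missing predictors and non-finite linear predictors error
  expect_error(simulate_pca_counts(tab, list(intercept = 0,
                                             beta = c(zz = 1), sd = 0)),
               "zz")
  tab$x[1] <- Inf
  expect_error(simulate_pca_counts(tab, list(intercept = 0, beta = c(x = 1),
                                             sd = 0), seed = 1),
               "non-finite")
})

test_that("trip files round-trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim(seed = 4, night_hours = 1)
  tr <- simulate_trip(cfg, "ind01")
  write_trip(tr, dir)
  depth <- readr::read_csv(file.path(dir, "ind01_depth.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(depth), nrow(tr$depth))
  expect_equal(names(depth), c("time_s", "depth_m"))
  truth <- jsonlite::read_json(file.path(dir, "ind01_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$dives$start_s), nrow(tr$truth$dives))
})
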