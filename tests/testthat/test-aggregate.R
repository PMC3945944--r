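# A hand-built dive set: regular 100-s dive cycles (60-s dive + 40-s
# interval) so window coverage is easy to reason about.
make_dives <- function(n = 12, individual_id = "a", bout_id = 1L,
                       t0 = 0, deep = TRUE, pca = NULL) {
  tibble::tibble(
    individual_id = individual_id,
    dive_id = seq_len(n),
    bout_id = bout_id,
    start_s = t0 + (seq_len(n) - 1) * 100,
    dive_duration = 60,
    post_dive_interval = 40,
    pca_count = pca %||% rep(2L, n),
    max_depth = 40, surface_duration = 40,
    descent_rate = 1.2, ascent_rate = 1.1, bottom_duration = 30,
    depth_variation_bottom = 2, steps_descent = 1, steps_ascent = 0,
    steps_descending_bottom = 1, steps_ascending_bottom = 1, wiggles = 1,
    deep = deep, degenerate = FALSE, included = TRUE)
}

test_that("the dive table applies the depth and inclusion filters", {
  d <- make_dives(10)
  d$max_depth[1:2] <- 12; d$deep[1:2] <- FALSE
  d$included[3] <- FALSE
  tab <- build_dive_table(d)
  expect_equal(nrow(tab), 7)
  expect_false(3 %in% tab$dive_id)
  # pass-through of per-dive metrics
  expect_equal(tab$bottom_duration, rep(30, 7))
  expect_equal(attr(tab, "scale"), "dive")
  # everything filtered away is an informative error
  d2 <- make_dives(4)
  d2$included <- FALSE
  expect_error(build_dive_table(d2), "bout inclusion")
})

test_that("bout rows sum responses, average predictors and count dives", {
  d <- make_dives(6, pca = c(2L, 3L, 0L, 1L, 1L, 4L))
  tab <- build_bout_table(build_dive_table(d), d)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pca_count, 11L)
  expect_equal(tab$n_dives, 6L)
  expect_equal(tab$max_depth, 40)
  expect_gt(tab$pct_time_deep, 0.99)
  # a bout diluted by shallow dives fails the 85 % coverage rule
  d2 <- make_dives(12, bout_id = 2L, t0 = 2000)
  d2$deep[7:12] <- FALSE
  d2$included[7:12] <- FALSE
  both <- dplyr::bind_rows(d, d2)
  tab2 <- build_bout_table(build_dive_table(both), both)
  expect_equal(tab2$bout_id, 1L)
})

test_that("window tables honour tiling, coverage and trailing-window rules", {
  d <- make_dives(36)                    # 3600 s of contiguous deep cycles
  dt <- build_dive_table(d)
  w30 <- build_window_table(dt, d, 1800)
  expect_equal(nrow(w30), 2)             # 2 full 30-min windows, fully paved
  expect_equal(w30$pct_time_deep, c(1, 1), tolerance = 1e-9)
  expect_equal(w30$n_dives, c(18L, 18L))
  # 3700 s of data: the partial trailing window is dropped
  d2 <- make_dives(37)
  w30b <- build_window_table(build_dive_table(d2), d2, 1800)
  expect_equal(nrow(w30b), 2)
  # one 100-s deep cycle in an 1800-s window: ~5.6 % coverage, excluded
  d3 <- make_dives(2)
  d3$start_s <- c(0, 1700)
  d3$deep[2] <- FALSE
  d3$included[2] <- FALSE
  expect_equal(nrow(build_window_table(build_dive_table(d3), d3, 1800)), 0)
})

test_that("responses are conserved from dives to bouts and windows", {
  set.seed(8)
  d <- make_dives(72, pca = rpois(72, 3))
  dt <- build_dive_table(d)
  bt <- build_bout_table(dt, d)
  expect_equal(sum(dt$pca_count), sum(bt$pca_count))
  w30 <- build_window_table(dt, d, 1800)
  w120 <- build_window_table(dt, d, 7200)
  for (i in seq_len(nrow(w30))) {
    w0 <- (i - 1) * 1800; w1 <- w0 + 1800
    expect_equal(w30$pca_count[i],
                 sum(dt$pca_count[dt$start_s >= w0 & dt$start_s < w1]))
  }
  # a 2-h window equals the sum of its four kept 30-min windows
  if (nrow(w120) == 1) expect_equal(w120$pca_count, sum(w30$pca_count[1:4]))
})

test_that("night tables keep only complete nights and sum their dives", {
  d <- dplyr::bind_rows(make_dives(5, t0 = 0),
                        make_dives(5, bout_id = 2L, t0 = 90000))
  d$dive_id <- seq_len(nrow(d))
  nights <- tibble::tibble(individual_id = "a", night_id = 1:2,
                           start_s = c(0, 86400), end_s = c(7200, 93600),
                           complete = c(TRUE, FALSE))
  dt <- build_dive_table(d)
  nt <- build_night_table(dt, d, nights)
  expect_equal(nrow(nt), 1)
  expect_equal(nt$night_id, 1L)
  expect_equal(nt$pca_count, sum(dt$pca_count[dt$start_s < 7200]))
})

test_that("standardization contracts hold and round-trip", {
  set.seed(9)
  d <- make_dives(30, pca = rpois(30, 2))
  d$max_depth <- rnorm(30, 40, 5)
  d$bottom_duration <- rnorm(30, 30, 4)
  dt <- build_dive_table(d)
  std <- standardize(dt, cols = c("max_depth", "bottom_duration"))
  expect_lt(abs(mean(std$max_depth)), 1e-9)
  expect_lt(abs(sd(std$max_depth) - 1), 1e-9)
  # train statistics applied to a shifted test set keep the shift visible
  dt2 <- dplyr::mutate(dt, max_depth = max_depth + 10)
  std2 <- standardize(dt2, stats = attr(std, "std_stats"))
  expect_gt(mean(std2$max_depth), 1)
  # round trip
  back <- destandardize(std)
  expect_equal(back$max_depth, dt$max_depth, tolerance = 1e-12)
  # zero-variance columns are named in the error
  expect_error(standardize(dt, cols = c("max_depth", "wiggles")), "wiggles")
})
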