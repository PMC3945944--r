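make_series <- function(depth) {
  tibble::tibble(time_s = seq_along(depth) - 1, depth_m = depth)
}

test_that("constant and linear surface offsets are removed", {
  base <- c(rep(0, 120), trapezoid_dive(30), rep(0, 120),
            trapezoid_dive(40), rep(0, 120))
  # constant +0.5 m
  co <- correct_surface_offset(make_series(base + 0.5))
  surf <- co$depth_m[base == 0]
  expect_lt(max(abs(surf)), 0.05)
  # linear 0 -> 1 m drift: corrected series close to the drift-free truth
  drift <- seq(0, 1, length.out = length(base))
  co <- correct_surface_offset(make_series(base + drift))
  expect_lt(max(abs(co$depth_m - base)), 0.1)
  # already-zeroed series is (nearly) untouched
  co <- correct_surface_offset(make_series(base))
  expect_lt(max(abs(co$depth_m - base)), 0.05)
})

test_that("offset correction demands surface records", {
  deep <- make_series(rep(30, 500))
  expect_error(correct_surface_offset(deep), "threshold")
})

test_that("dive detection matches an exhaustive scan oracle", {
  set.seed(42)
  for (rep in 1:20) {
    depth <- pmax(0, rnorm(300, 0, 0.1))
    n_d <- sample(0:4, 1)
    pos <- sort(sample(seq(10, 250, by = 60), n_d))
    for (p in pos) depth[p:(p + sample(5:20, 1))] <- runif(1, 4, 50)
    got <- detect_dives(make_series(depth))
    want <- oracle_detect_dives(depth)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start_idx[i], want[[i]][1])
      expect_equal(got$end_idx[i], want[[i]][2])
    }
  }
})

test_that("sub-threshold excursions are not dives; intervals are measured", {
  expect_equal(nrow(detect_dives(make_series(c(0, 1, 2.9, 2, 0)))), 0)
  # two rectangular 20-m excursions separated by 100 s of surface
  depth <- c(rep(0, 50), rep(20, 30), rep(0, 100), rep(20, 30), rep(0, 50))
  dv <- detect_dives(make_series(depth))
  expect_equal(nrow(dv), 2)
  # 100 surface samples, one consumed by each dive's extended crossing
  expect_equal(dv$post_dive_interval[1], 99)
  expect_equal(dv$max_depth, c(20, 20))
  dv1 <- detect_dives(make_series(c(rep(0, 10), rep(50, 20), rep(0, 10))))
  expect_equal(nrow(dv1), 1)
  expect_equal(dv1$max_depth, 50)
})

test_that("phase segmentation recovers constructed boundaries", {
  # trapezoid: 1 m/s to 30 m, 60 s flat, 1 m/s up
  depth <- trapezoid_dive(30, 1, 60)
  seg <- segment_phases(depth)
  expect_false(seg$degenerate)
  expect_equal(seg$descent_end_idx, 31)         # arrival at 30 m
  expect_equal(seg$ascent_start_idx, 31 + 60)
  # durations: descent 30 s, bottom 60 s, ascent 30 s, rate 1 m/s
  expect_equal(depth[seg$descent_end_idx] / (seg$descent_end_idx - 1), 1.0)

  # V-dive: bottom no longer than the grid allows
  vd <- c(seq(0, 30, 1), seq(29, 0, -1))
  seg <- segment_phases(vd)
  expect_lte(seg$ascent_start_idx - seg$descent_end_idx, 2)

  # a 5-s plateau at a third of the maximum depth is tolerated
  depth <- trapezoid_dive(30, 1, 60, plateau_depth = 10, plateau_s = 5)
  seg <- segment_phases(depth)
  expect_equal(depth[seg$descent_end_idx], 30)

  # a plateau at 70 % of the maximum depth starts the bottom phase
  depth <- trapezoid_dive(30, 1, 60, plateau_depth = 21, plateau_s = 5)
  seg <- segment_phases(depth)
  expect_equal(depth[seg$descent_end_idx], 21)
})

test_that("phase durations sum to the dive duration within one sample", {
  cfg <- tiny_sim(seed = 13, night_hours = 2)
  tr <- simulate_trip(cfg, "ind01")
  d <- dive_metrics(correct_surface_offset(tr$depth), "ind01")
  deep <- d$deep & !d$degenerate
  expect_gt(sum(deep), 10)
  total <- d$descent_duration[deep] + d$bottom_duration[deep] +
    d$ascent_duration[deep]
  expect_true(all(abs(total - d$dive_duration[deep]) <= 1))
  expect_true(all(d$descent_rate[deep] > 0 & d$ascent_rate[deep] > 0))
})

test_that("noise-free boundaries equal the generator truth exactly", {
  cfg <- tiny_sim(seed = 21, noise = 0, drift = 0, night_hours = 2)
  tr <- simulate_trip(cfg, "ind01")
  d <- dive_metrics(correct_surface_offset(tr$depth), "ind01")
  tt <- tr$truth$dives
  expect_equal(nrow(d), nrow(tt))
  deep <- tt$deep
  expect_equal(d$descent_end_s[deep], tt$descent_end_s[deep])
  expect_equal(d$ascent_start_s[deep], tt$ascent_start_s[deep])
})

test_that("detect_dives is idempotent on its own output spans", {
  cfg <- tiny_sim(seed = 5)
  tr <- simulate_trip(cfg, "ind01")
  co <- correct_surface_offset(tr$depth)
  d1 <- detect_dives(co)
  d2 <- detect_dives(co)
  expect_identical(d1, d2)
})
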