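test_that("transit steps follow the rate / duration / depth-fraction rules", {
  # one 5-s plateau at 40 % of a 30-m dive: exactly one step
  down <- trapezoid_dive(30, 1, 10, plateau_depth = 12, plateau_s = 5)
  de <- segment_phases(down)$descent_end_idx
  st <- detect_transit_steps(down[1:de], 30)
  expect_equal(nrow(st), 1)
  expect_equal(st$duration, 5)

  # a 10-s plateau fails the "< 8 s" rule
  down <- trapezoid_dive(30, 1, 10, plateau_depth = 12, plateau_s = 10)
  de <- segment_phases(down)$descent_end_idx
  expect_equal(nrow(detect_transit_steps(down[1:de], 30)), 0)

  # monotone constant-speed descent has no steps
  expect_equal(nrow(detect_transit_steps(seq(0, 30), 30)), 0)

  # a plateau at 70 % of max depth is not a transit step
  prof <- c(seq(0, 21, 1), rep(21, 5), seq(22, 30, 1))
  expect_equal(nrow(detect_transit_steps(prof, 30)), 0)
})

test_that("bottom steps are signed, capped runs", {
  flat <- rep(30, 40)
  expect_equal(vapply(detect_bottom_steps(flat), nrow, 0L),
               c(descending = 0L, ascending = 0L))

  # one 3-s excursion 2 m deeper and back
  b <- c(rep(30, 10), 30 + c(1, 2), rep(32, 3), 32 - c(1, 2), rep(30, 10))
  bs <- detect_bottom_steps(b)
  expect_equal(nrow(bs$descending), 1)
  expect_equal(nrow(bs$ascending), 1)

  # a staircase of three 2-s deepening runs separated by flats
  b <- c(rep(30, 8), 31, 32, rep(32, 4), 33, 34, rep(34, 4), 35, 36,
         rep(36, 8))
  bs <- detect_bottom_steps(b)
  expect_equal(nrow(bs$descending), 3)
  expect_equal(nrow(bs$ascending), 0)
})

test_that("wiggle pairing is greedy with the < 3 s gap rule", {
  asc <- tibble::tibble(start = 5L, end = 10L, duration = 5L)
  desc <- tibble::tibble(start = 12L, end = 14L, duration = 2L)
  expect_equal(detect_wiggles(asc, desc), 1)        # gap 2 s
  desc$start <- 15L
  expect_equal(detect_wiggles(asc, desc), 0)        # gap 5 s
  # A,D,A,D alternation with 1-s gaps pairs greedily into 2 wiggles
  asc <- tibble::tibble(start = c(1L, 11L), end = c(3L, 13L),
                        duration = c(2L, 2L))
  desc <- tibble::tibble(start = c(4L, 14L), end = c(6L, 16L),
                         duration = c(2L, 2L))
  expect_equal(detect_wiggles(asc, desc), 2)
  # either-order mode also counts descending-then-ascending successions
  expect_equal(detect_wiggles(desc, asc, either_order = FALSE), 0)
  expect_equal(detect_wiggles(desc, asc, either_order = TRUE), 2)
})

test_that("bottom depth variation is max depth minus bottom-start depth", {
  expect_equal(bottom_depth_variation(42, 30), 12)
  expect_equal(bottom_depth_variation(30, 30), 0)
})

test_that("feature counts equal the brute-force oracle on random profiles", {
  for (seed in 1:60) {
    depth <- random_profile(seed)
    md <- max(depth)
    got <- detect_transit_steps(depth, md)
    expect_equal(nrow(got), oracle_transit_steps(depth, md),
                 info = sprintf("transit seed %d", seed))
    bs <- detect_bottom_steps(depth)
    ob <- oracle_bottom_steps(depth)
    expect_equal(nrow(bs$descending), length(ob$descending),
                 info = sprintf("desc seed %d", seed))
    expect_equal(nrow(bs$ascending), length(ob$ascending),
                 info = sprintf("asc seed %d", seed))
    got_w <- detect_wiggles(bs$ascending, bs$descending)
    want_w <- oracle_wiggles(
      lapply(seq_len(nrow(bs$ascending)), function(i)
        c(bs$ascending$start[i], bs$ascending$end[i])),
      lapply(seq_len(nrow(bs$descending)), function(i)
        c(bs$descending$start[i], bs$descending$end[i])))
    expect_equal(got_w, want_w, info = sprintf("wiggle seed %d", seed))
  }
})

test_that("wiggles never outnumber either bottom-step kind and survive tiny noise", {
  cfg <- tiny_sim(seed = 31, noise = 0, drift = 0, night_hours = 2)
  tr <- simulate_trip(cfg, "ind01")
  co <- forage_config()
  d0 <- process_individual(tr$depth, NULL, "ind01", co)$dives
  set.seed(99)
  noisy <- tr$depth
  noisy$depth_m <- noisy$depth_m + rnorm(nrow(noisy), 0, 0.04)
  d1 <- process_individual(noisy, NULL, "ind01", co)$dives
  deep <- d0$deep & !d0$degenerate
  expect_true(all(d0$wiggles[deep] <=
                    pmin(d0$steps_descending_bottom[deep],
                         d0$steps_ascending_bottom[deep])))
  for (col in c("steps_descent", "steps_ascent", "steps_descending_bottom",
                "steps_ascending_bottom", "wiggles"))
    expect_equal(d1[[col]][deep], d0[[col]][deep], info = col)
})
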