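# Independent brute-force oracles, deliberately written as plain loops with
# no shared code with the package internals.

# Dives: exhaustive scan for maximal runs of depth > threshold, extended one
# sample outward.
oracle_detect_dives <- function(depth, thr = 3) {
  n <- length(depth)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (depth[i] > thr) {
      j <- i
      while (j < n && depth[j + 1L] > thr) j <- j + 1L
      out[[length(out) + 1L]] <- c(max(i - 1L, 1L), min(j + 1L, n))
      i <- j + 1L
    }
    i <- i + 1L
  }
  out
}

# Transit steps: every maximal run of |1-s diffs| < rate, interior, of
# length 1..(cap-1), with mean run depth < frac * max_depth.
oracle_transit_steps <- function(depth, max_depth, rate = 0.4, cap = 8,
                                 frac = 0.6) {
  d <- diff(depth)
  slow <- abs(d) < rate
  count <- 0L
  i <- 1L
  while (i <= length(d)) {
    if (slow[i]) {
      j <- i
      while (j < length(d) && slow[j + 1L]) j <- j + 1L
      len <- j - i + 1L
      md <- mean(depth[i:(j + 1L)])
      if (i > 1L && j < length(d) && len < cap && md < frac * max_depth)
        count <- count + 1L
      i <- j
    }
    i <- i + 1L
  }
  count
}

# Bottom steps: maximal runs of signed diffs beyond the rate threshold,
# shorter than the cap. Returns intervals as (start sample, end sample).
oracle_bottom_steps <- function(depth, rate = 0.4, cap = 8) {
  d <- diff(depth)
  find <- function(flag) {
    res <- list()
    i <- 1L
    while (i <= length(d)) {
      if (flag[i]) {
        j <- i
        while (j < length(d) && flag[j + 1L]) j <- j + 1L
        if (j - i + 1L < cap) res[[length(res) + 1L]] <- c(i, j + 1L)
        i <- j
      }
      i <- i + 1L
    }
    res
  }
  list(descending = find(d > rate), ascending = find(d < -rate))
}

# Wiggles: greedy in time order over (ascending, next descending) pairs with
# end-to-start gap < gap_s.
oracle_wiggles <- function(asc, desc, gap_s = 3) {
  used <- rep(FALSE, length(desc))
  count <- 0L
  for (a in asc) {
    for (k in seq_along(desc)) {
      if (!used[k] && desc[[k]][1] >= a[2] && desc[[k]][1] - a[2] < gap_s) {
        used[k] <- TRUE
        count <- count + 1L
        break
      }
    }
  }
  count
}

# C-index: O(n^2) double loop.
oracle_cindex <- function(obs, pred) {
  num <- den <- 0
  n <- length(obs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (obs[i] == obs[j]) next
    den <- den + 1
    if (pred[i] == pred[j]) num <- num + 0.5
    else if ((obs[i] > obs[j]) == (pred[i] > pred[j])) num <- num + 1
  }
  num / den
}

# Random piecewise-constant-rate dive profile for feature fuzzing: a
# sequence of integer-duration segments with rates drawn from {0 (flat),
# steep up, steep down, gentle}, on top of a deep baseline.
random_profile <- function(seed) {
  set.seed(seed)
  n_seg <- sample(8:20, 1)
  rates <- sample(c(0, 1.1, -1.1, 0.25, -0.25), n_seg, replace = TRUE,
                  prob = c(0.35, 0.2, 0.2, 0.125, 0.125))
  durs <- sample(1:9, n_seg, replace = TRUE)
  depth <- 30
  for (k in seq_len(n_seg)) depth <- c(depth, rep(rates[k], durs[k]))
  cumsum(depth)
}
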