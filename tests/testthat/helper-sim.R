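# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, fast trip configuration: one short night per individual.
tiny_sim <- function(seed = 1, n_individuals = 1, n_nights = 1,
                     night_hours = 2, noise = 0.1, drift = 0.5, ...) {
  sim_config(n_individuals = n_individuals, n_nights = n_nights,
             night_window = c(79200, 79200 + night_hours * 3600),
             depth_noise_sd = noise,
             drift = list(amplitude_m = drift, shape = "linear"),
             seed = seed, ...)
}

# Regression table drawn from the generative Poisson mixed model with
# independent standard-normal predictors.
make_glmm_tab <- function(n, m, beta, intercept, sigma, seed,
                          p = length(beta)) {
  set.seed(seed)
  id <- sprintf("i%02d", rep(seq_len(m), length.out = n))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  b <- setNames(rnorm(m, 0, sigma), sprintf("i%02d", seq_len(m)))
  y <- rpois(n, exp(intercept + as.vector(X %*% beta) + b[id]))
  tab <- tibble::tibble(individual_id = id, pca_count = y)
  for (j in seq_len(p)) tab[[paste0("x", j)]] <- X[, j]
  attr(tab, "truth_b") <- b
  tab
}

# Hand-built trapezoidal dive: descent at v down to depth d, flat bottom,
# ascent at v back up, with optional plateau inserted during descent.
trapezoid_dive <- function(depth_max = 30, v = 1, bottom_s = 60,
                           plateau_depth = NULL, plateau_s = 5) {
  down <- seq(0, depth_max, by = v)
  if (!is.null(plateau_depth)) {
    i <- which.min(abs(down - plateau_depth))
    down <- c(down[1:i], rep(down[i], plateau_s), down[(i + 1):length(down)])
  }
  up <- rev(seq(0, depth_max, by = v))
  c(down, rep(depth_max, bottom_s), up[-1])  # drop the duplicated bottom sample
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
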