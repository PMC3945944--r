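# Internal helpers shared across modules.

# Names of the per-dive predictors used at every scale (the eleven dive-level
# covariates); super-dive scales add n_dives and pct_time_deep.
dive_predictors <- function() {
  c("max_depth", "surface_duration", "descent_rate", "ascent_rate",
    "bottom_duration", "depth_variation_bottom", "steps_descent",
    "steps_ascent", "steps_descending_bottom", "steps_ascending_bottom",
    "wiggles")
}

scale_predictors <- function(scale) {
  if (identical(scale, "dive")) dive_predictors()
  else c(dive_predictors(), "n_dives", "pct_time_deep")
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Maximal runs of TRUE in a logical vector: tibble of start/end indices
# (inclusive) and lengths.
logical_runs <- function(flag) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

# Physicists' Gauss-Hermite nodes/weights via Golub-Welsch, cached per order.
gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  stopifnot(n >= 1)
  if (n == 1L) {
    out <- list(nodes = 0, weights = sqrt(pi))
  } else {
    k <- seq_len(n - 1L)
    off <- sqrt(k / 2)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- off
    J[cbind(k + 1L, k)] <- off
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- sqrt(pi) * e$vectors[1L, ]^2
    ord <- order(x)
    out <- list(nodes = x[ord], weights = w[ord])
  }
  gh_cache[[key]] <- out
  out
}

# Derive a per-unit 32-bit seed from a base seed and an index, for
# reproducible independent streams.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483629)
}

assert_uniform_grid <- function(time, dt, what = "series") {
  d <- diff(time)
  if (length(d) && (max(abs(d - dt)) > 1e-6))
    stopf("%s is not on a uniform %g-s grid", what, dt)
  invisible(TRUE)
}
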