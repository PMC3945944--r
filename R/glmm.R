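# Poisson mixed-model fitting. The marginal likelihood (scalar Gaussian
# random intercept, adaptive Gauss-Hermite quadrature) and its analytic
# gradient live in src/agq.cpp; this file provides the user-facing fit.

#' Fit a Poisson regression with an optional individual random intercept
#'
#' Counts are modeled with a log link on the (standardized) predictors.
#' With `use_random_intercept = TRUE` the individual random intercept is
#' integrated out by adaptive Gauss-Hermite quadrature (`nodes` quadrature
#' points; the marginal likelihood is maximised by quasi-Newton iteration
#' with an analytic gradient, the random-intercept sd constrained
#' non-negative). Without it, a plain Poisson GLM is fitted (the night
#' scale, whose sample size cannot support a random effect). Standard
#' errors come from the observed information at the optimum.
#'
#' @param table A standardized `ScaleTable` tibble with `pca_count` and
#'   `individual_id`.
#' @param subset Character vector of predictor columns (possibly empty: the
#'   null model).
#' @param use_random_intercept Include the per-individual random intercept.
#' @param nodes Quadrature nodes (>= 10 recommended).
#' @param start Optional starting values (coefficients, then sigma).
#' @param se Compute standard errors (skippable during bulk enumeration;
#'   [model_average()] fills them in for candidate models).
#' @return Object of class `fs_glmm`: coefficients, `se`, `sigma_b`,
#'   `logLik`, `k` (parameter count, the random-intercept sd included),
#'   `n`, `aicc`, `converged`, `subset`.
#' @export
fit_poisson_glmm <- function(table, subset = character(),
                             use_random_intercept = TRUE, nodes = 15,
                             start = NULL, se = TRUE) {
  y <- table$pca_count
  if (any(y < 0) || any(y != round(y))) stopf("responses must be non-negative counts")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, subset, drop = FALSE]))
  if (length(subset)) {
    sds <- apply(X[, -1, drop = FALSE], 2, sd)
    if (any(!is.finite(sds) | sds == 0))
      stopf("degenerate (zero-variance) predictor column(s): %s",
            paste(subset[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  n <- length(y); p <- ncol(X)

  if (!use_random_intercept) {
    fit <- glm.fit(X, y, family = poisson())
    eta <- as.vector(X %*% fit$coefficients)
    ll <- sum(y * eta - exp(eta) - lgamma(y + 1))
    se <- sqrt(diag(chol2inv(chol(crossprod(X * sqrt(fit$weights))))))
    out <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                se = setNames(se, colnames(X)),
                sigma_b = NA_real_, logLik = ll, k = p, n = n,
                converged = fit$converged, subset = subset,
                random_intercept = FALSE)
  } else {
    id <- as.character(table$individual_id)
    ord <- order(match(id, unique(id)))
    ys <- y[ord]; Xs <- X[ord, , drop = FALSE]; ids <- id[ord]
    r <- rle(ids)
    cl_end <- cumsum(r$lengths)
    cl_start <- c(0L, cl_end[-length(cl_end)])
    m <- length(cl_end)
    # parameter-free sufficient statistics
    S <- numeric(m); U <- matrix(0, p, m)
    for (i in seq_len(m)) {
      rows <- (cl_start[i] + 1L):cl_end[i]
      S[i] <- sum(ys[rows])
      U[, i] <- colSums(ys[rows] * Xs[rows, , drop = FALSE])
    }
    lfact <- sum(lgamma(ys + 1))
    gh <- gauss_hermite(nodes)
    lw <- log(gh$weights)
    fn <- function(par) agq_nll_cpp(par, Xs, as.integer(cl_start),
                                    as.integer(cl_end), S, U, lfact,
                                    gh$nodes, lw, FALSE)$nll
    gr <- function(par) agq_nll_cpp(par, Xs, as.integer(cl_start),
                                    as.integer(cl_end), S, U, lfact,
                                    gh$nodes, lw, TRUE)$grad
    if (is.null(start)) {
      b0 <- glm.fit(X, y, family = poisson())$coefficients
      start <- c(b0, 0.3)
    }
    opt <- optim(start, fn, gr, method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), 0), upper = c(rep(Inf, p), 15),
                 control = list(maxit = 500, factr = 1e7))
    if (opt$convergence != 0) {
      # derivative-free fallback for awkward small-sample surfaces
      fn2 <- function(q) fn(c(q[seq_len(p)], abs(q[p + 1])))
      o2 <- optim(c(opt$par[seq_len(p)], max(opt$par[p + 1], 0.05)), fn2,
                  method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-10))
      if (o2$value <= opt$value + 1e-8)
        opt <- list(par = c(o2$par[seq_len(p)], abs(o2$par[p + 1])),
                    value = o2$value, convergence = o2$convergence)
    }
    beta <- setNames(unname(opt$par[1:p]), colnames(X))
    sigma <- unname(opt$par[p + 1])
    ses <- if (se) agq_se(opt$par, fn, gr, p) else rep(NA_real_, p)
    out <- list(coefficients = beta, se = setNames(ses, colnames(X)),
                sigma_b = sigma, logLik = -opt$value, k = p + 1L, n = n,
                converged = opt$convergence == 0, subset = subset,
                random_intercept = TRUE)
  }
  out$aicc <- aicc(out$logLik, out$k, out$n)
  class(out) <- "fs_glmm"
  out
}

# Posterior modes of the per-individual random intercepts given fixed-effect
# predictions mu0 = exp(eta) and random-intercept sd sigma.
estimate_random_intercepts <- function(y, mu0, id, sigma) {
  uid <- unique(id)
  b <- setNames(numeric(length(uid)), uid)
  if (!is.finite(sigma) || sigma <= 0) return(b)
  for (u in uid) {
    rows <- id == u
    S <- sum(y[rows]); T <- sum(mu0[rows])
    bb <- 0
    for (it in 1:100) {
      g1 <- S - T * exp(bb) - bb / sigma^2
      g2 <- -T * exp(bb) - 1 / sigma^2
      step <- max(-5, min(5, g1 / g2))
      bb <- bb - step
      if (abs(step) < 1e-10) break
    }
    b[u] <- bb
  }
  b
}

# Standard errors from the observed information; at the sigma = 0 boundary
# only the fixed-effect block is invertible.
agq_se <- function(par, fn, gr, p) {
  se <- rep(NA_real_, p)
  H <- tryCatch(optimHess(par, fn, gr), error = function(e) NULL)
  cov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(cov) && all(diag(cov)[1:p] > 0)) {
    se <- sqrt(diag(cov)[1:p])
  } else if (!is.null(H)) {
    covb <- tryCatch(solve(H[1:p, 1:p, drop = FALSE]), error = function(e) NULL)
    if (!is.null(covb) && all(diag(covb) > 0)) se <- sqrt(diag(covb))
  }
  se
}

# Recompute standard errors for a fit produced with se = FALSE.
refresh_se <- function(fit, table, nodes) {
  if (!anyNA(fit$se)) return(fit)
  refit <- fit_poisson_glmm(table, fit$subset, fit$random_intercept, nodes,
                            start = c(fit$coefficients,
                                      if (fit$random_intercept) fit$sigma_b),
                            se = TRUE)
  fit$se <- refit$se
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`; converges to the AIC
#' as `n` grows.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return Numeric AICc.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0)
    stopf("AICc undefined: n - k - 1 <= 0 (model too rich for %d rows)", n)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.fs_glmm <- function(x, ...) {
  cat(sprintf("<fs_glmm> %s | logLik %.2f, AICc %.2f, k %d, n %d\n",
              if (length(x$subset)) paste(x$subset, collapse = " + ")
              else "(null model)",
              x$logLik, x$aicc, x$k, x$n))
  if (x$random_intercept)
    cat(sprintf("  random-intercept sd: %.3f\n", x$sigma_b))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @rdname fit_poisson_glmm
#' @param x,object An `fs_glmm` object.
#' @param ... Unused.
#' @export
tidy.fs_glmm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se))
}

#' @rdname fit_poisson_glmm
#' @export
glance.fs_glmm <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AICc = x$aicc, k = x$k, n = x$n,
                 sigma_b = x$sigma_b, converged = x$converged)
}

#' @rdname fit_poisson_glmm
#' @param newdata Standardized table with the model's predictor columns.
#' @param population_level Predict with the random intercept at zero (the
#'   only option for unseen individuals).
#' @export
predict.fs_glmm <- function(object, newdata, population_level = TRUE, ...) {
  miss <- setdiff(object$subset, names(newdata))
  if (length(miss))
    stopf("newdata lacks predictor column(s): %s", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(newdata[, object$subset, drop = FALSE]))
  exp(as.vector(X %*% object$coefficients))
}
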