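# All-subsets enumeration, AICc ranking, Akaike weights and full
# (zero-substitution) model averaging of the 0.95 cumulative-weight
# candidate set.

#' Enumerate and rank all predictor subsets
#'
#' Fits every subset of the candidate predictors of size 0 to `max_vars`
#' and ranks the fits by AICc. The cap enforces a minimum of 10 rows per
#' explanatory variable; non-converged fits are dropped from the ranking
#' with a warning.
#'
#' @param table Standardized `ScaleTable` tibble.
#' @param candidates Candidate predictor columns; defaults to every
#'   predictor of the table's scale that is present.
#' @param max_vars Cap on subset size.
#' @param use_random_intercept Mixed model (default) or plain GLM.
#' @param nodes Quadrature nodes.
#' @return Object of class `fs_ranked`: tibble `models` (`model_id`,
#'   `terms`, `k`, `logLik`, `AICc`, `delta`, `weight`, ranked), list
#'   `fits` aligned with `models`, plus the table and settings.
#' @export
enumerate_and_rank <- function(table, candidates = NULL, max_vars = NULL,
                               use_random_intercept = TRUE, nodes = 15) {
  candidates <- candidates %||%
    intersect(scale_predictors(attr(table, "scale") %||% "x"), names(table))
  max_vars <- max_vars %||% length(candidates)
  if (max_vars > length(candidates))
    stopf("max_vars (%d) exceeds the %d candidates", max_vars, length(candidates))
  if (nrow(table) < 10 * max_vars)
    stopf(paste("cap of %d predictors violates the minimum of 10 rows per",
                "variable (only %d rows)"), max_vars, nrow(table))

  subsets <- unlist(lapply(0:max_vars, function(k)
    combn(candidates, k, simplify = FALSE)), recursive = FALSE)

  # warm start every fit from the largest model's coefficients
  full <- fit_poisson_glmm(table, candidates[seq_len(min(max_vars,
                                                         length(candidates)))],
                           use_random_intercept, nodes)
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    st <- if (use_random_intercept && full$converged) {
      cf <- full$coefficients[c("(Intercept)", s)]
      cf[is.na(cf)] <- 0
      c(cf, max(full$sigma_b, 0.05))
    } else NULL
    fits[[i]] <- fit_poisson_glmm(table, s, use_random_intercept, nodes,
                                  start = st, se = FALSE)
  }

  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (all(!conv))
    stopf("no model in the enumeration converged; inspect the table")
  if (any(!conv))
    warning(sprintf("%d of %d models did not converge and were dropped",
                    sum(!conv), length(fits)), call. = FALSE)
  fits <- fits[conv]
  subsets <- subsets[conv]
  models <- tibble::tibble(
    model_id = seq_along(fits),
    terms = subsets,
    k = vapply(fits, `[[`, 0L, "k"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AICc = vapply(fits, `[[`, 0, "aicc"))
  ord <- order(models$AICc)
  models <- models[ord, ]
  fits <- fits[ord]
  models$delta <- models$AICc - models$AICc[1]
  models$weight <- aicc_weights(models$AICc)
  structure(list(models = models, fits = fits, table = table,
                 candidates = candidates, max_vars = max_vars,
                 use_random_intercept = use_random_intercept, nodes = nodes),
            class = "fs_ranked")
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`: the relative likelihood of each model in
#' the enumerated set. Accepts a numeric AICc vector or an `fs_ranked`.
#'
#' @param fits Numeric AICc values, or an `fs_ranked` object.
#' @return Numeric weights summing to 1.
#' @export
aicc_weights <- function(fits) {
  a <- if (inherits(fits, "fs_ranked")) fits$models$AICc else as.numeric(fits)
  if (any(!is.finite(a))) stopf("AICc values must be finite")
  d <- a - min(a)
  w <- exp(-d / 2)
  w / sum(w)
}

#' @export
print.fs_ranked <- function(x, ...) {
  cat(sprintf("<fs_ranked> %d models over %d candidates (cap %d)\n",
              nrow(x$models), length(x$candidates), x$max_vars))
  top <- utils::head(x$models, 5)
  top$terms <- vapply(top$terms, function(s)
    if (length(s)) paste(s, collapse = "+") else "(null)", "")
  print(as.data.frame(top), digits = 4)
  invisible(x)
}

#' Average the candidate model set
#'
#' The candidate set is the smallest weight-ordered prefix of the ranking
#' whose cumulative Akaike weight strictly exceeds `threshold`; its weights
#' are re-normalized. Coefficients are averaged with zero substituted where
#' a predictor is absent from a model (so rarely selected predictors shrink
#' toward zero), each predictor's importance is the summed weight of the
#' candidate models containing it, and unconditional standard errors
#' combine within-model variance and between-model coefficient spread.
#'
#' @param ranked An `fs_ranked` object.
#' @param threshold Cumulative-weight threshold for the candidate set.
#' @return Object of class `fs_avg`: tibble `coefficients` (`term`,
#'   `importance`, `estimate`, `std_error`), tibble `candidates`
#'   (per-model weights), `scale`, `threshold`.
#' @export
model_average <- function(ranked, threshold = 0.95) {
  m <- ranked$models
  ncand <- which(cumsum(m$weight) > threshold)[1]
  if (is.na(ncand)) ncand <- nrow(m)
  w <- m$weight[seq_len(ncand)]
  w <- w / sum(w)
  fits <- lapply(ranked$fits[seq_len(ncand)], refresh_se,
                 table = ranked$table, nodes = ranked$nodes)

  terms <- c("(Intercept)", ranked$candidates)
  est <- se2 <- imp <- setNames(numeric(length(terms)), terms)
  B <- S <- matrix(0, ncand, length(terms), dimnames = list(NULL, terms))
  for (i in seq_len(ncand)) {
    f <- fits[[i]]
    B[i, names(f$coefficients)] <- f$coefficients
    S[i, names(f$se)] <- ifelse(is.na(f$se), 0, f$se)
    imp[c("(Intercept)", f$subset)] <- imp[c("(Intercept)", f$subset)] + w[i]
  }
  est <- colSums(w * B)
  # Burnham & Anderson unconditional SE (zero substitution for absent terms)
  se <- sqrt(colSums(w * (S^2 + sweep(B, 2, est)^2)))
  imp <- pmin(1, pmax(0, imp))   # guard against rounding past the bounds

  cand <- m[seq_len(ncand), c("model_id", "terms", "k", "logLik", "AICc",
                              "delta", "weight")]
  cand$weight_renorm <- w

  # weight-averaged random-intercept sd and per-individual posterior modes,
  # for conditional (training-individual) fitted values
  sig <- vapply(fits, function(f)
    if (isTRUE(f$random_intercept)) f$sigma_b else 0, numeric(1))
  sigma_b <- sum(w * sig)
  ranef <- NULL
  if (sigma_b > 0 && "individual_id" %in% names(ranked$table)) {
    est <- setNames(est, terms)
    Xf <- cbind(1, as.matrix(ranked$table[, ranked$candidates, drop = FALSE]))
    mu0 <- exp(as.vector(Xf %*% c(est[1], est[ranked$candidates])))
    ranef <- estimate_random_intercepts(ranked$table$pca_count, mu0,
                                        as.character(ranked$table$individual_id),
                                        sigma_b)
  }
  structure(list(
    coefficients = tibble::tibble(term = terms, importance = unname(imp),
                                  estimate = unname(est),
                                  std_error = unname(se)),
    candidates = cand,
    cumulative_weight = sum(m$weight[seq_len(ncand)]),
    scale = attr(ranked$table, "scale"),
    threshold = threshold,
    sigma_b = sigma_b,
    ranef = ranef,
    use_random_intercept = ranked$use_random_intercept),
    class = "fs_avg")
}

#' @export
print.fs_avg <- function(x, ...) {
  cat(sprintf("<fs_avg> %s scale | %d candidate models (cum. weight %.3f)\n",
              x$scale %||% "?", nrow(x$candidates), x$cumulative_weight))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @rdname model_average
#' @param x,object An `fs_avg` object.
#' @param ... Unused.
#' @export
tidy.fs_avg <- function(x, ...) {
  dplyr::rename(x$coefficients, std.error = "std_error")
}

#' @rdname model_average
#' @export
glance.fs_avg <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x$candidates),
                 cumulative_weight = x$cumulative_weight,
                 scale = x$scale %||% NA_character_)
}

#' Predict expected counts from an averaged model
#'
#' `mu = exp(x' beta_bar)` at the population level: the random intercept is
#' set to zero, the only choice for individuals absent from the training
#' set. With `population_level = FALSE`, the posterior-mode random
#' intercepts of training individuals are added (fitted values on the
#' training set; unseen individuals still get zero).
#'
#' @param object An `fs_avg`.
#' @param newdata Table standardized with the training statistics.
#' @param population_level Set the random intercept to zero.
#' @param ... Unused.
#' @return Numeric vector of expected counts.
#' @export
predict.fs_avg <- function(object, newdata, population_level = TRUE, ...) {
  cf <- object$coefficients
  terms <- cf$term[cf$term != "(Intercept)"]
  miss <- setdiff(terms, names(newdata))
  if (length(miss))
    stopf("newdata lacks predictor column(s): %s", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(newdata[, terms, drop = FALSE]))
  beta <- cf$estimate[match(c("(Intercept)", terms), cf$term)]
  eta <- as.vector(X %*% beta)
  if (!population_level && !is.null(object$ranef) &&
      "individual_id" %in% names(newdata)) {
    b <- object$ranef[as.character(newdata$individual_id)]
    b[is.na(b)] <- 0
    eta <- eta + b
  }
  exp(eta)
}
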