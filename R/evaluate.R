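#' Concordance index between observed and predicted counts
#'
#' Over all pairs with different observed responses, a pair is concordant
#' when the prediction ordering matches the observation ordering; tied
#' predictions score 0.5. The C-index is the concordant score divided by
#' the number of usable pairs and ranges from 0.5 (chance) to 1 (perfect
#' ordering); values below 0.5 indicate anti-concordant predictions.
#'
#' @param observed Observed counts (at least two distinct values).
#' @param predicted Predicted expected counts, same length.
#' @return Numeric in \[0, 1\].
#' @export
concordance_index <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stopf("observed and predicted must have the same length")
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(unique(o)) < 2)
    stopf("C-index undefined: all observed responses are equal")
  n <- length(o)
  score <- 0; usable <- 0
  chunk <- 512L
  for (a in seq(1L, n - 1L, by = chunk)) {
    ia <- a:min(a + chunk - 1L, n - 1L)
    for (b in seq(a, n, by = chunk)) {
      ib <- b:min(b + chunk - 1L, n)
      do <- outer(o[ia], o[ib], `-`)
      dp <- outer(p[ia], p[ib], `-`)
      if (a == b) {
        keep <- upper.tri(do)
        do <- do[keep]; dp <- dp[keep]
      }
      use <- do != 0
      usable <- usable + sum(use)
      s <- sign(do[use]) * sign(dp[use])
      score <- score + sum(s > 0) + 0.5 * sum(dp[use] == 0)
    }
  }
  if (usable == 0) stopf("C-index undefined: no usable pairs")
  score / usable
}

#' Classify predictive performance from a C-index
#'
#' Bands are half-open with boundaries assigned to the lower band:
#' (0.9, 1\] excellent, (0.8, 0.9\] good, (0.7, 0.8\] reasonable,
#' (0.6, 0.7\] poor, \[0.5, 0.6\] unsuccessful; values below 0.5 are
#' flagged anti-concordant.
#'
#' @param c_index Numeric C-index values.
#' @return Character labels.
#' @export
classify_performance <- function(c_index) {
  vapply(c_index, function(ci) {
    if (!is.finite(ci)) return(NA_character_)
    if (ci < 0.5) return("anti-concordant")
    if (ci > 0.9) "excellent"
    else if (ci > 0.8) "good"
    else if (ci > 0.7) "reasonable"
    else if (ci > 0.6) "poor"
    else "unsuccessful"
  }, character(1))
}

#' Leave-one-individual-out cross-validation
#'
#' Each individual is held out in turn; the full selection-and-averaging
#' procedure is re-run on the remaining individuals (standardization
#' statistics computed from the training set only) and the held-out
#' individual is predicted at the population level (random intercept zero).
#' Predictions are pooled across folds for the headline C-index;
#' per-individual C-indices are reported as diagnostics to surface
#' outlying animals. A full-data C-index (model fitted and evaluated on
#' all individuals) is computed for comparison.
#'
#' @param table An unstandardized `ScaleTable` tibble with `individual_id`
#'   and `pca_count`.
#' @param candidates Candidate predictors (default: the scale's set).
#' @param max_vars Subset-size cap.
#' @param use_random_intercept Mixed model or plain GLM.
#' @param threshold Candidate-set cumulative-weight threshold.
#' @param nodes Quadrature nodes.
#' @return Object of class `fs_cv`: `predictions` (tibble `individual_id`,
#'   `observed`, `predicted`), `folds` (per-individual n and C-index),
#'   `c_index_pooled`, `c_index_mean_fold`, `c_index_full`, `label`.
#' @export
loocv <- function(table, candidates = NULL, max_vars = NULL,
                  use_random_intercept = TRUE, threshold = 0.95, nodes = 15) {
  ids <- unique(table$individual_id)
  if (length(ids) < 3) stopf("leave-one-out validation needs >= 3 individuals")
  candidates <- candidates %||%
    intersect(scale_predictors(attr(table, "scale") %||% "x"), names(table))

  preds <- list()
  for (id in ids) {
    train <- table[table$individual_id != id, ]
    test <- table[table$individual_id == id, ]
    # drop fold-degenerate predictors (zero variance in the training set)
    sds <- vapply(train[candidates], sd, numeric(1))
    cand <- candidates[is.finite(sds) & sds > 0]
    if (length(cand) < length(candidates))
      message(sprintf("fold %s: dropped zero-variance predictor(s): %s", id,
                      paste(setdiff(candidates, cand), collapse = ", ")))
    cap <- min(max_vars %||% length(cand), length(cand),
               floor(nrow(train) / 10))
    tr_std <- standardize(train, cols = cand)
    te_std <- standardize(test, stats = attr(tr_std, "std_stats"))
    rk <- enumerate_and_rank(tr_std, cand, cap, use_random_intercept, nodes)
    avg <- model_average(rk, threshold)
    preds[[id]] <- tibble::tibble(
      individual_id = id,
      observed = test$pca_count,
      predicted = predict(avg, te_std))
  }
  predictions <- dplyr::bind_rows(preds)

  folds <- predictions |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      c_index = tryCatch(concordance_index(.data$observed, .data$predicted),
                         error = function(e) NA_real_),
      .groups = "drop")

  # full-data reference model
  sds <- vapply(table[candidates], sd, numeric(1))
  cand <- candidates[is.finite(sds) & sds > 0]
  cap <- min(max_vars %||% length(cand), length(cand), floor(nrow(table) / 10))
  std <- standardize(table, cols = cand)
  full_avg <- model_average(
    enumerate_and_rank(std, cand, cap, use_random_intercept, nodes), threshold)
  c_full <- concordance_index(table$pca_count,
                              predict(full_avg, std, population_level = FALSE))

  c_pool <- concordance_index(predictions$observed, predictions$predicted)
  structure(list(predictions = predictions, folds = folds,
                 c_index_pooled = c_pool,
                 c_index_mean_fold = mean(folds$c_index, na.rm = TRUE),
                 c_index_full = c_full,
                 full_model = full_avg,
                 label = classify_performance(c_pool)),
            class = "fs_cv")
}

#' @export
print.fs_cv <- function(x, ...) {
  cat(sprintf(
    "<fs_cv> %d folds | pooled C = %.3f (%s), mean fold C = %.3f, full-data C = %.3f\n",
    nrow(x$folds), x$c_index_pooled, x$label, x$c_index_mean_fold,
    x$c_index_full))
  invisible(x)
}

#' @rdname loocv
#' @param x,object An `fs_cv` object.
#' @param ... Unused.
#' @export
tidy.fs_cv <- function(x, ...) {
  dplyr::mutate(x$folds, label = classify_performance(.data$c_index))
}

#' @rdname loocv
#' @export
glance.fs_cv <- function(x, ...) {
  tibble::tibble(c_index_pooled = x$c_index_pooled,
                 c_index_mean_fold = x$c_index_mean_fold,
                 c_index_full = x$c_index_full,
                 n_folds = nrow(x$folds),
                 label = x$label)
}
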