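std_tab <- function(n, m, beta, intercept, sigma, seed) {
  tab <- make_glmm_tab(n, m, beta, intercept, sigma, seed)
  standardize(tab, cols = paste0("x", seq_along(beta)))
}

test_that("the enumeration covers every subset and ranks by AICc", {
  tab <- std_tab(200, 5, c(0.4, 0.3, 0, 0), 0.5, 0.3, seed = 1)
  rk <- enumerate_and_rank(tab, paste0("x", 1:4), 4)
  expect_equal(nrow(rk$models), 16)            # 2^4
  expect_equal(rk$models$AICc, sort(rk$models$AICc))
  expect_equal(sum(rk$models$weight), 1, tolerance = 1e-9)
  # subset-size counts follow the binomial sums
  sizes <- lengths(rk$models$terms)
  expect_equal(as.integer(table(sizes)), choose(4, 0:4))
  # a cap produces the truncated binomial sum
  rk2 <- enumerate_and_rank(tab, paste0("x", 1:4), 2)
  expect_equal(nrow(rk2$models), sum(choose(4, 0:2)))
  # the 10-rows-per-variable guard
  expect_error(enumerate_and_rank(tab[1:30, ], paste0("x", 1:4), 4),
               "10 rows")
})

test_that("Akaike weights follow the exponential rule", {
  expect_equal(aicc_weights(c(100, 100)), c(0.5, 0.5))
  w <- aicc_weights(c(100, 102))
  expect_equal(w, c(0.731, 0.269), tolerance = 1e-3)
  expect_error(aicc_weights(c(1, Inf)), "finite")
})

test_that("ranking is invariant to predictor column order", {
  tab <- std_tab(200, 5, c(0.4, 0.3, 0.1), 0.5, 0.3, seed = 2)
  rk1 <- enumerate_and_rank(tab, c("x1", "x2", "x3"), 3)
  rk2 <- enumerate_and_rank(tab, c("x3", "x1", "x2"), 3)
  key <- function(rk) vapply(rk$models$terms,
                             function(s) paste(sort(s), collapse = "+"), "")
  expect_equal(key(rk1), key(rk2))
  expect_equal(rk1$models$AICc, rk2$models$AICc, tolerance = 1e-5)
})

test_that("model averaging implements zero-substitution and importance", {
  tab <- std_tab(400, 5, c(0.5, 0.3, 0, 0, 0), 1, 0.3, seed = 3)
  rk <- enumerate_and_rank(tab, paste0("x", 1:5), 5)
  avg <- model_average(rk, threshold = 0.95)
  expect_gt(avg$cumulative_weight, 0.95)
  cf <- avg$coefficients
  # importance equals a brute-force recomputation from the candidate list
  w <- avg$candidates$weight_renorm
  for (term in paste0("x", 1:5)) {
    imp <- sum(w[vapply(avg$candidates$terms, function(s) term %in% s, TRUE)])
    expect_equal(cf$importance[cf$term == term], imp, tolerance = 1e-12)
  }
  # averaged coefficient equals the weighted sum with zeros substituted
  for (term in paste0("x", 1:5)) {
    b <- vapply(seq_along(w), function(i) {
      f <- rk$fits[[i]]
      if (term %in% f$subset) unname(f$coefficients[term]) else 0
    }, numeric(1))
    expect_equal(cf$estimate[cf$term == term], sum(w * b), tolerance = 1e-12)
  }
  # a weighted arithmetic sanity case from two hand-made models
  expect_equal(0.6 * 1.0 + 0.4 * 0, 0.6)
})

test_that("a single dominant model is returned unchanged by averaging", {
  # one strong predictor against the null model only: its model's Akaike
  # weight is essentially 1, so the average must equal that model
  tab <- std_tab(1500, 5, c(1.2, 0, 0), 0.5, 0.2, seed = 4)
  rk <- enumerate_and_rank(tab, "x1", 1)
  expect_gt(rk$models$weight[1], 0.95)
  avg <- model_average(rk)
  expect_equal(nrow(avg$candidates), 1)
  best <- rk$fits[[1]]
  expect_equal(avg$coefficients$estimate[avg$coefficients$term == "x1"],
               unname(best$coefficients["x1"]), tolerance = 1e-10)
  expect_equal(avg$coefficients$importance[avg$coefficients$term == "x1"], 1)
})

test_that("averaged predictions follow the log link", {
  tab <- std_tab(300, 5, c(0.4, 0.3), 0.7, 0.3, seed = 5)
  avg <- model_average(enumerate_and_rank(tab, c("x1", "x2"), 2))
  zero_row <- tab[1, ]
  zero_row$x1 <- 0; zero_row$x2 <- 0
  mu0 <- predict(avg, zero_row)
  b0 <- avg$coefficients$estimate[avg$coefficients$term == "(Intercept)"]
  expect_equal(mu0, exp(b0), tolerance = 1e-12)
  # doubling a predictor shifts the log prediction by beta * dx
  one_row <- zero_row; one_row$x1 <- 2
  b1 <- avg$coefficients$estimate[avg$coefficients$term == "x1"]
  expect_equal(log(predict(avg, one_row)) - log(mu0), 2 * b1,
               tolerance = 1e-12)
  expect_error(predict(avg, dplyr::select(tab, -"x1")), "x1")
})

test_that("true predictors earn high importance; nulls stay low", {
  hit <- 0
  null_imp <- c()
  for (r in 1:5) {
    tab <- std_tab(2000, 10, c(0.3, 0.3, 0.3, rep(0, 8)), 1, 0.5,
                   seed = 700 + r)
    avg <- model_average(enumerate_and_rank(tab, paste0("x", 1:11), 4))
    imp <- setNames(avg$coefficients$importance, avg$coefficients$term)
    hit <- hit + all(imp[c("x1", "x2", "x3")] > 0.9)
    null_imp <- c(null_imp, imp[paste0("x", 4:11)])
  }
  expect_gte(hit, 4)
  expect_lt(median(null_imp), 0.5)
})
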