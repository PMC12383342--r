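make_feature_tbl <- function(m, ids = NULL) {
  out <- tibble::as_tibble(as.data.frame(m))
  if (!is.null(ids)) out <- dplyr::mutate(out, patient_id = ids, .before = 1)
  out
}

test_that("ICC(2,1) is 1 for identical tables and near 0 for noise", {
  set.seed(1)
  n <- 30
  a <- matrix(rnorm(n * 50), n, dimnames = list(NULL, paste0("f", 1:50)))
  ta <- make_feature_tbl(a)
  res <- icc_filter(ta, ta)
  expect_true(all(abs(res$icc - 1) < 1e-12))
  expect_true(all(res$kept))

  b <- matrix(rnorm(n * 50), n, dimnames = list(NULL, paste0("f", 1:50)))
  res2 <- icc_filter(ta, make_feature_tbl(b))
  expect_lt(abs(mean(res2$icc)), 0.15)
  expect_false(any(res2$kept))
})

test_that("ICC matches the two-way ANOVA definition on a worked example", {
  # correlated rater pair with a systematic offset
  set.seed(7)
  truth <- rnorm(40, 0, 2)
  a <- truth + rnorm(40, 0, 0.5)
  b <- truth + 0.3 + rnorm(40, 0, 0.5)
  res <- icc_filter(make_feature_tbl(cbind(f = a)),
                    make_feature_tbl(cbind(f = b)),
                    selection_config(icc_threshold = 0.5))
  # independent oracle: mean squares from a two-way fixed-effects fit
  x <- cbind(a, b); n <- 40; k <- 2
  msr <- k * sum((rowMeans(x) - mean(x))^2) / (n - 1)
  msc <- n * sum((colMeans(x) - mean(x))^2) / (k - 1)
  mse <- summary(stats::lm(c(a, b) ~ factor(rep(1:40, 2)) +
                             factor(rep(1:2, each = 40))))$sigma^2
  icc_ref <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_ref, tolerance = 1e-8)
})

test_that("z-scoring uses training statistics with population SD", {
  tr <- make_feature_tbl(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  te <- make_feature_tbl(cbind(a = c(2, 4), b = c(20, 30)))
  z <- zscore_fit_apply(tr, te)
  expect_equal(z$train$a, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_lt(abs(mean(z$train$b)), 1e-10)
  expect_equal(sqrt(mean(z$train$b^2)), 1, tolerance = 1e-10)
  # affine map: the test shift survives in standardized units
  expect_equal(z$others[[1]]$a, (c(2, 4) - 2) / sqrt(2 / 3),
               tolerance = 1e-10)
  expect_warning(zscore_fit_apply(make_feature_tbl(cbind(c0 = rep(5, 3)))),
                 "zero-SD")
})

test_that("the t-test screen keeps separations and controls type-I error", {
  set.seed(3)
  labels <- rep(c(0, 1), each = 100)
  strong <- labels + rnorm(200, 0, 0.05)
  tb <- make_feature_tbl(cbind(strong = strong))
  res <- ttest_filter(tb, labels)
  expect_lt(res$p_value[1], 1e-6)
  expect_true(res$kept[1])

  # null features: rejection rate 5% +/- 2% over 2000 features at n=200
  nullm <- matrix(rnorm(200 * 2000), 200,
                  dimnames = list(NULL, paste0("n", 1:2000)))
  resn <- ttest_filter(make_feature_tbl(nullm), labels)
  expect_lt(abs(mean(resn$kept) - 0.05), 0.02)
  # Welch p-values agree with stats::t.test
  ref <- t.test(nullm[labels == 1, 7], nullm[labels == 0, 7])$p.value
  expect_equal(unname(resn$p_value[7]), ref, tolerance = 1e-10)
  expect_error(ttest_filter(tb, rep(1, 200)), "class")
})

test_that("greedy correlation pruning removes the most redundant feature", {
  set.seed(5)
  n <- 200
  base <- rnorm(n)
  a <- base + rnorm(n, 0, 0.1)                # correlated with b and c
  b <- base + rnorm(n, 0, 0.1)
  c0 <- rnorm(n)
  tb <- make_feature_tbl(cbind(a = a, b = b, c = c0))
  kept <- correlation_prune(tb, selection_config(corr_threshold = 0.9))
  expect_length(kept, 2L)
  expect_true("c" %in% kept)

  # duplicated column: exactly one of the pair is dropped
  tb2 <- make_feature_tbl(cbind(x = base, y = base, z = c0))
  kept2 <- correlation_prune(tb2)
  expect_length(kept2, 2L)
  expect_true("z" %in% kept2)

  # orthogonal columns all survive
  tb3 <- make_feature_tbl(matrix(rnorm(n * 4), n,
                                 dimnames = list(NULL, paste0("o", 1:4))))
  expect_length(correlation_prune(tb3), 4L)

  # partner-count rule: A correlates with both B and C, which are mutually
  # independent, so A has two over-threshold partners and is removed. Note
  # cor(A,B) = cor(A,C) = r with cor(B,C) = 0 forces r <= 1/sqrt(2), so
  # the rule is exercised at a feasible threshold.
  u <- scale(rnorm(n))[, 1]; w <- scale(rnorm(n))[, 1]
  w <- scale(w - u * sum(u * w) / sum(u^2))[, 1]   # exactly orthogonal
  tb4 <- make_feature_tbl(cbind(A = (u + w) / sqrt(2), B = u, C = w))
  kept4 <- correlation_prune(tb4, selection_config(corr_threshold = 0.65))
  expect_setequal(kept4, c("B", "C"))
})

test_that("LASSO shrinks fully at large lambda and recovers planted signal", {
  set.seed(11)
  n <- 400
  x <- matrix(rnorm(n * 50), n, dimnames = list(NULL, paste0("f", 1:50)))
  y <- rbinom(n, 1, plogis(x[, 1] - x[, 2]))
  tb <- make_feature_tbl(x)
  big <- lasso_select(tb, y, lambda = c(10, 5))
  expect_length(big$selected, 0L)

  # unpenalized limit approaches OLS
  small <- glmnet::glmnet(x[, 1:5], y, lambda = 0)
  ols <- lm(y ~ x[, 1:5])
  expect_equal(as.numeric(coef(small))[-1], unname(coef(ols))[-1],
               tolerance = 1e-3)

  # a strongly planted predictor is always selected
  sel1 <- lasso_select(tb, y, selection_config(seed = 4))
  expect_true(all(c("f1", "f2") %in% sel1$selected))
})

test_that("the cascade is nested and ignores test-set statistics", {
  set.seed(17)
  n <- 120
  x <- matrix(rnorm(n * 40), n, dimnames = list(NULL, paste0("f", 1:40)))
  x[, 2] <- x[, 1] + rnorm(n, 0, 0.05)   # a redundant pair
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 3]))
  tr <- make_feature_tbl(x)
  te <- make_feature_tbl(matrix(rnorm(40 * 40), 40,
                                dimnames = list(NULL, paste0("f", 1:40))))
  rep1 <- select_features(tr, y, selection_config(seed = 2), test = te)
  st <- rep1$stages
  expect_true(all(st$zscore %in% st$input))
  expect_true(all(st$ttest %in% st$zscore))
  expect_true(all(st$correlation %in% st$ttest))
  expect_true(all(st$lasso %in% st$correlation))
  # replacing the test set by pure noise must not change the selection
  te2 <- make_feature_tbl(matrix(rnorm(40 * 40, 100, 50), 40,
                                 dimnames = list(NULL, paste0("f", 1:40))))
  rep2 <- select_features(tr, y, selection_config(seed = 2), test = te2)
  expect_identical(rep1$stages, rep2$stages)
  # ICC stage engages when a retest table is supplied: the first 10
  # features get rater noise large enough to fail the 0.85 threshold
  noise <- cbind(matrix(rnorm(n * 10, 0, 2), n),
                 matrix(rnorm(n * 30, 0, 0.05), n))
  retest <- make_feature_tbl(x + noise)
  rep3 <- select_features(tr, y, selection_config(seed = 2), retest = retest)
  expect_lt(length(rep3$stages$icc), length(rep3$stages$input))
  expect_identical(tidy(rep3)$stage[1:2], c("input", "icc"))
})
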