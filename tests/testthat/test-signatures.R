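test_that("univariate screening reproduces the 2x2 cross-product odds ratio", {
  # exposure/outcome counts [[30,10],[10,30]] -> OR 9
  x <- c(rep(1, 40), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  res <- univariate_screen(tibble::tibble(exposure = x), y)
  expect_equal(res$odds_ratio[1], 9, tolerance = 0.01)
  expect_true(res$significant[1])
  expect_true(res$ci_low[1] > 1)
})

test_that("null covariates stay near OR 1 with covering intervals", {
  set.seed(21)
  n <- 1000
  y <- rbinom(n, 1, 0.4)
  x <- rnorm(n)
  res <- univariate_screen(tibble::tibble(noise = x), y)
  expect_gt(res$odds_ratio[1], 0.8)
  expect_lt(res$odds_ratio[1], 1.25)
  expect_true(res$ci_low[1] < 1 && res$ci_high[1] > 1)
})

test_that("complete separation is flagged with a penalized fallback", {
  y <- rep(c(0, 1), each = 20)
  x <- y * 10 + seq(0, 0.1, length.out = 40)
  res <- suppressWarnings(univariate_screen(tibble::tibble(sep = x), y))
  expect_true(res$separation[1])
  expect_true(is.finite(res$estimate[1]))
})

test_that("multivariate fits recover known coefficients", {
  set.seed(5)
  n <- 2000
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  eta <- 0.8 * d$a - 0.6 * d$b + 0.4 * d$c
  y <- rbinom(n, 1, plogis(eta))
  mv <- multivariate_fit(d, y, c("a", "b", "c"))
  est <- mv$table$estimate
  expect_lt(abs(est[1] - 0.8) / 0.8, 0.15)
  expect_lt(abs(est[2] + 0.6) / 0.6, 0.15)
  expect_lt(abs(est[3] - 0.4) / 0.4, 0.15)
  expect_setequal(mv$retained, c("a", "b", "c"))
  # adding pure noise leaves other coefficients within one SE
  d2 <- dplyr::mutate(d, noise = rnorm(n))
  mv2 <- multivariate_fit(d2, y, c("a", "b", "c", "noise"))
  se <- summary(mv$fit)$coefficients[-1, 2]
  expect_true(all(abs(mv2$table$estimate[1:3] - est) < se))
  # no-candidate edge case degrades gracefully
  mv0 <- multivariate_fit(d, y, character(0))
  expect_length(mv0$retained, 0L)
})

test_that("the zoo separates separable data and stays at chance under nulls", {
  set.seed(31)
  n <- 160
  y <- rep(c(0, 1), each = n / 2)
  x <- tibble::tibble(f1 = y + rnorm(n, 0, 0.1),
                      f2 = rnorm(n), f3 = rnorm(n))
  sig <- train_signature(x, y, algorithms = zoo_algorithms(),
                         folds = 5, seed = 3)
  for (algo in zoo_algorithms()) {
    expect_gte(sig$fits[[algo]]$cv_auc, 0.99)
  }
  expect_s3_class(tidy(sig), "tbl_df")
  expect_equal(glance(sig)$n_features, 3L)
  # grid-search argmax contract
  rep_best <- dplyr::summarise(
    dplyr::group_by(sig$cv_report, algorithm),
    best = max(cv_auc))
  for (algo in names(sig$fits)) {
    expect_equal(sig$fits[[algo]]$cv_auc,
                 rep_best$best[rep_best$algorithm == algo])
  }

  # permuted labels: CV AUC near chance at n=400
  set.seed(32)
  n2 <- 400
  xn <- tibble::tibble(g1 = rnorm(n2), g2 = rnorm(n2), g3 = rnorm(n2))
  yn <- sample(rep(c(0, 1), each = n2 / 2))
  sign <- train_signature(xn, yn, algorithms = "lr", folds = 5, seed = 4)
  expect_gt(sign$fits$lr$cv_auc, 0.4)
  expect_lt(sign$fits$lr$cv_auc, 0.6)
})

test_that("prediction is bounded and the Youden threshold maximizes J", {
  set.seed(41)
  y <- rep(c(0, 1), each = 50)
  x <- tibble::tibble(f = y + rnorm(100, 0, 0.8))
  sig <- train_signature(x, y, algorithms = "lr", seed = 1)
  p <- predict(sig, x)
  expect_true(all(p >= 0 & p <= 1))
  thr <- youden_threshold(p, y)
  j_at <- function(t) mean(p[y == 1] >= t) + mean(p[y == 0] < t) - 1
  grid <- seq(0.05, 0.95, by = 0.01)
  expect_gte(j_at(thr), max(vapply(grid, j_at, numeric(1))) - 1e-9)
})

test_that("the nomogram is an exact re-parameterization of its logistic", {
  set.seed(51)
  n <- 300
  d <- tibble::tibble(age = rnorm(n, 60, 8),
                      treatment = factor(sample(c("NACT", "NACRT"), n, TRUE)),
                      MLNSD_mm = rgamma(n, 7, 1),
                      habitat_score = runif(n),
                      mil_score = runif(n))
  eta <- -1 + 0.04 * (60 - d$age) + 2 * d$habitat_score + 1.5 * d$mil_score +
    0.1 * d$MLNSD_mm - 0.5 * (d$treatment == "NACRT")
  y <- rbinom(n, 1, plogis(eta))
  nomo <- build_nomogram(d, y)
  ap <- apply_nomogram(nomo, d)
  ref <- predict(nomo$fit, newdata = data.frame(d), type = "response")
  expect_equal(ap$probability, unname(ref), tolerance = 1e-9)
  # the largest-leverage variable spans exactly 0..100 points
  td <- tidy(nomo)
  expect_equal(max(td$max_points), 100, tolerance = 1e-9)
  pts <- as.matrix(ap[, startsWith(names(ap), "points_")])
  expect_true(all(pts >= -1e-9))
  expect_equal(max(apply(pts, 2, max)), 100, tolerance = 0.5)
  # probability is increasing in total points when one variable moves
  ord <- order(ap$total_points)
  d_onevar <- d
  d_onevar$habitat_score <- seq(0, 1, length.out = n)
  d_onevar$age <- mean(d$age); d_onevar$MLNSD_mm <- mean(d$MLNSD_mm)
  d_onevar$mil_score <- 0.5
  d_onevar$treatment <- factor("NACT", levels = levels(d$treatment))
  ap2 <- apply_nomogram(nomo, d_onevar)
  expect_true(all(diff(ap2$probability[order(ap2$total_points)]) > -1e-12))
})

test_that("a zero-coefficient nomogram variable contributes no points", {
  set.seed(61)
  n <- 400
  d <- tibble::tibble(strong = rnorm(n), null = rep(c(0, 1), n / 2))
  y <- rbinom(n, 1, plogis(1.5 * d$strong))
  nomo <- build_nomogram(d, y)
  td <- tidy(nomo)
  expect_lt(td$max_points[td$term == "null"], 15)
  expect_equal(unname(td$max_points[td$term == "strong"]), 100)
})
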