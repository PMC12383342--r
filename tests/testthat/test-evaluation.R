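brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("AUC equals brute-force pair enumeration, ties included", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0.75)

  set.seed(7)
  for (i in 1:12) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  # sign reversal maps AUC to 1 - AUC
  set.seed(8)
  sc <- runif(60); lb <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(-sc, lb)$auc, 1 - roc_auc(sc, lb)$auc,
               tolerance = 1e-12)
})

test_that("AUC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(9)
  labels <- rbinom(150, 1, 0.35)
  scores <- rnorm(150) + labels
  r <- roc_auc(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(sqrt(r$var), sqrt(pROC::var(pr, method = "delong")),
               tolerance = 1e-8)
})

test_that("the DeLong test is null-calibrated and handles self-comparison", {
  expect_warning(res <- delong_test(c(0.2, 0.8, 0.3, 0.9),
                                    c(0.2, 0.8, 0.3, 0.9), c(0, 1, 0, 1)),
                 "identical")
  expect_equal(res$p_value, 1)
  expect_equal(res$delta, 0)

  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- rbinom(120, 1, 0.4)
  s1 <- rnorm(120) + labels
  s2 <- 0.5 * s1 + rnorm(120) + 0.5 * labels
  ours <- delong_test(s1, s2, labels)
  ref <- pROC::roc.test(pROC::roc(labels, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, s2, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("threshold metrics reproduce the hand-worked confusion matrix", {
  # TP=3, FN=1, TN=4, FP=2
  labels <- c(rep(1, 4), rep(0, 6))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.1, 0.2, 0.3, 0.4)
  tm <- threshold_metrics(scores, labels, 0.5, n_boot = 200, seed = 1)
  est <- setNames(tm$estimate, tm$metric)
  expect_equal(est[["sensitivity"]], 0.75)
  expect_equal(est[["specificity"]], 2 / 3, tolerance = 1e-12)
  expect_equal(est[["ppv"]], 0.6)
  expect_equal(est[["npv"]], 0.8)
  expect_equal(est[["accuracy"]], 0.7)
  expect_true(all(tm$ci_low <= tm$estimate & tm$estimate <= tm$ci_high))
  # degenerate predicted class: PPV undefined, reported as NA
  tm2 <- threshold_metrics(c(0.1, 0.2, 0.3, 0.2), c(0, 1, 0, 1), 0.9,
                           n_boot = 50, seed = 1)
  expect_true(is.na(tm2$estimate[tm2$metric == "ppv"]))
  expect_error(threshold_metrics(scores, labels, 1.5), "threshold")
})

test_that("bootstrap CIs tighten with sample size", {
  width <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    lb <- rbinom(n, 1, 0.4)
    sc <- rnorm(n) + lb
    tm <- threshold_metrics(sc, lb, 0.5, n_boot = 300, seed = 2)
    mean(tm$ci_high - tm$ci_low)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("Hosmer-Lemeshow has the g-2 df rule and null calibration", {
  set.seed(17)
  p <- runif(500, 0.05, 0.95)
  y <- rbinom(500, 1, p)
  hl <- hosmer_lemeshow(p, y)
  expect_equal(hl$df, 8L)
  expect_true(hl$p_value > 0 && hl$p_value <= 1)
  expect_error(hosmer_lemeshow(runif(20), rbinom(20, 1, 0.5)), "at least")
})

test_that("calibration curves cover the diagonal for calibrated models", {
  set.seed(19)
  p <- runif(1500, 0.05, 0.95)
  y <- rbinom(1500, 1, p)
  cal <- calibration_curve(p, y, n_boot = 300, seed = 3)
  covered <- mean(cal$curve$lower <= cal$curve$predicted &
                    cal$curve$predicted <= cal$curve$upper)
  expect_gte(covered, 0.8)
  # bands widen as n shrinks
  cal_small <- calibration_curve(p[1:100], y[1:100], n_boot = 300, seed = 3)
  expect_gt(mean(cal_small$curve$upper - cal_small$curve$lower),
            mean(cal$curve$upper - cal$curve$lower))
  expect_error(calibration_curve(runif(10), rbinom(10, 1, 0.5)), "n >= 20")
})

test_that("decision curves obey the closed-form identities", {
  set.seed(23)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)          # prevalence 0.5
  perfect <- y * 0.9 + 0.05
  dc <- decision_curve(perfect, y, thresholds = c(0.25, 0.5, 0.75))
  expect_equal(dc$nb_model[dc$threshold == 0.5], 0.5)
  expect_true(all(dc$nb_none == 0))
  # treat-all crosses zero exactly at the prevalence
  pi0 <- 0.3
  y2 <- c(rep(1, 300), rep(0, 700))
  dc2 <- decision_curve(runif(1000), y2, thresholds = pi0)
  expect_equal(dc2$nb_all, 0, tolerance = 1e-12)
  # net benefit never exceeds prevalence
  sc <- runif(1000)
  dc3 <- decision_curve(sc, y2)
  expect_true(all(dc3$nb_model <= mean(y2) + 1e-12))
  expect_error(decision_curve(sc, y2, thresholds = c(0, 0.5)), "strictly")
})

test_that("evaluation bundles assemble and plot", {
  set.seed(29)
  y <- rbinom(300, 1, 0.35)
  p <- plogis(qlogis(0.35) + 1.2 * y + rnorm(300, 0, 0.8))
  ev <- evaluate_model(p, y, threshold = 0.4, seed = 1, n_boot = 200)
  expect_s3_class(ev$roc, "roc_result")
  expect_s3_class(ev$calibration, "calibration_result")
  expect_s3_class(ev$dca, "decision_curve")
  expect_equal(glance(ev$roc)$n_pos, sum(y))
  expect_s3_class(autoplot(ev$roc), "ggplot")
  expect_s3_class(autoplot(ev$calibration), "ggplot")
  expect_s3_class(autoplot(ev$dca), "ggplot")
})
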