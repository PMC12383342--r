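# fast tie-aware Mann-Whitney AUC (no inference); used by CV loops
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve and AUC with DeLong variance
#'
#' AUC as the Mann-Whitney statistic with midranks for ties; variance from
#' the DeLong structural components; Wald 95% CI (clipped to \[0,1\]), with a
#' logit-transformed variant available.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 vector.
#' @param ci_method `"wald"` or `"logit"`.
#' @return A `roc_result`: `auc`, `var`, `ci`, `curve` tibble, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("wald", "logit")) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("need both classes")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v <- delong_components(pos, neg)
  auc <- v$auc
  var_auc <- stats::var(v$v10) / length(pos) + stats::var(v$v01) / length(neg)
  se <- sqrt(var_auc)
  ci <- if (ci_method == "wald") {
    c(auc - 1.96 * se, auc + 1.96 * se)
  } else {
    if (auc <= 0 || auc >= 1 || se == 0) {
      c(auc, auc)
    } else {
      l <- stats::qlogis(auc); sel <- se / (auc * (1 - auc))
      stats::plogis(c(l - 1.96 * sel, l + 1.96 * sel))
    }
  }
  ci <- pmin(pmax(ci, 0), 1)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(cuts, function(t) mean(neg >= t), numeric(1)))
  structure(list(auc = auc, var = var_auc, ci = ci, curve = curve,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f); %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, var = x$var,
                 ci_low = x$ci[1], ci_high = x$ci[2],
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

# DeLong structural components via midranks: V10 for positives, V01 for
# negatives; AUC is their common mean.
delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  all <- c(pos, neg)
  r_all <- rank(all, ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided z-test of the paired AUC difference of two score vectors on the
#' same patients, normalized by the DeLong covariance estimate. Identical
#' scores (zero-variance difference) give p = 1 with a warning.
#'
#' @param scores_1,scores_2 Paired score vectors.
#' @param labels Binary 0/1 vector.
#' @return Tibble: `auc_1`, `auc_2`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  labels <- as.integer(labels)
  ip <- labels == 1
  c1 <- delong_components(scores_1[ip], scores_1[!ip])
  c2 <- delong_components(scores_2[ip], scores_2[!ip])
  m <- sum(ip); n <- sum(!ip)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- c1$auc - c2$auc
  if (var_delta <= .Machine$double.eps) {
    if (abs(delta) > 1e-12)
      warning("zero DeLong variance with nonzero AUC difference")
    else warning("identical models: zero-variance difference")
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_1 = c1$auc, auc_2 = c2$auc, delta = delta,
                 z = z, p_value = p)
}

#' Confusion-matrix metrics at a threshold, with bootstrap CIs
#'
#' Accuracy, sensitivity, specificity, PPV and NPV at `scores >= threshold`,
#' each with a percentile bootstrap 95% CI stratified by class. Metrics with
#' an empty predicted class (undefined PPV/NPV) are reported as NA.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @param threshold Decision threshold in (0, 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for resampling.
#' @return Tibble: `metric`, `estimate`, `ci_low`, `ci_high`; attribute
#'   `threshold`.
#' @export
threshold_metrics <- function(scores, labels, threshold, n_boot = 2000L,
                              seed = 1L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  labels <- as.integer(labels)
  point <- confusion_metrics(scores, labels, threshold)
  set.seed(seed)
  ip <- which(labels == 1); ineg <- which(labels == 0)
  boot <- matrix(NA_real_, n_boot, 5)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    boot[b, ] <- confusion_metrics(scores[idx], labels[idx], threshold)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- tibble::tibble(metric = names(point), estimate = unname(point),
                        ci_low = ci[1, ], ci_high = ci[2, ])
  attr(out, "threshold") <- threshold
  out
}

confusion_metrics <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of predicted probabilities (ties kept together;
#' empty groups collapsed with a warning), chi-square statistic
#' `sum((O - E)^2 / (E * (1 - E / n_g)))` with `groups - 2` degrees of
#' freedom.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @param groups Number of risk groups (default 10).
#' @return Tibble: `chisq`, `df`, `p_value`, `groups`.
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10L) {
  n <- length(probs)
  if (n < 5 * groups) stop("need at least 5 observations per group")
  brk <- unique(stats::quantile(probs, probs = seq(0, 1, length.out =
                                                     groups + 1)))
  if (length(brk) - 1L < groups) {
    warning("tied probabilities: groups reduced to ", length(brk) - 1L)
  }
  g <- cut(probs, breaks = brk, include.lowest = TRUE)
  ng <- tapply(rep(1, n), g, sum)
  og <- tapply(as.numeric(labels), g, sum)
  eg <- tapply(probs, g, sum)
  keep <- !is.na(ng) & ng > 0
  ng <- ng[keep]; og <- og[keep]; eg <- eg[keep]
  chisq <- sum((og - eg)^2 / (eg * (1 - eg / ng)))
  df <- length(ng) - 2L
  tibble::tibble(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 groups = length(ng))
}

#' Bootstrap calibration curve
#'
#' Bins patients by predicted probability and plots observed event frequency
#' against mean prediction, with percentile bootstrap bands (stratified by
#' class) over `n_boot` resamples.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @param bins Number of probability bins.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @return A `calibration_result`: `curve` tibble (`bin_mid`, `predicted`,
#'   `observed`, `lower`, `upper`, `n`), `n_boot`.
#' @export
calibration_curve <- function(probs, labels, bins = 10L, n_boot = 1000L,
                              seed = 1L) {
  if (length(probs) < 20L) stop("need n >= 20 for a calibration curve")
  labels <- as.integer(labels)
  brk <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1)))
  if (length(brk) < 2L) brk <- c(min(probs) - 1e-9, max(probs) + 1e-9)
  assign_bin <- function(p) cut(p, breaks = brk, include.lowest = TRUE)
  g <- assign_bin(probs)
  curve <- tibble::tibble(
    bin = levels(g),
    predicted = as.numeric(tapply(probs, g, mean)),
    observed = as.numeric(tapply(labels, g, mean)),
    n = as.integer(tapply(rep(1, length(g)), g, sum)))
  set.seed(seed)
  ip <- which(labels == 1); ineg <- which(labels == 0)
  bmat <- matrix(NA_real_, n_boot, nrow(curve))
  for (b in seq_len(n_boot)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    gb <- assign_bin(probs[idx])
    bmat[b, ] <- as.numeric(tapply(labels[idx], gb, mean))
  }
  curve$lower <- apply(bmat, 2, stats::quantile, 0.025, na.rm = TRUE)
  curve$upper <- apply(bmat, 2, stats::quantile, 0.975, na.rm = TRUE)
  curve <- curve[!is.na(curve$predicted), ]
  structure(list(curve = curve, n_boot = n_boot),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", nrow(x$curve), "bins,", x$n_boot,
      "bootstrap resamples\n")
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability t:
#' `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)`, against treat-all
#' `pi - (1-pi) * t/(1-t)` and treat-none (identically zero).
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @param thresholds Threshold grid strictly inside (0, 1).
#' @return A `decision_curve` tibble: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0,1)")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
  out <- tibble::tibble(threshold = thresholds,
                        nb_model = nb,
                        nb_all = prev - (1 - prev) * thresholds /
                          (1 - thresholds),
                        nb_none = 0)
  class(out) <- c("decision_curve", class(out))
  out
}

#' Full evaluation bundle for one model on one cohort
#'
#' @param scores Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @param threshold Decision threshold (e.g. the training Youden point).
#' @param seed Seed for all bootstraps.
#' @param n_boot Bootstrap replicates for threshold metrics and calibration.
#' @return An `eval_report` list: `roc`, `metrics`, `calibration`,
#'   `hosmer_lemeshow`, `dca`.
#' @export
evaluate_model <- function(scores, labels, threshold = 0.5, seed = 1L,
                           n_boot = 1000L) {
  structure(list(
    roc = roc_auc(scores, labels),
    metrics = threshold_metrics(scores, labels, threshold,
                                n_boot = n_boot, seed = seed),
    calibration = if (length(scores) >= 20)
      calibration_curve(scores, labels, n_boot = n_boot, seed = seed)
      else NULL,
    hosmer_lemeshow = if (length(scores) >= 50)
      hosmer_lemeshow(scores, labels) else NULL,
    dca = decision_curve(scores, labels)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$roc)
  print(x$metrics)
  if (!is.null(x$hosmer_lemeshow)) print(x$hosmer_lemeshow)
  invisible(x)
}
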