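#' Feature-selection configuration
#'
#' Defaults: robustness filter at ICC >= 0.85, Welch t-test screen at
#' p < 0.05, greedy pruning of Pearson |r| > 0.9 pairs, and LASSO with
#' 10-fold cross-validation choosing the minimum-MSE lambda.
#'
#' @param icc_threshold Keep features with ICC at or above this (inclusive).
#' @param ttest_alpha Keep features with p strictly below this.
#' @param corr_threshold Prune while any pairwise |r| exceeds this.
#' @param lasso_folds CV folds for the LASSO stage.
#' @param seed Seed for CV fold assignment.
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_threshold = 0.85, ttest_alpha = 0.05,
                             corr_threshold = 0.9, lasso_folds = 10L,
                             seed = 1L) {
  stopifnot(icc_threshold > 0, icc_threshold < 1,
            ttest_alpha > 0, ttest_alpha < 1,
            corr_threshold > 0, corr_threshold < 1, lasso_folds >= 2L)
  structure(list(icc_threshold = icc_threshold, ttest_alpha = ttest_alpha,
                 corr_threshold = corr_threshold,
                 lasso_folds = as.integer(lasso_folds),
                 seed = as.integer(seed)),
            class = "selection_config")
}

feature_matrix <- function(tbl) {
  m <- as.matrix(dplyr::select(tbl, -dplyr::any_of("patient_id")))
  storage.mode(m) <- "double"
  m
}

#' ICC robustness filter across duplicate segmentations
#'
#' Per-feature two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation ICC(2,1) between two feature tables of the same
#' patients (two raters, or test-retest). Features with ICC at or above the
#' threshold are kept; zero-variance features (undefined ICC) are dropped
#' with a warning.
#'
#' @param table_a,table_b Feature tibbles with identical patients/columns.
#' @param cfg A [selection_config()].
#' @return Tibble `feature`, `icc`, `kept`.
#' @export
icc_filter <- function(table_a, table_b, cfg = selection_config()) {
  a <- feature_matrix(table_a); b <- feature_matrix(table_b)
  if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b)))
    stop("tables must share patients and features")
  n <- nrow(a); k <- 2
  icc <- vapply(seq_len(ncol(a)), function(j) {
    x <- cbind(a[, j], b[, j])
    if (stats::sd(x) == 0) return(NA_real_)
    row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
    msr <- k * sum((row_m - g)^2) / (n - 1)
    msc <- n * sum((col_m - g)^2) / (k - 1)
    sse <- sum((x - outer(row_m, rep(1, k)) -
                  outer(rep(1, n), col_m) + g)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }, numeric(1))
  undef <- is.na(icc)
  if (any(undef))
    warning(sum(undef), " zero-variance features dropped (ICC undefined)")
  tibble::tibble(feature = colnames(a), icc = icc,
                 kept = !undef & icc >= cfg$icc_threshold)
}

#' Z-score standardization fitted on training data
#'
#' Columns are centered and scaled with the training mean and population SD;
#' the same affine map is applied to any other tables. Zero-SD columns are
#' dropped with a warning.
#'
#' @param train Training feature tibble.
#' @param ... Further tibbles to transform with the training statistics.
#' @return List with `train`, `others` (the transformed `...`), and the
#'   `center`/`scale` vectors used.
#' @export
zscore_fit_apply <- function(train, ...) {
  m <- feature_matrix(train)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))   # population SD
  keep <- sdev > 0
  if (any(!keep)) warning(sum(!keep), " zero-SD features dropped")
  tf <- function(tbl) {
    x <- feature_matrix(tbl)[, keep, drop = FALSE]
    x <- sweep(sweep(x, 2, mu[keep]), 2, sdev[keep], `/`)
    out <- tibble::as_tibble(x)
    if ("patient_id" %in% names(tbl))
      out <- dplyr::mutate(out, patient_id = tbl$patient_id, .before = 1)
    out
  }
  list(train = tf(train), others = lapply(list(...), tf),
       center = mu[keep], scale = sdev[keep])
}

#' Welch t-test screen against the binary label
#'
#' Two-sided Welch t-test per feature; keeps p strictly below the alpha.
#'
#' @param tbl Feature tibble.
#' @param labels Binary 0/1 vector, one per row.
#' @param cfg A [selection_config()].
#' @return Tibble `feature`, `p_value`, `kept`.
#' @export
ttest_filter <- function(tbl, labels, cfg = selection_config()) {
  m <- feature_matrix(tbl)
  g1 <- labels == 1
  if (sum(g1) < 2 || sum(!g1) < 2) stop("each class needs >= 2 samples")
  x1 <- m[g1, , drop = FALSE]; x0 <- m[!g1, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1
  tibble::tibble(feature = colnames(m), p_value = p, kept = p < cfg$ttest_alpha)
}

#' Greedy correlation pruning
#'
#' While any feature pair has Pearson |r| above the threshold, removes the
#' feature with the most over-threshold partners (ties broken by larger mean
#' |r| with its partners, then lexicographic name), so one representative of
#' each correlated block survives.
#'
#' @inheritParams ttest_filter
#' @return Character vector of surviving feature names.
#' @export
correlation_prune <- function(tbl, cfg = selection_config()) {
  m <- feature_matrix(tbl)
  if (ncol(m) < 2L) return(colnames(m))
  r <- abs(suppressWarnings(stats::cor(m)))
  r[is.na(r)] <- 0
  diag(r) <- 0
  alive <- rep(TRUE, ncol(m))
  nms <- colnames(m)
  repeat {
    ra <- r[alive, alive, drop = FALSE]
    over <- ra > cfg$corr_threshold
    if (!any(over)) break
    cnt <- rowSums(over)
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1L) {
      meanr <- vapply(cand, function(i) mean(ra[i, over[i, ]]), numeric(1))
      cand <- cand[meanr == max(meanr)]
      if (length(cand) > 1L)
        cand <- cand[order(rownames(ra)[cand])][1]
    }
    drop_name <- rownames(ra)[cand[1]]
    alive[match(drop_name, nms)] <- FALSE
  }
  nms[alive]
}

#' LASSO feature selection with cross-validated lambda
#'
#' L1-penalized linear (MSE) regression of the 0/1 label on the features.
#' Lambda is chosen to minimize the mean 10-fold cross-validated MSE; the
#' selection is the set of nonzero coefficients at that lambda.
#'
#' @inheritParams ttest_filter
#' @param lambda Optional lambda grid (log-spaced positive values).
#' @return List: `selected` names, `coefficients` (named, nonzero),
#'   `lambda_min`, and the `cv` object.
#' @export
lasso_select <- function(tbl, labels, cfg = selection_config(),
                         lambda = NULL) {
  m <- feature_matrix(tbl)
  set.seed(cfg$seed)
  cv <- glmnet::cv.glmnet(m, as.numeric(labels), family = "gaussian",
                          alpha = 1, nfolds = cfg$lasso_folds,
                          lambda = lambda, type.measure = "mse",
                          standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  nz <- co[co != 0]
  list(selected = names(nz), coefficients = nz,
       lambda_min = cv$lambda.min, cv = cv)
}

#' The full selection cascade
#'
#' ICC filter (optional; the habitat and MIL chains skip it because cluster
#' identities make duplicate segmentations ill-defined), z-score fit on the
#' training table, Welch t-test screen, greedy correlation pruning, then
#' LASSO. Survivors are strictly nested across stages.
#'
#' @param train Training feature tibble.
#' @param labels Binary training labels.
#' @param cfg A [selection_config()].
#' @param retest Optional duplicate-segmentation table enabling the ICC
#'   stage.
#' @param test Optional held-out table transformed with training statistics.
#' @return A `selection_report`: per-stage survivors, the z-score map, the
#'   LASSO fit, and standardized `train`/`test` tables restricted to the
#'   final selection.
#' @export
select_features <- function(train, labels, cfg = selection_config(),
                            retest = NULL, test = NULL) {
  stages <- list()
  current <- setdiff(names(train), "patient_id")
  stages$input <- current

  if (!is.null(retest)) {
    icc <- icc_filter(train, retest, cfg)
    current <- icc$feature[icc$kept]
    stages$icc <- current
  } else icc <- NULL

  keep_cols <- function(tbl, feats)
    dplyr::select(tbl, dplyr::any_of(c("patient_id", feats)))

  z <- if (is.null(test)) {
    zscore_fit_apply(keep_cols(train, current))
  } else {
    zscore_fit_apply(keep_cols(train, current), keep_cols(test, current))
  }
  ztrain <- z$train
  current <- intersect(current, names(ztrain))
  stages$zscore <- current

  tt <- ttest_filter(keep_cols(ztrain, current), labels, cfg)
  current <- tt$feature[tt$kept]
  if (length(current) == 0L) {
    # degenerate chain (no univariately significant feature): keep the
    # single most significant one so downstream models stay defined
    warning("no features pass the t-test screen; keeping the smallest p")
    current <- tt$feature[which.min(tt$p_value)]
  }
  stages$ttest <- current

  current <- correlation_prune(keep_cols(ztrain, current), cfg)
  stages$correlation <- current

  if (length(current) >= 2L) {
    las <- lasso_select(keep_cols(ztrain, current), labels, cfg)
    if (length(las$selected) > 0L) {
      current <- las$selected
    } else {
      # all coefficients shrunk to zero at lambda.min: keep the first
      # predictor to enter the regularization path so the signature is
      # never empty
      first_in <- stats::predict(las$cv$glmnet.fit,
                                 type = "nonzero",
                                 s = min(las$cv$glmnet.fit$lambda[
                                   las$cv$glmnet.fit$df > 0]))
      idx <- first_in[[1]][1]
      current <- colnames(feature_matrix(keep_cols(ztrain, current)))[idx]
    }
  } else {
    las <- NULL
  }
  stages$lasso <- current

  ztest <- if (!is.null(test)) keep_cols(z$others[[1]], current) else NULL
  structure(list(stages = stages, icc = icc, ttest = tt, lasso = las,
                 center = z$center, scale = z$scale,
                 train = keep_cols(ztrain, current), test = ztest,
                 config = cfg),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  sizes <- vapply(x$stages, length, integer(1))
  cat("<selection_report>\n")
  for (s in names(sizes)) cat(sprintf("  %-12s %d\n", s, sizes[[s]]))
  invisible(x)
}

#' @export
tidy.selection_report <- function(x, ...) {
  tibble::tibble(stage = names(x$stages),
                 n_features = vapply(x$stages, length, integer(1)))
}
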