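#' Univariate logistic screening of clinicoradiological variables
#'
#' One single-variable logistic fit per candidate column, reporting the
#' coefficient, odds ratio, Wald 95% CI and p-value. Variables with p < 0.05
#' advance to the multivariate fit. Complete separation is flagged and the
#' variable refit with a small ridge penalty.
#'
#' @param clinical Tibble of candidate variables (numeric, binary or factor);
#'   a `patient_id` column is ignored.
#' @param labels Binary 0/1 outcome vector.
#' @param alpha Significance level gating entry to the multivariate model.
#' @return A `logistic_screen` tibble: `variable`, `estimate`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `significant`, `separation`.
#' @export
univariate_screen <- function(clinical, labels, alpha = 0.05) {
  if (length(unique(labels)) < 2L) stop("need both classes")
  vars <- setdiff(names(clinical), c("patient_id", "label"))
  rows <- lapply(vars, function(v) {
    d <- data.frame(y = labels, x = clinical[[v]])
    fit <- suppressWarnings(stats::glm(y ~ x, data = d, family = stats::binomial()))
    # complete separation pushes the linear predictor to the saturation zone
    sep <- !fit$converged || max(abs(stats::predict(fit))) > 15
    if (sep) {
      # penalized fallback: small ridge via glmnet keeps the estimate finite
      xm <- stats::model.matrix(~x, d)[, -1, drop = FALSE]
      pen <- glmnet::glmnet(cbind(xm, 0), d$y, family = "binomial",
                            alpha = 0, lambda = 0.01)
      est <- as.numeric(stats::coef(pen))[2]
      se <- NA_real_; p <- NA_real_
    } else {
      sm <- summary(fit)$coefficients
      est <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
    }
    tibble::tibble(variable = v, estimate = est,
                   odds_ratio = exp(est),
                   ci_low = exp(est - 1.96 * se),
                   ci_high = exp(est + 1.96 * se),
                   p_value = p,
                   significant = !is.na(p) & p < alpha,
                   separation = sep)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("logistic_screen", class(out))
  out
}

#' Multivariate logistic fit of screened variables
#'
#' Joint logistic fit of the screening survivors; Wald CIs; the retained set
#' is the variables significant (p < alpha) in the joint model. A condition
#' number guard warns on near-collinear designs.
#'
#' @param clinical Tibble holding at least the screened variables.
#' @param labels Binary outcome vector.
#' @param variables Character vector of variables to enter.
#' @param alpha Joint-model significance threshold.
#' @return A `multivariate_fit` list: `table` (per-variable tibble),
#'   `retained`, and the underlying `glm` fit.
#' @export
multivariate_fit <- function(clinical, labels, variables, alpha = 0.05) {
  if (length(variables) == 0L)
    return(structure(list(table = tibble::tibble(), retained = character(0),
                          fit = NULL), class = "multivariate_fit"))
  d <- data.frame(y = labels, clinical[, variables, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = d, family = stats::binomial()))
  X <- stats::model.matrix(fit)
  kappa_x <- kappa(crossprod(scale(X[, -1, drop = FALSE])), exact = FALSE)
  if (is.finite(kappa_x) && kappa_x > 1e6)
    warning("near-collinear design (condition number ", signif(kappa_x, 2), ")")
  sm <- summary(fit)$coefficients
  rows <- sm[-1, , drop = FALSE]
  tab <- tibble::tibble(variable = rownames(rows),
                        estimate = rows[, 1],
                        odds_ratio = exp(rows[, 1]),
                        ci_low = exp(rows[, 1] - 1.96 * rows[, 2]),
                        ci_high = exp(rows[, 1] + 1.96 * rows[, 2]),
                        p_value = rows[, 4],
                        retained = rows[, 4] < alpha)
  # map model-matrix terms back to source variables for the retained set
  retained <- unique(unlist(lapply(variables, function(v)
    if (any(tab$retained & startsWith(tab$variable, v))) v else NULL)))
  structure(list(table = tab, retained = retained, fit = fit),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat("<multivariate_fit> retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' @export
tidy.multivariate_fit <- function(x, ...) x$table

#' Build the clinicoradiological signature
#'
#' Univariate screen at p < 0.05 followed by a multivariate logistic fit; the
#' signature is the joint logistic model over the independently significant
#' variables, scoring patients by predicted probability.
#'
#' @inheritParams univariate_screen
#' @return A `clinic_signature`: `screen`, `multivariate`, `variables`, `fit`.
#' @export
clinic_signature <- function(clinical, labels, alpha = 0.05) {
  sc <- univariate_screen(clinical, labels, alpha)
  mv <- multivariate_fit(clinical, labels,
                         sc$variable[sc$significant], alpha)
  vars <- if (length(mv$retained)) mv$retained else sc$variable[sc$significant]
  fit <- if (length(vars)) {
    d <- data.frame(y = labels, clinical[, vars, drop = FALSE])
    suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  } else NULL
  structure(list(screen = sc, multivariate = mv, variables = vars, fit = fit),
            class = "clinic_signature")
}

#' @export
predict.clinic_signature <- function(object, newdata, ...) {
  if (is.null(object$fit)) return(rep(0.5, nrow(newdata)))
  stats::predict(object$fit, newdata = newdata, type = "response")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- model zoo ------------------------------------------------------------

zoo_algorithms <- function() {
  c("lr", "svm", "rf", "et", "xgb_shallow", "xgb_deep", "mlp")
}

default_grids <- function() {
  list(lr = data.frame(lambda = c(0, 0.01, 0.1)),
       svm = data.frame(cost = c(0.1, 1, 10)),
       rf = data.frame(mtry_frac = c(0.33, 0.6)),
       et = data.frame(mtry_frac = c(0.33, 0.6)),
       xgb_shallow = data.frame(nrounds = c(50, 100)),
       xgb_deep = data.frame(nrounds = c(50, 100)),
       mlp = data.frame(size = c(3, 6)))
}

fit_zoo_model <- function(algo, x, y, par, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  switch(algo,
    lr = {
      if (par$lambda == 0) {
        d <- data.frame(y = y, x)
        suppressWarnings(stats::glm(y ~ ., data = d,
                                    family = stats::binomial()))
      } else {
        xm <- as.matrix(x)
        if (ncol(xm) < 2) xm <- cbind(xm, `.pad` = 0)  # glmnet needs >= 2
        glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                       lambda = par$lambda)
      }
    },
    svm = e1071::svm(as.matrix(x), yf, kernel = "radial", cost = par$cost,
                     probability = TRUE),
    rf = ranger::ranger(x = x, y = yf, probability = TRUE, num.trees = 300,
                        mtry = max(1L, floor(par$mtry_frac * ncol(x))),
                        seed = seed),
    et = ranger::ranger(x = x, y = yf, probability = TRUE, num.trees = 300,
                        splitrule = "extratrees", num.random.splits = 1,
                        mtry = max(1L, floor(par$mtry_frac * ncol(x))),
                        seed = seed),
    xgb_shallow = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = par$nrounds, verbose = 0),
    xgb_deep = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 5,
                    eta = 0.1, subsample = 0.8, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = par$nrounds, verbose = 0),
    mlp = nnet::nnet(x = as.matrix(x), y = y, size = par$size, decay = 0.01,
                     maxit = 200, trace = FALSE, entropy = TRUE),
    stop("unknown algorithm: ", algo))
}

predict_zoo_model <- function(algo, model, x) {
  switch(algo,
    lr = {
      if (inherits(model, "glmnet")) {
        xm <- as.matrix(x)
        if (ncol(xm) < 2) xm <- cbind(xm, `.pad` = 0)
        as.numeric(stats::predict(model, xm, type = "response"))
      } else {
        as.numeric(stats::predict(model, newdata = data.frame(x),
                                  type = "response"))
      }
    },
    svm = {
      pr <- stats::predict(model, as.matrix(x), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = stats::predict(model, data = x)$predictions[, "1"],
    et = stats::predict(model, data = x)$predictions[, "1"],
    xgb_shallow = as.numeric(stats::predict(model,
                                            xgboost::xgb.DMatrix(
                                              as.matrix(x)))),
    xgb_deep = as.numeric(stats::predict(model,
                                         xgboost::xgb.DMatrix(
                                           as.matrix(x)))),
    mlp = as.numeric(stats::predict(model, as.matrix(x))),
    stop("unknown algorithm: ", algo))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) stop("a class has fewer samples than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train a radiomic signature over the model zoo
#'
#' For each algorithm: exhaustive grid search maximizing mean cross-validated
#' AUC over seeded stratified folds; refit on the full training set at the
#' best hyperparameters; record the Youden-optimal threshold from the
#' training ROC. The zoo holds logistic regression, an RBF support-vector
#' machine, random forest, extremely randomized trees, two gradient-boosting
#' variants and a single-hidden-layer perceptron.
#'
#' @param features Feature tibble (`patient_id` column optional).
#' @param labels Binary 0/1 vector.
#' @param algorithms Subset of `zoo_algorithms()` to fit.
#' @param folds Cross-validation folds.
#' @param seed Seed controlling folds and stochastic learners.
#' @return A `signature_model`: per-algorithm fits, CV report, the best
#'   algorithm by mean CV AUC, and its training threshold.
#' @export
train_signature <- function(features, labels,
                            algorithms = c("lr", "rf"),
                            folds = 5L, seed = 1L) {
  x <- as.data.frame(feature_matrix(features))
  y <- as.integer(labels)
  fold <- stratified_folds(y, folds, seed)
  grids <- default_grids()
  cv_rows <- list(); fits <- list(); thresholds <- list()
  for (algo in algorithms) {
    grid <- grids[[algo]]
    aucs <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fold_auc <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        m <- fit_zoo_model(algo, x[tr, , drop = FALSE], y[tr],
                           grid[g, , drop = FALSE], seed + 7 * f)
        p <- predict_zoo_model(algo, m, x[!tr, , drop = FALSE])
        auc_mw(p, y[!tr])
      }, numeric(1))
      aucs[g] <- mean(fold_auc)
      cv_rows[[length(cv_rows) + 1L]] <-
        tibble::tibble(algorithm = algo, grid_row = g,
                       cv_auc = aucs[g],
                       params = paste(names(grid), grid[g, ],
                                      sep = "=", collapse = ","))
    }
    best <- which.max(aucs)
    fit <- fit_zoo_model(algo, x, y, grid[best, , drop = FALSE], seed)
    p_train <- predict_zoo_model(algo, fit, x)
    fits[[algo]] <- list(model = fit, params = grid[best, , drop = FALSE],
                         cv_auc = aucs[best])
    thresholds[[algo]] <- youden_threshold(p_train, y)
  }
  report <- dplyr::bind_rows(cv_rows)
  best_algo <- names(fits)[which.max(vapply(fits, function(f) f$cv_auc,
                                            numeric(1)))]
  structure(list(fits = fits, cv_report = report, best = best_algo,
                 thresholds = thresholds,
                 feature_names = colnames(x), folds = folds, seed = seed),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> best:", x$best,
      sprintf("(CV AUC %.3f);", x$fits[[x$best]]$cv_auc),
      length(x$feature_names), "features\n")
  invisible(x)
}

#' @export
predict.signature_model <- function(object, newdata, algorithm = NULL, ...) {
  algo <- algorithm %||% object$best
  x <- as.data.frame(feature_matrix(newdata))[, object$feature_names,
                                              drop = FALSE]
  predict_zoo_model(algo, object$fits[[algo]]$model, x)
}

#' @export
tidy.signature_model <- function(x, ...) x$cv_report

#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(best_algorithm = x$best,
                 cv_auc = x$fits[[x$best]]$cv_auc,
                 n_features = length(x$feature_names),
                 folds = x$folds)
}

#' Youden-optimal probability threshold from a training ROC
#'
#' @param scores Predicted probabilities.
#' @param labels Binary 0/1 vector.
#' @return The threshold maximizing sensitivity + specificity - 1.
#' @export
youden_threshold <- function(scores, labels) {
  cuts <- sort(unique(scores))
  if (length(cuts) > 1L) cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  j <- vapply(cuts, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}
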