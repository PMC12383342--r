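#' Build a fusion nomogram
#'
#' Logistic model over the component signature scores (predicted
#' probabilities) and the independent clinicoradiological predictors, with
#' the fitted model re-parameterized on a 0-100 point scale: the points of
#' variable i at value x are `100 * |b_i| * (x - ref_i) / max_j(|b_j| *
#' range_j)`, with the reference at the variable's minimum-risk end, so the
#' largest-leverage variable spans exactly 0-100. The probability map is the
#' inverse logit of the underlying linear predictor, so points are an exact
#' re-parameterization, not an approximation.
#'
#' @param data Tibble of nomogram inputs (e.g. `age`, `treatment`, `MLNSD_mm`,
#'   `habitat_score`, `mil_score`); factors are expanded to model-matrix
#'   columns.
#' @param labels Binary 0/1 outcome.
#' @return A `nomogram` object.
#' @export
build_nomogram <- function(data, labels) {
  d <- data.frame(y = labels,
                  data[, setdiff(names(data), c("patient_id", "label")),
                       drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = d,
                                     family = stats::binomial()))
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  beta <- stats::coef(fit)[-1]
  beta[is.na(beta)] <- 0
  rng <- apply(X, 2, range)
  # reference = the end of the observed range with the lower risk
  ref <- ifelse(beta >= 0, rng[1, ], rng[2, ])
  lever <- abs(beta) * (rng[2, ] - rng[1, ])
  denom <- max(lever)
  if (denom == 0) stop("all coefficients are zero; nothing to scale")
  scale_pts <- 100 / denom
  structure(list(fit = fit, beta = beta, ref = ref,
                 ranges = rng, scale = scale_pts,
                 terms = colnames(X)),
            class = "nomogram")
}

#' Apply a nomogram to new patients
#'
#' @param nomo A [build_nomogram()] object.
#' @param newdata Tibble with the nomogram's input variables.
#' @return Tibble: per-variable points, `total_points`, `probability`.
#' @export
apply_nomogram <- function(nomo, newdata) {
  d <- data.frame(newdata[, setdiff(names(newdata),
                                    c("patient_id", "label")),
                          drop = FALSE])
  X <- stats::model.matrix(stats::delete.response(stats::terms(nomo$fit)),
                           data = d)[, -1, drop = FALSE]
  X <- X[, nomo$terms, drop = FALSE]
  # signed form: beta * (x - ref) is nonnegative inside the training range
  # (the reference sits at the minimum-risk end) and stays monotone for
  # values beyond it
  pts <- sweep(sweep(X, 2, nomo$ref), 2, nomo$beta, `*`) * nomo$scale
  colnames(pts) <- paste0("points_", nomo$terms)
  eta <- stats::coef(nomo$fit)[1] + drop(X %*% nomo$beta)
  out <- tibble::as_tibble(pts)
  out$total_points <- rowSums(pts)
  out$probability <- unname(stats::plogis(eta))
  if ("patient_id" %in% names(newdata))
    out <- dplyr::mutate(out, patient_id = newdata$patient_id, .before = 1)
  out
}

#' @export
print.nomogram <- function(x, ...) {
  cat("<nomogram> terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.nomogram <- function(x, ...) {
  tibble::tibble(term = x$terms, estimate = x$beta,
                 reference = x$ref,
                 max_points = abs(x$beta) * (x$ranges[2, ] - x$ranges[1, ]) *
                   x$scale)
}

#' Point-scale chart of a nomogram
#'
#' @param object A `nomogram`.
#' @param ... Unused.
#' @return A ggplot showing each variable's point span.
#' @export
autoplot.nomogram <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$max_points,
                                   y = stats::reorder(.data$term,
                                                      .data$max_points))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "maximum points (0-100 scale)", y = NULL,
                  title = "Nomogram variable leverage") +
    ggplot2::theme_minimal()
}
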