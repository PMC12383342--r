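#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path(color = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve with bootstrap bands
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted probability", y = "observed frequency",
                  title = sprintf("Calibration (%d bootstrap resamples)",
                                  object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Plot a decision curve
#'
#' @param object A `decision_curve` tibble.
#' @param ... Unused.
#' @return A ggplot of net benefit against threshold probability.
#' @export
autoplot.decision_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("nb_model", "nb_all", "nb_none"),
                              names_to = "strategy", values_to = "nb")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                     color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::scale_color_manual(values = c(nb_model = "firebrick",
                                           nb_all = "grey40",
                                           nb_none = "grey70"),
                                labels = c(nb_model = "model",
                                           nb_all = "treat all",
                                           nb_none = "treat none")) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  color = NULL, title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a habitat map
#'
#' @param h A `habitat_map`.
#' @param slice Axial slice index; defaults to the largest-area slice.
#' @return A ggplot raster of habitat labels.
#' @export
plot_habitat_slice <- function(h, slice = NULL) {
  arr <- unclass(h)
  if (is.null(slice)) slice <- which.max(apply(arr > 0, 3, sum))
  sl <- arr[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$habitat <- factor(as.vector(sl))
  ggplot2::ggplot(df[df$habitat != "0", ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$habitat)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Habitat map, axial slice %d", slice),
                  fill = "habitat") +
    ggplot2::theme_minimal()
}
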