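#' First-order intensity statistics of a region
#'
#' The 19 standard first-order radiomic statistics of the in-ROI voxel
#' values. Entropy and uniformity are computed on the supplied discretized
#' values. `total_energy` (the voxel-volume-scaled duplicate of energy) is
#' dropped when `include_total_energy = FALSE`, giving the 18-feature set
#' used per derived image.
#'
#' @param values Numeric vector of in-ROI voxel values.
#' @param binned Integer vector of in-ROI discretized values (1..n_bins).
#' @param voxel_volume Voxel volume in mm^3 (for total energy).
#' @param include_total_energy Keep the voxel-volume-scaled energy?
#' @return Named numeric vector (19 or 18 values).
#' @export
first_order_features <- function(values, binned,
                                 voxel_volume = 1,
                                 include_total_energy = TRUE) {
  if (length(values) == 0L) stop("empty ROI")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)           # population variance
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  qs <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                        names = FALSE, type = 7)
  sub <- values[values >= qs[1] & values <= qs[5]]
  rmad <- if (length(sub)) mean(abs(sub - mean(sub))) else 0
  p <- tabulate(binned)
  p <- p[p > 0] / n
  out <- c(
    energy = sum(values^2),
    total_energy = voxel_volume * sum(values^2),
    entropy = -sum(p * log2(p)),
    minimum = min(values),
    p10 = qs[1], p90 = qs[5],
    maximum = max(values),
    mean = mu,
    median = qs[3],
    iqr = qs[4] - qs[2],
    range = max(values) - min(values),
    mad = mean(abs(values - mu)),
    rmad = rmad,
    rms = sqrt(mean(values^2)),
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
  if (!include_total_energy) out <- out[names(out) != "total_energy"]
  out
}
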