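#' Texture-matrix features of a discretized region
#'
#' Computes the 73 texture features of a binned ROI: 22 from the gray-level
#' co-occurrence matrix (GLCM), 16 from the run-length matrix (GLRLM), 16
#' from the size-zone matrix (GLSZM), 14 from the dependence matrix (GLDM)
#' and 5 from the neighborhood gray-tone difference matrix (NGTDM). GLCM and
#' GLRLM are computed for each of the 13 unique 3D directions and the
#' per-direction features averaged. Degenerate single-level regions yield
#' defined values (e.g. joint entropy 0, maximum probability 1), never
#' errors.
#'
#' @param binned Integer array of bin labels, 0 outside the ROI.
#' @param n_bins Number of gray levels used in `binned`.
#' @return Named numeric vector of length 73.
#' @export
texture_features <- function(binned, n_bins) {
  dims <- dim(binned)
  np <- sum(binned > 0L)
  if (np == 0L) stop("empty ROI")
  b <- as.integer(binned)

  glcm <- cpp_glcm(b, as.integer(dims), as.integer(n_bins))
  glcm_f <- rowMeans(cpp_glcm_features(glcm, as.integer(n_bins)))
  names(glcm_f) <- glcm_feature_names()

  glrlm <- cpp_glrlm(b, as.integer(dims), as.integer(n_bins))
  glrlm_f <- rowMeans(cpp_run_features(glrlm, as.integer(n_bins),
                                       dim(glrlm)[2], np))
  names(glrlm_f) <- glrlm_feature_names()

  zones <- cpp_glszm_zones(b, as.integer(dims))
  glszm_f <- glszm_features(zones, n_bins, np)

  gldm <- cpp_gldm(b, as.integer(dims), as.integer(n_bins), 0L)
  gldm_f <- gldm_features(gldm)

  ngtdm <- cpp_ngtdm(b, as.integer(dims), as.integer(n_bins))
  ngtdm_f <- ngtdm_features(ngtdm, np)

  c(stats::setNames(glcm_f, paste0("glcm_", names(glcm_f))),
    stats::setNames(glrlm_f, paste0("glrlm_", names(glrlm_f))),
    stats::setNames(glszm_f, paste0("glszm_", names(glszm_f))),
    stats::setNames(gldm_f, paste0("gldm_", names(gldm_f))),
    stats::setNames(ngtdm_f, paste0("ngtdm_", names(ngtdm_f))))
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "id", "idm", "idmn",
    "idn", "imc1", "imc2", "inverse_variance", "joint_average",
    "joint_energy", "joint_entropy", "maximum_probability", "sum_entropy",
    "sum_squares")
}

glrlm_feature_names <- function() {
  c("short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
    "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
    "run_length_nonuniformity_normalized", "run_percentage",
    "gray_level_variance", "run_variance", "run_entropy",
    "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
    "short_run_low_gray_level_emphasis",
    "short_run_high_gray_level_emphasis",
    "long_run_low_gray_level_emphasis",
    "long_run_high_gray_level_emphasis")
}

glcm_features <- function(P) {
  tot <- sum(P)
  keep <- which(rowSums(P) > 0)
  if (tot == 0 || length(keep) == 0) {
    # no voxel pairs along this direction: defined degenerate output
    out <- numeric(22)
    names(out) <- c("autocorrelation", "cluster_prominence", "cluster_shade",
                    "cluster_tendency", "contrast", "correlation",
                    "difference_average", "difference_entropy",
                    "difference_variance", "id", "idm", "idmn", "idn",
                    "imc1", "imc2", "inverse_variance", "joint_average",
                    "joint_energy", "joint_entropy", "maximum_probability",
                    "sum_entropy", "sum_squares")
    out["correlation"] <- 1
    return(out)
  }
  # crop to occupied gray levels (original level values kept in i/j)
  P <- P[keep, keep, drop = FALSE] / tot
  ng <- length(keep)
  i <- matrix(keep, ng, ng); j <- t(i)
  px <- rowSums(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  # difference and sum distributions
  pd_r <- rowsum(as.vector(P), as.vector(abs(i - j)))
  pd <- as.numeric(pd_r); kd <- as.numeric(rownames(pd_r))
  ps_r <- rowsum(as.vector(P), as.vector(i + j))
  ps <- as.numeric(ps_r)
  da <- sum(kd * pd)
  hxy <- -sum(xlog2(P))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(xlog2(pxpy))
  hx <- -sum(xlog2(px))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offd <- i != j
  c(autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
    difference_average = da,
    difference_entropy = -sum(xlog2(pd)),
    difference_variance = sum((kd - da)^2 * pd),
    id = sum(P / (1 + abs(i - j))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(P[offd] / (i[offd] - j[offd])^2),
    joint_average = mu,
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    maximum_probability = max(P),
    sum_entropy = -sum(xlog2(ps)),
    sum_squares = sig2)
}

glrlm_features <- function(P, np) {
  run_matrix_features(P, np,
                      prefix = c("short_run_emphasis", "long_run_emphasis",
                                 "gray_level_nonuniformity",
                                 "gray_level_nonuniformity_normalized",
                                 "run_length_nonuniformity",
                                 "run_length_nonuniformity_normalized",
                                 "run_percentage",
                                 "gray_level_variance", "run_variance",
                                 "run_entropy",
                                 "low_gray_level_run_emphasis",
                                 "high_gray_level_run_emphasis",
                                 "short_run_low_gray_level_emphasis",
                                 "short_run_high_gray_level_emphasis",
                                 "long_run_low_gray_level_emphasis",
                                 "long_run_high_gray_level_emphasis"))
}

glszm_features <- function(zones, n_bins, np) {
  smax <- if (nrow(zones)) max(zones[, 2]) else 1L
  P <- matrix(0, n_bins, smax)
  if (nrow(zones))
    for (r in seq_len(nrow(zones))) {
      P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
    }
  run_matrix_features(P, np,
                      prefix = c("small_area_emphasis", "large_area_emphasis",
                                 "gray_level_nonuniformity",
                                 "gray_level_nonuniformity_normalized",
                                 "size_zone_nonuniformity",
                                 "size_zone_nonuniformity_normalized",
                                 "zone_percentage",
                                 "gray_level_variance", "zone_variance",
                                 "zone_entropy",
                                 "low_gray_level_zone_emphasis",
                                 "high_gray_level_zone_emphasis",
                                 "small_area_low_gray_level_emphasis",
                                 "small_area_high_gray_level_emphasis",
                                 "large_area_low_gray_level_emphasis",
                                 "large_area_high_gray_level_emphasis"))
}

# shared skeleton for the run-length / size-zone families: P is levels x
# lengths, np the ROI voxel count; names supplied by the caller.
run_matrix_features <- function(P, np, prefix) {
  nr <- sum(P)
  if (nr == 0) { out <- numeric(16); names(out) <- prefix; return(out) }
  rk <- which(rowSums(P) > 0); ck <- which(colSums(P) > 0)
  P <- P[rk, ck, drop = FALSE]
  i <- matrix(rk, length(rk), length(ck))
  l <- matrix(ck, length(rk), length(ck), byrow = TRUE)
  p <- P / nr
  ri <- rowSums(P); cl <- colSums(P)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  out <- c(sum(P / l^2) / nr,
           sum(P * l^2) / nr,
           sum(ri^2) / nr,
           sum(ri^2) / nr^2,
           sum(cl^2) / nr,
           sum(cl^2) / nr^2,
           nr / np,
           sum((i - mu_i)^2 * p),
           sum((l - mu_l)^2 * p),
           -sum(xlog2(p)),
           sum(P / i^2) / nr,
           sum(P * i^2) / nr,
           sum(P / (i^2 * l^2)) / nr,
           sum(P * i^2 / l^2) / nr,
           sum(P * l^2 / i^2) / nr,
           sum(P * i^2 * l^2) / nr)
  names(out) <- prefix
  out
}

gldm_features <- function(P) {
  nz <- sum(P)
  i <- row(P); d <- col(P)
  p <- P / nz
  ri <- rowSums(P); cd <- colSums(P)
  mu_i <- sum(i * p); mu_d <- sum(d * p)
  c(small_dependence_emphasis = sum(P / d^2) / nz,
    large_dependence_emphasis = sum(P * d^2) / nz,
    gray_level_nonuniformity = sum(ri^2) / nz,
    dependence_nonuniformity = sum(cd^2) / nz,
    dependence_nonuniformity_normalized = sum(cd^2) / nz^2,
    gray_level_variance = sum((i - mu_i)^2 * p),
    dependence_variance = sum((d - mu_d)^2 * p),
    dependence_entropy = -sum(xlog2(p)),
    low_gray_level_emphasis = sum(P / i^2) / nz,
    high_gray_level_emphasis = sum(P * i^2) / nz,
    small_dependence_low_gray_level_emphasis = sum(P / (i^2 * d^2)) / nz,
    small_dependence_high_gray_level_emphasis = sum(P * i^2 / d^2) / nz,
    large_dependence_low_gray_level_emphasis = sum(P * d^2 / i^2) / nz,
    large_dependence_high_gray_level_emphasis = sum(P * i^2 * d^2) / nz)
}

ngtdm_features <- function(M, np) {
  n_i <- M[, 1]; s_i <- M[, 2]
  nv <- sum(n_i)
  p_i <- n_i / nv
  lev <- seq_len(nrow(M))
  act <- p_i > 0
  ngp <- sum(act)
  coarseness <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contrast <- 0
  if (ngp > 1) {
    ii <- outer(lev[act], lev[act], `-`)^2
    pp <- outer(p_i[act], p_i[act])
    contrast <- sum(pp * ii) / (ngp * (ngp - 1)) * sum(s_i) / nv
  }
  denom <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], `-`)))
  busyness <- if (denom > 0) sum(p_i * s_i) / denom else 0
  complexity <- 0
  strength <- 0
  if (ngp > 1) {
    la <- lev[act]; pa <- p_i[act]; sa <- s_i[act]
    A <- abs(outer(la, la, `-`))
    num <- outer(pa * sa, pa * sa, `+`)
    den <- outer(pa, pa, `+`)
    complexity <- sum(A * num / den) / nv
    strength <- if (sum(s_i) > 0)
      sum(outer(pa, pa, `+`) * outer(la, la, `-`)^2) / sum(s_i) else 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
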