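#' Habitat clustering configuration
#'
#' @param window_edge Odd sliding-window edge length in voxels (default 3,
#'   i.e. a 3x3x3 neighborhood).
#' @param k Number of habitats (default 3).
#' @param seed Integer seed for K-means refinement.
#' @param standardize Z-score the 19 feature channels before clustering.
#' @return A `habitat_config` list.
#' @export
habitat_config <- function(window_edge = 3L, k = 3L, seed = 1L,
                           standardize = TRUE) {
  if (window_edge < 3L || window_edge %% 2L == 0L)
    stop("window_edge must be odd and >= 3")
  if (k < 2L) stop("k must be >= 2")
  structure(list(window_edge = as.integer(window_edge), k = as.integer(k),
                 seed = as.integer(seed), standardize = standardize),
            class = "habitat_config")
}

#' Names of the 19 local first-order feature channels
#' @return Character vector of length 19.
#' @export
local_feature_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
    "mean", "median", "iqr", "range", "mad", "rmad", "rms", "sd",
    "skewness", "kurtosis", "variance", "uniformity")
}

#' Voxel-wise local first-order features over a sliding window
#'
#' For every in-mask voxel, the 19 first-order statistics of its in-mask
#' 3x3x3 (by default) neighborhood. Entropy and uniformity are computed on
#' the fixed-bin-width discretized values so they are consistent with the
#' global discretization. Voxels whose neighborhood holds fewer than 2
#' in-mask voxels are flagged (NA rows) and assigned post hoc by
#' [cluster_habitats()].
#'
#' @param vol A clipped, resampled `ct_volume`.
#' @param mask A `mask_volume` on the same grid.
#' @param cfg A [habitat_config()].
#' @param pre A [preprocess_config()] supplying the discretization.
#' @return A `voxel_features` object: `values` (n_voxels x 19 matrix),
#'   `index` (linear voxel indices), `hu` (voxel HU), `dim`, `spacing`.
#' @export
local_voxel_features <- function(vol, mask, cfg = habitat_config(),
                                 pre = preprocess_config()) {
  check_aligned(vol, mask)
  if (sum(mask$values) == 0L) stop("mask is empty")
  disc <- discretize(vol, mask, pre)
  half <- (cfg$window_edge - 1L) %/% 2L
  res <- cpp_local_stats(as.numeric(vol$values),
                         as.integer(disc$binned),
                         as.integer(mask$values),
                         dim(vol$values),
                         prod(vol$spacing), disc$n_bins, half)
  stats <- res$stats
  colnames(stats) <- local_feature_names()
  idx <- res$index + 1L  # C++ indices are 0-based
  structure(list(values = stats, index = idx,
                 hu = as.numeric(vol$values)[idx],
                 n_in = res$n_in, dim = dim(vol$values),
                 spacing = vol$spacing),
            class = "voxel_features")
}

#' @export
print.voxel_features <- function(x, ...) {
  cat("<voxel_features> ", nrow(x$values), " voxels x ", ncol(x$values),
      " channels\n", sep = "")
  invisible(x)
}

# Deterministic seeding along the intensity axis: centers start at the
# feature vectors of the voxels sitting at the k evenly spaced quantiles of
# the window-mean HU channel. Habitats are intensity-ordered structures, so
# this puts one seed per putative compartment, and the init is invariant to
# voxel ordering (up to exact ties in the mean channel).
quantile_hu_centers <- function(x, mean_col, k) {
  qs <- stats::quantile(mean_col, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE)
  idx <- vapply(qs, function(q) which.min(abs(mean_col - q)), integer(1))
  x[idx, , drop = FALSE]
}

#' Partition a tumor into habitats by K-means on local features
#'
#' Channels are z-scored (population SD) when `cfg$standardize` is on, then
#' clustered with Lloyd's K-means from deterministic intensity-quantile
#' seeds.
#' Final labels 1..k are ordered by ascending cluster mean of the mean-HU
#' channel, so label identity is reproducible. Flagged voxels (degenerate
#' neighborhoods) are assigned to the cluster with the nearest mean HU.
#'
#' @param features A `voxel_features` object.
#' @param cfg A [habitat_config()].
#' @return A `habitat_map`: integer array, 0 outside the tumor, 1..k inside.
#' @export
cluster_habitats <- function(features, cfg = habitat_config()) {
  x <- features$values
  ok <- stats::complete.cases(x)
  xf <- x[ok, , drop = FALSE]
  if (nrow(xf) < cfg$k) stop("fewer usable voxels than clusters")
  keep <- apply(xf, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("fewer distinct feature vectors than clusters")
  mean_col <- xf[, "mean"]
  if (cfg$standardize) {
    xs <- scale(xf[, keep, drop = FALSE])
  } else {
    xs <- xf[, keep, drop = FALSE]
  }
  if (nrow(unique(xs)) < cfg$k)
    stop("fewer distinct feature vectors than clusters")
  set.seed(cfg$seed)
  init <- quantile_hu_centers(xs, mean_col, cfg$k)
  if (nrow(unique(init)) < cfg$k)
    init <- xs[!duplicated(xs), , drop = FALSE][seq_len(cfg$k), , drop = FALSE]
  km <- suppressWarnings(
    stats::kmeans(xs, centers = init, iter.max = 100L, algorithm = "Lloyd"))
  cl <- km$cluster
  # order labels by ascending mean HU of the cluster
  hu_means <- vapply(seq_len(cfg$k), function(j) mean(mean_col[cl == j]),
                     numeric(1))
  relabel <- match(seq_len(cfg$k), order(hu_means))
  cl <- relabel[cl]
  out <- array(0L, features$dim)
  out[features$index[ok]] <- cl
  if (any(!ok)) {
    cl_hu <- vapply(seq_len(cfg$k), function(j)
      mean(features$hu[ok][cl == j]), numeric(1))
    for (i in which(!ok)) {
      out[features$index[i]] <- which.min(abs(features$hu[i] - cl_hu))
    }
  }
  structure(out, class = "habitat_map", spacing = features$spacing,
            k = cfg$k)
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- table(factor(x[x > 0], levels = seq_len(attr(x, "k"))))
  cat("<habitat_map> k = ", attr(x, "k"), "; voxels per habitat: ",
      paste(as.integer(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Split a habitat map into one binary mask per habitat
#'
#' The returned masks are pairwise disjoint and their union is the tumor ROI.
#'
#' @param h A `habitat_map`.
#' @return Named list of `mask_volume`s (`habitat_1` ... `habitat_k`).
#' @export
habitat_masks <- function(h) {
  k <- attr(h, "k")
  sp <- attr(h, "spacing")
  labs <- seq_len(k)
  out <- lapply(labs, function(j) {
    m <- (unclass(h) == j) * 1L
    dim(m) <- dim(h)
    mask_volume(m, sp)
  })
  names(out) <- paste0("habitat_", labs)
  out
}

#' Adjusted Rand index between two label maps
#'
#' Agreement between two partitions corrected for chance; 1 is identity,
#' 0 is the chance level.
#'
#' @param a,b Integer label vectors (or arrays) of equal length; zeros
#'   (background) are dropped where both are zero.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  keep <- !(a == 0L & b == 0L)
  a <- a[keep]; b <- b[keep]
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Mean silhouette width of a clustering
#'
#' @param x Feature matrix (rows = points).
#' @param cl Integer cluster labels.
#' @param max_points Subsample cap for the O(n^2) distance matrix.
#' @param seed Seed for the subsample.
#' @return Mean silhouette width.
#' @export
mean_silhouette <- function(x, cl, max_points = 1500L, seed = 1L) {
  n <- nrow(x)
  if (n > max_points) {
    set.seed(seed)
    sel <- sort(sample.int(n, max_points))
    x <- x[sel, , drop = FALSE]; cl <- cl[sel]
  }
  d <- as.matrix(stats::dist(x))
  ks <- sort(unique(cl))
  s <- numeric(length(cl))
  for (i in seq_along(cl)) {
    own <- cl[i]
    a <- mean(d[i, cl == own & seq_along(cl) != i])
    if (!is.finite(a)) { s[i] <- 0; next }
    b <- min(vapply(ks[ks != own], function(j) mean(d[i, cl == j]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
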