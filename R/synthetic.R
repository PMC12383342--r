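#' Synthetic cohort configuration
#'
#' Describes a phantom CT cohort with planted intratumoral subregions. Each
#' tumor is an ellipsoid layered along its major axis into `n_subregions`
#' compartments — by default a low-HU necrotic pole, an intermediate-HU
#' tumor body, and a high-HU enhancing pole — each textured with a Gaussian
#' random field of compartment-specific amplitude and correlation length,
#' and blended through a partial-volume ramp at the interfaces. Labels are
#' drawn from a known logistic model over latent image features (core volume
#' fraction, enhancing-pole intensity and heterogeneity, tumor-body
#' enhancement) and clinical covariates (MLNSD, age, treatment), so
#' downstream models have a recoverable target.
#'
#' Compartment means are separated by more than 3 within-compartment SDs by
#' default, so habitat clustering has recoverable signal.
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence Target marginal probability of a positive label.
#' @param volume_shape Integer voxel dimensions of each CT volume.
#' @param voxel_spacing_mm Voxel spacing in mm.
#' @param n_subregions Number of planted compartments (innermost first).
#' @param subregion_params List with one entry per compartment:
#'   `mean_hu`, `sd_hu`, `corr_len` (texture correlation length, voxels).
#' @param effect_vector Named log-odds coefficients on the standardized
#'   latent features `core_fraction`, `rim_hu`, `body_hu`, `rim_texture`,
#'   `mlnsd`, `age`, `treatment`.
#' @param tumor_radius_mm Range of the tumor's largest semi-axis in mm.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          prevalence = 0.3,
                          volume_shape = c(64L, 64L, 64L),
                          voxel_spacing_mm = c(1, 1, 1),
                          n_subregions = 3L,
                          subregion_params = NULL,
                          effect_vector = c(core_fraction = 0.2,
                                            rim_hu = 0.2,
                                            body_hu = 2.0,
                                            rim_texture = 0.5,
                                            mlnsd = 0.6,
                                            age = -0.4,
                                            treatment = -0.5),
                          tumor_radius_mm = c(9, 14),
                          seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (any(volume_shape <= 0)) stop("volume_shape must be positive")
  if (n_subregions < 1L) stop("n_subregions must be >= 1")
  if (is.null(subregion_params)) {
    base <- list(
      list(mean_hu = 15,  sd_hu = 5,  corr_len = 3.0),   # necrotic core
      list(mean_hu = 85,  sd_hu = 12, corr_len = 2.0),   # periphery
      list(mean_hu = 175, sd_hu = 24, corr_len = 0.8))   # enhancing rim
    if (n_subregions == 3L) {
      subregion_params <- base
    } else {
      hus <- seq(15, 175, length.out = n_subregions)
      subregion_params <- lapply(seq_len(n_subregions), function(i) {
        list(mean_hu = hus[i], sd_hu = 5 + 9 * (i - 1),
             corr_len = 3 / i)
      })
    }
  }
  if (length(subregion_params) != n_subregions)
    stop("subregion_params must have one entry per subregion")
  if (max(tumor_radius_mm) * 2 >= min(volume_shape * voxel_spacing_mm) - 6)
    stop("volume too small to contain the requested tumor")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence,
                 volume_shape = as.integer(volume_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_subregions = as.integer(n_subregions),
                 subregion_params = subregion_params,
                 effect_vector = effect_vector,
                 tumor_radius_mm = tumor_radius_mm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Stationary Gaussian random field: smoothed white noise rescaled to unit SD.
grf_noise <- function(dims, corr_len) {
  z <- array(stats::rnorm(prod(dims)), dims)
  if (corr_len > 0) {
    k <- gaussian_kernel(corr_len / 2)
    z <- array(cpp_sep_conv3d(z, as.integer(dims), k, k, k), dims)
    z <- z / stats::sd(z)
  }
  z
}

# Latent standardization constants for the label model: fixed by design so
# that effect_vector coefficients are interpretable and recoverable.
latent_scale <- function() {
  list(core_fraction = c(0.315, 0.078), rim_hu = c(175, 5),
       body_hu = c(0, 9.815), rim_texture = c(0.75, 0.1443), mlnsd = c(8, 3), age = c(60, 8),
       treatment = c(0.5, 0.5))
}

#' Generate a synthetic phantom cohort
#'
#' Deterministic given the config (including its seed). Returns a list of
#' patients, each holding a `ct` volume, a `mask`, the ground-truth
#' `true_habitat` label map, a one-row `clinical` tibble, the binary `label`,
#' and the latent features that generated it.
#'
#' @param config A [cohort_config()].
#' @param images Generate voxel data? With `images = FALSE` only the latent
#'   features, clinical covariates and labels are drawn (a much faster mode
#'   for studying the label model; its random stream differs from the full
#'   mode).
#' @return A list of class `synthetic_cohort`.
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  sc <- latent_scale()

  patients <- vector("list", n)
  lat <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("core_fraction", "rim_hu", "body_hu",
                                        "rim_texture", "mlnsd", "age",
                                        "treatment")))
  for (i in seq_len(n)) {
    p <- simulate_patient_image(config, images = images)
    lat[i, ] <- c(p$latent$core_fraction, p$latent$rim_hu,
                  p$latent$body_hu, p$latent$rim_texture, p$latent$mlnsd,
                  p$latent$age, p$latent$treatment)
    patients[[i]] <- p
  }
  z <- sapply(colnames(lat), function(v) (lat[, v] - sc[[v]][1]) / sc[[v]][2])
  eta <- as.numeric(z %*% config$effect_vector[colnames(lat)])
  # intercept calibrated so the cohort-average risk hits the target prevalence
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                         config$prevalence,
                       interval = c(-30, 30))$root
  probs <- stats::plogis(b0 + eta)
  labels <- stats::rbinom(n, 1L, probs)

  for (i in seq_len(n)) {
    patients[[i]]$label <- labels[i]
    patients[[i]]$risk <- probs[i]
    patients[[i]]$clinical$label <- labels[i]
    patients[[i]]$id <- sprintf("P%04d", i)
    patients[[i]]$clinical$patient_id <- sprintf("P%04d", i)
  }
  structure(patients, class = "synthetic_cohort",
            intercept = b0, config = config)
}

simulate_patient_image <- function(config, images = TRUE) {
  d <- config$volume_shape
  sp <- config$voxel_spacing_mm
  ns <- config$n_subregions
  rr <- config$tumor_radius_mm

  # ellipsoid geometry: largest semi-axis in mm, others shrunk
  a_mm <- stats::runif(1, rr[1], rr[2])
  axes_mm <- a_mm * c(1, stats::runif(1, 0.7, 0.9), stats::runif(1, 0.6, 0.85))
  axes_mm <- sample(axes_mm)   # random orientation along grid axes
  center <- d / 2 + stats::runif(3, -2, 2)

  core_fraction <- stats::runif(1, 0.18, 0.45)
  rim_hu_shift <- stats::rnorm(1, 0, 5)
  rim_tex_mult <- stats::runif(1, 0.5, 1.0)   # rim heterogeneity latent
  body_hu_shift <- stats::runif(1, -17, 17)   # tumor-body enhancement latent

  latent0 <- list(core_fraction = core_fraction,
                  rim_hu = config$subregion_params[[ns]]$mean_hu +
                    rim_hu_shift,
                  body_hu = body_hu_shift,
                  rim_texture = rim_tex_mult)
  if (!images) {
    latent <- c(latent0,
                list(mlnsd = stats::rgamma(1, shape = 7, scale = 8 / 7),
                     age = stats::rnorm(1, 60, 8),
                     treatment = stats::rbinom(1, 1, 0.5)))
    clinical <- make_clinical_row(latent, axes_mm)
    return(list(ct = NULL, mask = NULL, true_habitat = NULL,
                clinical = clinical, latent = latent))
  }

  co <- lapply(1:3, function(ax) ((seq_len(d[ax]) - center[ax]) * sp[ax]))
  RX <- array(co[[1]] / axes_mm[1], d)
  RY <- array(rep(co[[2]], each = d[1]) / axes_mm[2], d)
  RZ <- array(rep(co[[3]], each = d[1] * d[2]) / axes_mm[3], d)
  rho <- sqrt(RX^2 + RY^2 + RZ^2)
  mask <- (rho <= 1) * 1L

  # compartments layered along a random axis (necrotic pole, intermediate
  # body, enhancing pole), emulating the proximal-to-distal heterogeneity of
  # an elongated tumor. Layering means only intensity-adjacent compartments
  # share an interface, which keeps partial-volume transition voxels within
  # the intensity range spanned by their two neighbors. Cuts are placed at
  # volume quantiles: the first (core) layer takes the sampled latent
  # core_fraction of the voxels, the remaining layers split the rest evenly.
  inmask <- which(mask == 1L)
  P <- cbind(RX[inmask], RY[inmask], RZ[inmask])
  if (ns == 1L) {
    shell_lab <- rep(1L, length(inmask))
  } else {
    # layer along the major axis (the proximal-distal direction of an
    # elongated tumor), where compartment cross-sections are smallest
    u <- as.numeric(seq_len(3) == which.max(axes_mm))
    proj <- as.numeric(P %*% (u * axes_mm))
    fr <- c(core_fraction,
            rep((1 - core_fraction) / (ns - 1), ns - 1))
    cuts <- stats::quantile(proj, cumsum(fr)[-ns])
    shell_lab <- 1L + rowSums(outer(proj, cuts, `>`))
  }
  shell <- array(0L, d)
  shell[inmask] <- shell_lab

  # compose HU by mixing the background and per-compartment textured fields
  # with Gaussian-smoothed compartment weights: emulates the scanner's
  # partial-volume blur and infiltrative transitions, so compartment
  # interfaces are ramps rather than step edges. Truth labels stay crisp.
  # Compartment fields and blending are computed on the tumor bounding box
  # (plus margin) only; the soft-tissue background spans the whole volume.
  vals <- 40 + 15 * grf_noise(d, 4)          # mediastinal soft tissue
  w3 <- arrayInd(inmask, d)
  lo <- pmax(apply(w3, 2, min) - 5L, 1L)
  hi <- pmin(apply(w3, 2, max) + 5L, d)
  bd <- hi - lo + 1L
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  shell_b <- sub(shell)
  kblend <- gaussian_kernel(0.9)
  wsum <- array(0, bd); acc <- array(0, bd)
  for (s in 0:ns) {
    f_s <- if (s == 0) {
      sub(vals)
    } else {
      pars <- config$subregion_params[[s]]
      mu <- pars$mean_hu + if (s == ns) rim_hu_shift else 0
      if (ns >= 2 && s == ns - 1) mu <- mu + body_hu_shift
      sd_s <- pars$sd_hu * if (s == ns) rim_tex_mult else 1
      mu + sd_s * grf_noise(bd, pars$corr_len)
    }
    ind <- (shell_b == s) * 1
    w <- array(cpp_sep_conv3d(ind, as.integer(bd), kblend, kblend, kblend),
               bd)
    acc <- acc + w * f_s
    wsum <- wsum + w
  }
  vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- acc / wsum
  vals <- pmin(pmax(vals, -1024), 3071)

  latent <- c(latent0,
              list(mlnsd = stats::rgamma(1, shape = 7, scale = 8 / 7),
                   age = stats::rnorm(1, 60, 8),
                   treatment = stats::rbinom(1, 1, 0.5)))
  clinical <- make_clinical_row(latent, axes_mm)

  list(ct = ct_volume(vals, sp), mask = mask_volume(mask, sp),
       true_habitat = structure(shell * mask, class = "habitat_map",
                                spacing = sp, k = ns),
       clinical = clinical, latent = latent)
}

# clinical covariates loosely matched to a thoracic-oncology cohort; only
# age, treatment and MLNSD carry label signal (through the latents)
make_clinical_row <- function(latent, axes_mm) {
  tibble::tibble(
    patient_id = NA_character_,
    age = round(latent$age, 1),
    sex = stats::rbinom(1, 1, 0.8),
    smoking = stats::rbinom(1, 1, 0.55),
    drinking = stats::rbinom(1, 1, 0.5),
    cT = sample(1:4, 1, prob = c(0.1, 0.3, 0.45, 0.15)),
    cN = sample(0:3, 1, prob = c(0.25, 0.4, 0.25, 0.1)),
    treatment = factor(ifelse(latent$treatment == 1, "NACRT", "NACT"),
                       levels = c("NACT", "NACRT")),
    TMD_mm = round(2 * max(axes_mm) + stats::rnorm(1, 0, 1), 1),
    MLNSD_mm = round(latent$mlnsd, 1),
    enhancement = stats::rbinom(1, 1, 0.5),
    MLNF = stats::rbinom(1, 1, 0.3),
    MLNEV = stats::rbinom(1, 1, 0.25),
    MLNN = stats::rbinom(1, 1, 0.2),
    label = NA_integer_)
}

#' Clinical covariate table of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble with one row per patient, covariates and the binary label.
#' @export
cohort_clinical <- function(cohort) {
  dplyr::bind_rows(lapply(cohort, function(p) p$clinical))
}

#' @rdname cohort_clinical
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(p) as.integer(p$label), integer(1))
}

#' Rater-perturbed duplicate of a segmentation mask
#'
#' Simulates inter-rater boundary disagreement by `round(magnitude)` rounds of
#' random morphological jitter: each round dilates or erodes a random subset
#' of boundary voxels. Expected Dice with the input decreases monotonically in
#' `magnitude`; `magnitude = 0` returns the input unchanged.
#'
#' @param mask A `mask_volume`.
#' @param magnitude Jitter strength in voxel units (>= 0).
#' @param seed Integer seed.
#' @return A perturbed `mask_volume` of identical shape.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (sum(mask$values) == 0L) stop("mask is empty")
  rounds <- round(magnitude)
  if (rounds == 0) return(mask)
  set.seed(seed)
  m <- mask$values
  for (r in seq_len(rounds)) {
    if (stats::runif(1) < 0.5) {
      cand <- shift_union(m) & !m      # outward shell
      sel <- which(cand)
      sel <- sel[stats::runif(length(sel)) < 0.5]
      m[sel] <- 1L
    } else {
      inner <- shift_intersect(m)
      cand <- m == 1L & !inner         # inner boundary shell
      sel <- which(cand)
      sel <- sel[stats::runif(length(sel)) < 0.5]
      m2 <- m; m2[sel] <- 0L
      if (sum(m2) >= 8L) m <- m2
    }
  }
  dim(m) <- dim(mask$values)
  storage.mode(m) <- "integer"
  mask_volume(m, mask$spacing, mask$origin)
}

shift_axis <- function(m, ax, by) {
  d <- dim(m); out <- array(0L, d)
  idx_src <- lapply(d, seq_len); idx_dst <- idx_src
  n <- d[ax]
  if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
  else if (by < 0) { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

shift_union <- function(m) {
  u <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) u <- u | shift_axis(m, ax, by)
  u
}

shift_intersect <- function(m) {
  u <- m == 1L
  for (ax in 1:3) for (by in c(-1L, 1L)) u <- u & (shift_axis(m, ax, by) == 1L)
  u
}

#' Dice similarity of two binary masks
#' @param a,b `mask_volume`s on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks as NIfTI, the clinical table as CSV, and ground truth
#' (labels, latents, generator intercept) as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    write_volume(p$ct, file.path(dir, paste0(p$id, "_ct.nii.gz")))
    write_volume(p$mask, file.path(dir, paste0(p$id, "_mask.nii.gz")))
    h <- p$true_habitat
    write_volume(list(values = unclass(h), spacing = attr(h, "spacing")),
                 file.path(dir, paste0(p$id, "_habitat.nii.gz")))
  }
  utils::write.csv(cohort_clinical(cohort),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  truth <- list(intercept = attr(cohort, "intercept"),
                labels = cohort_labels(cohort),
                latents = lapply(cohort, function(p) p$latent))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<synthetic_cohort> ", length(x), " patients; prevalence ",
      round(mean(cohort_labels(x)), 3), "; volume ",
      paste(cfg$volume_shape, collapse = "x"), "; seed ", cfg$seed, "\n",
      sep = "")
  invisible(x)
}
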