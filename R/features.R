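#' Extract the handcrafted radiomic feature bank from a region
#'
#' With the full 20-image [filter_bank()] this yields 1834 named features:
#' 14 geometry features (computed once, on the mask), 360 intensity features
#' (18 first-order statistics per derived image) and 1460 texture features
#' (73 per derived image). The original image is discretized with the
#' fixed-HU-bin-width rule; derived images, whose scale is not HU, with a
#' fixed 32-bin count. Input is expected to be clipped and resampled (see
#' [clip_hu()], [resample_isotropic()]).
#'
#' @param vol A preprocessed `ct_volume`.
#' @param mask A `mask_volume` on the same grid.
#' @param bank A [filter_bank()].
#' @param pre A [preprocess_config()].
#' @param derived_bins Bin count for non-HU derived images.
#' @return Named numeric feature vector, ordered shape, intensity, texture.
#' @export
extract_features <- function(vol, mask, bank = filter_bank(),
                             pre = preprocess_config(),
                             derived_bins = 32L) {
  cr <- crop_to_mask(vol, mask, margin = 3L)
  v <- cr$vol; m <- cr$mask
  inmask <- m$values == 1L
  vv <- prod(v$spacing)

  shape <- shape_features(m)
  names(shape) <- paste0("shape_", names(shape))

  fo <- list(); tex <- list()
  for (f in names(bank)) {
    dv <- apply_filter_values(f, v$values, v$spacing)
    if (f == "original") {
      binned <- discretize(v, m, pre)$binned
      nb <- pre$n_bins
    } else {
      binned <- discretize_fixed_count(dv, m$values, derived_bins)
      nb <- derived_bins
    }
    fo_f <- first_order_features(dv[inmask], binned[inmask],
                                 voxel_volume = vv,
                                 include_total_energy = FALSE)
    fo[[f]] <- stats::setNames(fo_f, paste0("fo_", f, "_", names(fo_f)))
    tex_f <- texture_features(binned, nb)
    tex[[f]] <- stats::setNames(tex_f, paste0("tex_", f, "_", names(tex_f)))
  }
  c(shape, unlist(unname(fo)), unlist(unname(tex)))
}

#' @rdname extract_features
#' @export
extract_intra_features <- extract_features

#' Habitat-aggregated radiomic features
#'
#' Extracts the full feature bank from each habitat subregion and returns the
#' feature-wise arithmetic mean across subregions. Averaging makes the result
#' invariant to habitat label permutation, which matters because unsupervised
#' cluster identities are not comparable across patients. Subregions smaller
#' than `min_voxels` are excluded from the mean.
#'
#' @param vol A preprocessed `ct_volume`.
#' @param habitat A `habitat_map` from [cluster_habitats()].
#' @inheritParams extract_features
#' @param min_voxels Minimum subregion size to enter the mean.
#' @return Named numeric feature vector (same names as [extract_features()]).
#' @export
extract_habitat_features <- function(vol, habitat, bank = filter_bank(),
                                     pre = preprocess_config(),
                                     derived_bins = 32L, min_voxels = 10L) {
  masks <- habitat_masks(habitat)
  sizes <- vapply(masks, function(m) sum(m$values), numeric(1))
  use <- sizes >= min_voxels
  if (!any(use)) stop("all habitat subregions below min_voxels")
  vecs <- lapply(masks[use], function(m)
    extract_features(vol, m, bank, pre, derived_bins))
  Reduce(`+`, vecs) / length(vecs)
}

#' Feature metadata for a filter bank
#'
#' @inheritParams extract_features
#' @return Tibble with columns `feature`, `category`, `filter`, `family`.
#' @export
feature_metadata <- function(bank = filter_bank()) {
  fam <- function(nm) {
    dplyr::case_when(grepl("_glcm_", nm) ~ "glcm",
                     grepl("_glrlm_", nm) ~ "glrlm",
                     grepl("_glszm_", nm) ~ "glszm",
                     grepl("_gldm_", nm) ~ "gldm",
                     grepl("_ngtdm_", nm) ~ "ngtdm",
                     TRUE ~ NA_character_)
  }
  shape_nm <- paste0("shape_", c("mesh_volume", "voxel_volume",
                                 "surface_area", "surface_volume_ratio",
                                 "sphericity", "max_3d_diameter",
                                 "max_2d_diameter_slice",
                                 "max_2d_diameter_column",
                                 "max_2d_diameter_row", "major_axis_length",
                                 "minor_axis_length", "least_axis_length",
                                 "elongation", "flatness"))
  fo_nm <- unlist(lapply(names(bank), function(f)
    paste0("fo_", f, "_",
           setdiff(local_feature_names(), "total_energy"))))
  tex_base <- names(texture_features(array(c(1L, 2L, 1L, 2L, 0L, 0L, 0L, 0L),
                                           c(2, 2, 2)), 2L))
  tex_nm <- unlist(lapply(names(bank), function(f)
    paste0("tex_", f, "_", tex_base)))
  tibble::tibble(
    feature = c(shape_nm, fo_nm, tex_nm),
    category = c(rep("geometry", length(shape_nm)),
                 rep("intensity", length(fo_nm)),
                 rep("texture", length(tex_nm))),
    filter = c(rep("original", length(shape_nm)),
               rep(names(bank), each = 18L),
               rep(names(bank), each = 73L)),
    family = fam(c(shape_nm, fo_nm, tex_nm)))
}

#' Per-patient feature tables for a cohort
#'
#' Runs the whole-ROI (`intra`) or habitat-aggregated (`habitat`) extraction
#' over a synthetic cohort (or any list of patients with `ct`, `mask`, `id`),
#' returning a tidy patients-by-features tibble.
#'
#' @param cohort List of patients (`ct`, `mask`, `id` fields).
#' @param mode `"intra"` or `"habitat"`.
#' @inheritParams extract_features
#' @param hcfg A [habitat_config()] (habitat mode only).
#' @param clip Clip volumes to the HU window first (on by default).
#' @return Tibble: `patient_id` plus one column per feature, with a
#'   `provenance` attribute (`"Intra"` or `"Habitat"`).
#' @export
cohort_feature_table <- function(cohort, mode = c("intra", "habitat"),
                                 bank = filter_bank(),
                                 pre = preprocess_config(),
                                 hcfg = habitat_config(), clip = TRUE) {
  mode <- match.arg(mode)
  rows <- lapply(cohort, function(p) {
    v <- if (clip) clip_hu(p$ct, pre) else p$ct
    vec <- if (mode == "intra") {
      extract_features(v, p$mask, bank, pre)
    } else {
      vf <- local_voxel_features(v, p$mask, hcfg, pre)
      h <- cluster_habitats(vf, hcfg)
      extract_habitat_features(v, h, bank, pre)
    }
    tibble::as_tibble(as.list(vec)) |>
      dplyr::mutate(patient_id = p$id, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- if (mode == "intra") "Intra" else "Habitat"
  out
}
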