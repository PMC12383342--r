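test_that("the full bank yields exactly 1834 features split 14/360/1460", {
  p <- phantom_patient()
  v <- clip_hu(p$ct)
  fv <- extract_features(v, p$mask)
  expect_length(fv, 1834L)
  md <- feature_metadata()
  expect_identical(names(fv), md$feature)
  expect_equal(unname(table(md$category)[c("geometry", "intensity",
                                           "texture")]),
               c(14L, 360L, 1460L), ignore_attr = TRUE)
  expect_false(anyNA(fv))
  expect_false(any(duplicated(names(fv))))
  # determinism
  fv2 <- extract_features(v, p$mask)
  expect_identical(fv, fv2)
})

test_that("the filter bank holds exactly 20 derived images", {
  bank <- filter_bank()
  expect_length(bank, 20L)
  expect_equal(sum(startsWith(names(bank), "wavelet_")), 8L)
  expect_equal(sum(startsWith(names(bank), "log_sigma_")), 6L)
  expect_error(filter_bank("nonexistent_filter"), "unknown")
})

test_that("shape features follow closed-form geometry", {
  sph <- shape_features(make_sphere_mask(15, dims = c(40, 40, 40)))
  expect_length(sph, 14L)
  expect_gte(sph[["sphericity"]], 0.95)
  expect_lte(sph[["sphericity"]], 1.0)
  expect_lt(abs(sph[["mesh_volume"]] - 4 / 3 * pi * 15^3) /
              (4 / 3 * pi * 15^3), 0.05)
  expect_lt(abs(sph[["max_3d_diameter"]] - 30) / 30, 0.05)
  expect_lt(abs(sph[["major_axis_length"]] -
                  sph[["least_axis_length"]]) /
              sph[["major_axis_length"]], 0.05)

  cube <- shape_features(make_cube_mask(12))
  expect_lt(abs(cube[["mesh_volume"]] - 12^3) / 12^3, 0.05)
  expect_equal(cube[["elongation"]], 1, tolerance = 1e-6)

  expect_error(shape_features(mask_volume(array(c(1L, rep(0L, 26)),
                                                c(3, 3, 3)))),
               "too small")
})

test_that("shape depends on the mask only; intensity shifts move first-order", {
  p <- phantom_patient()
  v <- clip_hu(p$ct)
  bank <- filter_bank("original")
  f1 <- extract_features(v, p$mask, bank)
  v2 <- ct_volume(pmin(v$values + 10, 225), v$spacing)
  f2 <- extract_features(v2, p$mask, bank)
  shp <- startsWith(names(f1), "shape_")
  expect_identical(f1[shp], f2[shp])
  expect_equal(unname(f2["fo_original_mean"] - f1["fo_original_mean"]),
               10, tolerance = 0.2)
})

test_that("first-order statistics match hand computations", {
  fo <- first_order_features(c(0, 0, 4, 4), c(1, 1, 2, 2))
  expect_length(fo, 19L)
  expect_equal(fo[["mean"]], 2)
  expect_equal(fo[["variance"]], 4)       # population variance
  expect_equal(fo[["rms"]], sqrt(8))
  expect_equal(fo[["uniformity"]], 0.5)
  expect_equal(fo[["entropy"]], 1)
  expect_equal(fo[["energy"]], 32)
  expect_length(first_order_features(c(1, 2), c(1, 2),
                                     include_total_energy = FALSE), 18L)
  # constant ROI degenerates cleanly
  fc <- first_order_features(rep(3, 10), rep(1L, 10))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["skewness"]], 0)
  expect_error(first_order_features(numeric(0), integer(0)), "empty")
})

test_that("texture family returns 73 features and handles constant regions", {
  set.seed(2)
  b <- array(sample(1:6, 6^3, TRUE), c(6, 6, 6))
  tf <- texture_features(b, 6L)
  expect_length(tf, 73L)
  fams <- c(glcm = 22L, glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L)
  for (f in names(fams)) {
    expect_equal(sum(startsWith(names(tf), paste0(f, "_"))), fams[[f]])
  }
  # constant region: single co-occurrence cell
  bc <- array(1L, c(4, 4, 4))
  tc <- texture_features(bc, 4L)
  expect_equal(tc[["glcm_joint_entropy"]], 0)
  expect_equal(tc[["glcm_maximum_probability"]], 1)
  expect_equal(tc[["glszm_gray_level_variance"]], 0)
})

test_that("GLRLM long-run emphasis is anisotropic on a striped phantom", {
  # stripes constant along y: long runs along y, length-1 runs along x
  b <- array(0L, c(4, 4, 2))
  b[, , 1] <- rep(c(1L, 2L, 1L, 2L), times = 4)
  b[, , 2] <- b[, , 1]
  glrlm <- habitomics:::cpp_glrlm(as.integer(b), dim(b), 2L)
  # direction 1 = x (across stripes), direction 2 = y (along stripes)
  lre <- function(P) {
    l <- col(P)
    sum(P * l^2) / sum(P)
  }
  expect_gt(lre(glrlm[, , 2]), lre(glrlm[, , 1]))
  # hand-built oracle for the x direction: 16 runs of length 1 per slice
  expect_equal(sum(glrlm[, 1, 1]), 32)
  expect_equal(sum(glrlm[, , 1]), 32)
  # y direction: every column is a single run of length 4
  expect_equal(sum(glrlm[, 4, 2]), 8)
})

test_that("C++ texture features agree with the plain-R reference", {
  set.seed(5)
  b <- array(sample(0:7, 14^3, TRUE, prob = c(3, rep(1, 7))), c(14, 14, 14))
  glcm <- habitomics:::cpp_glcm(as.integer(b), dim(b), 7L)
  fc <- habitomics:::cpp_glcm_features(glcm, 7L)
  for (d in seq_len(13)) {
    fr <- habitomics:::glcm_features(glcm[, , d])
    expect_equal(unname(fc[, d]), unname(fr), tolerance = 1e-12)
  }
  glrlm <- habitomics:::cpp_glrlm(as.integer(b), dim(b), 7L)
  np <- sum(b > 0)
  fc2 <- habitomics:::cpp_run_features(glrlm, 7L, dim(glrlm)[2], np)
  for (d in seq_len(13)) {
    fr2 <- habitomics:::glrlm_features(glrlm[, , d], np)
    expect_equal(unname(fc2[, d]), unname(fr2), tolerance = 1e-12)
  }
})

test_that("direction-averaged texture is stable under 90-degree rotation", {
  co <- generate_cohort(cohort_config(1, seed = 33, volume_shape = c(48, 48, 48),
                                      tumor_radius_mm = c(8, 11)))
  p <- co[[1]]
  v <- clip_hu(p$ct)
  bank <- filter_bank("original")
  f1 <- extract_features(v, p$mask, bank)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  v2 <- ct_volume(rot(v$values), v$spacing)
  m2 <- mask_volume(rot(p$mask$values), p$mask$spacing)
  f2 <- extract_features(v2, m2, bank)
  tex <- grep("^tex_", names(f1), value = TRUE)
  rel <- abs(f2[tex] - f1[tex]) / pmax(abs(f1[tex]), 1e-8)
  expect_lt(median(rel), 0.02)
  expect_lt(max(rel), 0.05)
})

test_that("habitat aggregation is a label-invariant arithmetic mean", {
  p <- phantom_patient()
  v <- clip_hu(p$ct)
  vf <- local_voxel_features(v, p$mask)
  h <- cluster_habitats(vf)
  bank <- filter_bank("original")
  hv <- extract_habitat_features(v, h, bank)
  # label permutation leaves the aggregate unchanged
  perm <- unclass(h)
  perm[perm > 0] <- c(3L, 1L, 2L)[perm[perm > 0]]
  hperm <- structure(perm, class = "habitat_map",
                     spacing = attr(h, "spacing"), k = 3L)
  hv2 <- extract_habitat_features(v, hperm, bank)
  expect_equal(hv, hv2, tolerance = 1e-12)
  # the aggregate is the arithmetic mean of per-subregion vectors
  per <- sapply(habitat_masks(h), function(m)
    extract_features(v, m, bank))
  expect_equal(unname(hv), unname(rowMeans(per)), tolerance = 1e-12)
  # tiny subregions are excluded; all-tiny errors out
  expect_error(extract_habitat_features(v, h, bank, min_voxels = 1e6),
               "below min_voxels")
})
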