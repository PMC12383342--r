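test_that("central slice selection maximizes ROI area with low-index ties", {
  m <- array(0L, c(6, 6, 5))
  m[1:3, 1, 2] <- 1L   # area 3
  m[1:5, 1:2, 3] <- 1L # area 10
  m[1:4, 1, 4] <- 1L   # area 4
  expect_equal(select_central_slice(mask_volume(m)), 3L)
  # tie: two slices with equal area -> lower index
  m2 <- array(0L, c(4, 4, 4))
  m2[1:3, 1:2, 2] <- 1L
  m2[1:3, 1:2, 3] <- 1L
  expect_equal(select_central_slice(mask_volume(m2)), 2L)
  # sphere: equatorial slice
  sph <- make_sphere_mask(8, dims = c(25, 25, 25))
  expect_equal(select_central_slice(sph), 13L)  # equatorial slice
  expect_error(select_central_slice(mask_volume(array(0L, c(3, 3, 3)))),
               "empty")
})

test_that("stacks hold five 224x224 slices normalized to [-1, 1]", {
  p <- phantom_patient()
  st <- build_stack(clip_hu(p$ct), p$mask, id = "P1")
  expect_equal(dim(st$slices), c(224, 224, 5))
  expect_equal(st$offsets, c(-4L, -2L, 0L, 2L, 4L))
  expect_gte(min(st$slices), -1)
  expect_lte(max(st$slices), 1)
  # a slice attaining its own min and max maps them exactly to -1 and 1
  for (s in 1:5) {
    expect_equal(min(st$slices[, , s]), -1)
    expect_equal(max(st$slices[, , s]), 1)
  }
  # constant slice degenerates to all zeros
  v0 <- ct_volume(array(50, c(30, 30, 9)))
  m0 <- array(0L, c(30, 30, 9)); m0[10:20, 10:20, 5] <- 1L
  st0 <- build_stack(v0, mask_volume(m0))
  expect_true(all(st0$slices == 0))
})

test_that("stack construction shifts with the tumor (translation consistency)", {
  base <- array(0L, c(40, 40, 21))
  base[15:25, 15:25, 8:12] <- 1L
  v <- make_noisy_volume(mask_volume(base), seed = 6)
  st1 <- build_stack(clip_hu(v), mask_volume(base))
  shifted <- array(0L, c(40, 40, 21))
  shifted[15:25, 15:25, 10:14] <- 1L
  v2 <- ct_volume(v$values[, , c(19:21, 1:18)] * 0, v$spacing) # placeholder
  # translate the volume content by 2 slices along z
  vals2 <- array(0, c(40, 40, 21))
  vals2[, , 3:21] <- v$values[, , 1:19]
  v2 <- ct_volume(vals2, v$spacing)
  st2 <- build_stack(clip_hu(v2), mask_volume(shifted))
  expect_equal(st2$central, st1$central + 2L)
  expect_equal(st2$slices, st1$slices, tolerance = 1e-12)
})

test_that("the default registry trains 15 slice models deterministically", {
  co <- small_cohort()
  labels <- cohort_labels(co)
  stacks <- lapply(co, function(p) build_stack(clip_hu(p$ct), p$mask,
                                               id = p$id))
  models <- fit_slice_models(stacks, labels,
                             config = slice_train_config(seed = 4))
  expect_equal(length(models$models) * models$n_offsets, 15L)
  pm <- predict_matrix(models, stacks)
  expect_equal(nrow(pm), length(co) * 15L)
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  expect_identical(pm$label, as.integer(pm$prob >= 0.5))
  # determinism under the same seed (fresh stacks to defeat the cache)
  stacks2 <- lapply(co, function(p) build_stack(clip_hu(p$ct), p$mask,
                                                id = p$id))
  models2 <- fit_slice_models(stacks2, labels,
                              config = slice_train_config(seed = 4))
  pm2 <- predict_matrix(models2, stacks2)
  expect_equal(pm$prob, pm2$prob, tolerance = 1e-12)
  expect_error(fit_slice_models(stacks, rep(1, length(co))), "classes")
})

test_that("the reference backbone separates linearly separable slices", {
  # synthetic slices whose mean intensity carries the label
  set.seed(9)
  n <- 60
  labels <- rep(c(0, 1), each = n / 2)
  stacks <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(224^2, ifelse(labels[i] == 1, 0.4, -0.4), 0.3),
                   224, 224)
    structure(list(slices = array(rep(base, 5), c(224, 224, 5)),
                   offsets = c(-4L, -2L, 0L, 2L, 4L), central = 3L,
                   id = paste0("S", i),
                   cache = new.env(parent = emptyenv())),
              class = "slice_stack")
  })
  bk <- backbone_registry()["convnet_s"]
  models <- fit_slice_models(stacks, labels, backbones = bk,
                             config = slice_train_config(seed = 2))
  pm <- predict_matrix(models, stacks)
  acc <- mean((pm$prob >= 0.5) == (labels[match(pm$patient_id,
                                                paste0("S", 1:n))] == 1))
  expect_gte(acc, 0.95)
})

test_that("PLH histograms follow the documented binning", {
  pred <- tibble::tibble(
    patient_id = "A", backbone = "bk",
    offset = c(-4L, -2L, 0L, 2L, 4L),
    prob = c(0.1, 0.2, 0.9, 0.85, 0.5),
    label = as.integer(prob >= 0.5))
  ph <- plh_features(pred, bins = 5L)
  expect_equal(unname(unlist(ph[1, paste0("plh_bk_bin", 1:5)])),
               c(1, 1, 1, 0, 2))
  expect_equal(ph$plh_bk_npos[1], 3)
  # boundary: probability 1.0 lands in the top bin; counts always sum to 5
  pred2 <- dplyr::mutate(pred, prob = 1, label = 1L)
  ph2 <- plh_features(pred2, bins = 5L)
  expect_equal(ph2$plh_bk_bin5[1], 5)
  expect_equal(sum(ph[1, paste0("plh_bk_bin", 1:5)]), 5)
})

test_that("BoW TF-IDF matches the stated formula on a toy corpus", {
  # doc1 tokens {A, A, B}, doc2 {B}: encode via two backbones' deciles
  pred <- tibble::tibble(
    patient_id = c("d1", "d1", "d1", "d2"),
    backbone = c("m", "m", "m", "m"),
    offset = c(-4L, -2L, 0L, 0L),
    prob = c(0.05, 0.05, 0.95, 0.95),
    label = as.integer(prob >= 0.5))
  bw <- bow_features(pred, deciles = 10L)
  tokA <- "bow_m_d1"; tokB <- "bow_m_d10"
  expect_setequal(bw$vocabulary, c(tokA, tokB))
  # idf with N=2: A appears in 1 doc, B in 2
  idfA <- log(3 / 2) + 1; idfB <- log(3 / 3) + 1
  raw1 <- c(2 * idfA, 1 * idfB)
  expected1 <- raw1 / sqrt(sum(raw1^2))
  expect_equal(unname(unlist(bw$train[bw$train$patient_id == "d1",
                                      c(tokA, tokB)])),
               expected1, tolerance = 1e-12)
  expect_equal(bw$train[[tokA]][bw$train$patient_id == "d2"], 0)
  # row norms are 1
  m <- as.matrix(bw$train[, bw$vocabulary])
  expect_equal(unname(rowSums(m^2)), c(1, 1), tolerance = 1e-10)
})

test_that("MIL fusion concatenates with unique namespaced columns", {
  co <- small_cohort()[1:10]
  labels <- cohort_labels(small_cohort())[1:10]
  stacks <- lapply(co, function(p) build_stack(clip_hu(p$ct), p$mask,
                                               id = p$id))
  models <- fit_slice_models(stacks, labels,
                             config = slice_train_config(seed = 1))
  pm <- predict_matrix(models, stacks)
  plh <- plh_features(pm)
  bw <- bow_features(pm)
  fused <- fuse_mil(plh, bw$train)
  expect_equal(ncol(fused) - 1L, (ncol(plh) - 1L) + (ncol(bw$train) - 1L))
  expect_false(any(duplicated(names(fused))))
  # PLH/BoW are slice-order invariant (set statistics)
  pm_shuf <- pm[sample(nrow(pm)), ]
  expect_equal(dplyr::arrange(plh_features(pm_shuf), patient_id),
               dplyr::arrange(plh, patient_id))
  expect_error(fuse_mil(plh, dplyr::mutate(bw$train,
                                           patient_id = paste0(patient_id,
                                                               "x"))),
               "differ")
})

test_that("a constant-probability stub backbone degrades gracefully", {
  pred <- tidyr::expand_grid(patient_id = c("a", "b", "c"),
                             backbone = c("stub1", "stub2", "stub3"),
                             offset = c(-4L, -2L, 0L, 2L, 4L)) |>
    dplyr::mutate(prob = 0.5, label = 1L)
  plh <- plh_features(pred)
  bins <- as.matrix(plh[, grep("bin", names(plh))])
  expect_true(all(rowSums(bins) == 15))
  expect_true(all(bins[, grep("bin3", colnames(bins))] == 5))
  bw <- bow_features(pred)
  expect_length(bw$vocabulary, 3L)   # one token per backbone
  fused <- fuse_mil(plh, bw$train)
  expect_equal(nrow(fused), 3L)
})
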