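#' Central-slice selection for 2.5D stacks
#'
#' Index of the axial slice with the largest in-mask cross-sectional area;
#' ties go to the lower index.
#'
#' @param mask A `mask_volume`.
#' @return Integer axial (third-axis) slice index.
#' @export
select_central_slice <- function(mask) {
  areas <- apply(mask$values, 3, sum)
  if (all(areas == 0)) stop("mask is empty")
  which.max(areas)  # which.max returns the first (lowest) maximum
}

#' Build a five-slice 2.5D stack
#'
#' Takes axial slices at offsets -4, -2, 0, +2, +4 from the central slice
#' (offsets beyond the volume are replaced by the nearest valid slice). Each
#' slice is cropped to the central-slice ROI bounding box grown 10% per side
#' and squared, HU-clipped, min-max normalized to \[-1, 1\] per slice
#' (constant slices map to all zeros), and resized to 224 x 224 with
#' nearest-neighbor interpolation.
#'
#' @param vol A `ct_volume`.
#' @param mask A `mask_volume` on the same grid.
#' @param central Central slice index; defaults to [select_central_slice()].
#' @param offsets Axial offsets of the five slices.
#' @param size Output side length in pixels.
#' @param margin Fractional bounding-box expansion per side.
#' @param pre A [preprocess_config()] for the HU clip.
#' @param id Optional patient identifier carried on the stack.
#' @return A `slice_stack`: `slices` (size x size x 5 array in \[-1,1\]),
#'   `offsets`, `central`, `id`.
#' @export
build_stack <- function(vol, mask, central = NULL,
                        offsets = c(-4L, -2L, 0L, 2L, 4L),
                        size = 224L, margin = 0.1,
                        pre = preprocess_config(), id = NULL) {
  check_aligned(vol, mask)
  if (is.null(central)) central <- select_central_slice(mask)
  d <- dim(vol$values)
  sl <- mask$values[, , central]
  w <- which(sl == 1L, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("central slice holds no ROI voxels")
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  span <- hi - lo + 1L
  lo <- lo - ceiling(margin * span); hi <- hi + ceiling(margin * span)
  side <- max(hi - lo + 1L)
  mid <- (lo + hi) / 2
  lo <- floor(mid - side / 2 + 0.5); hi <- lo + side - 1L
  lo <- pmax(lo, 1L); hi <- pmin(hi, d[1:2])

  out <- array(0, c(size, size, length(offsets)))
  for (s in seq_along(offsets)) {
    z <- min(max(central + offsets[s], 1L), d[3])
    img <- vol$values[lo[1]:hi[1], lo[2]:hi[2], z]
    img <- pmin(pmax(img, pre$clip_lo), pre$clip_hi)
    rng <- range(img)
    img <- if (diff(rng) > 0) 2 * (img - rng[1]) / diff(rng) - 1 else img * 0
    out[, , s] <- resize_nn(img, size)
  }
  structure(list(slices = out, offsets = offsets, central = central, id = id,
                 cache = new.env(parent = emptyenv())),
            class = "slice_stack")
}

resize_nn <- function(img, size) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(size) - 0.5) * d[1] / size + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(size) - 0.5) * d[2] / size + 0.5), 1), d[2])
  img[ri, ci]
}

#' The slice-classifier backbone registry
#'
#' Backbones are pluggable per-slice binary classifiers behind a common
#' `fit`/`predict_proba` contract. The three reference backbones are small
#' seeded convolutional classifiers — fixed random convolutional filters over
#' a mean-pooled slice followed by a logistic head trained with stochastic
#' gradient descent, sigmoid cross-entropy loss, and a cosine-decay learning
#' rate — differing in filter count and receptive field. They train on a CPU
#' in seconds, so the pipeline (not pretrained weights) is what is exercised.
#'
#' @return Named list of backbone descriptors.
#' @export
backbone_registry <- function() {
  list(
    convnet_s = list(name = "convnet_s", n_filters = 8L, filter_size = 5L,
                     downsample = 8L, seed_offset = 101L),
    convnet_m = list(name = "convnet_m", n_filters = 16L, filter_size = 5L,
                     downsample = 8L, seed_offset = 202L),
    convnet_w = list(name = "convnet_w", n_filters = 16L, filter_size = 7L,
                     downsample = 8L, seed_offset = 303L))
}

#' Slice-model training configuration
#'
#' @param epochs SGD epochs.
#' @param batch_size Minibatch size.
#' @param lr0 Initial learning rate (cosine-decayed to 0 over training).
#' @param seed Base seed; each backbone adds its own offset.
#' @return A `slice_train_config` list.
#' @export
slice_train_config <- function(epochs = 30L, batch_size = 16L, lr0 = 0.5,
                               seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr0 = lr0, seed = as.integer(seed)),
            class = "slice_train_config")
}

# mean-pool a square image by an integer factor (reshape + colMeans)
mean_pool <- function(img, f) {
  d <- dim(img)
  n1 <- d[1] %/% f; n2 <- d[2] %/% f
  img <- img[seq_len(n1 * f), seq_len(n2 * f), drop = FALSE]
  a <- matrix(.colMeans(img, f, n1 * n2 * f), n1, n2 * f)
  t(matrix(.colMeans(t(a), f, n2 * n1), n2, n1))
}

backbone_filters <- function(backbone) {
  set.seed(backbone$seed_offset)
  fs <- backbone$filter_size
  filts <- lapply(seq_len(backbone$n_filters), function(i) {
    k <- matrix(stats::rnorm(fs * fs), fs, fs)
    k - mean(k)
  })
  filts
}

conv2_valid <- function(img, k) {
  fs <- nrow(k)
  d <- dim(img)
  out <- matrix(0, d[1] - fs + 1, d[2] - fs + 1)
  for (a in seq_len(fs)) for (b in seq_len(fs)) {
    out <- out + k[a, b] *
      img[a:(a + nrow(out) - 1), b:(b + ncol(out) - 1)]
  }
  out
}

# fixed random-filter convolutional features: ReLU then global mean and max
# pooling per filter
backbone_featurize <- function(slice, backbone, filters) {
  img <- mean_pool(slice, backbone$downsample)
  feats <- cpp_conv_relu_pool(img, filters)   # (mean, max) per filter
  # zero-mean filters are blind to the slice's DC level, so the pooled
  # image's global mean and SD are appended as two intensity channels
  c(as.numeric(feats), mean(img), stats::sd(img))
}

n_backbone_features <- function(backbone) 2L * backbone$n_filters + 2L

# featurize one offset of every stack under a backbone, memoized on each
# stack's cache environment (featurization is deterministic per backbone)
stack_feature_matrix <- function(stacks, backbone, filters, s) {
  key <- paste0(backbone$name, "_s", s)
  t(vapply(stacks, function(st) {
    if (!is.null(st$cache[[key]])) return(st$cache[[key]])
    f <- backbone_featurize(st$slices[, , s], backbone, filters)
    st$cache[[key]] <- f
    f
  }, numeric(n_backbone_features(backbone))))
}

sgd_logistic <- function(x, y, cfg, seed) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  w <- stats::rnorm(p, 0, 0.01); b <- 0
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  total <- cfg$epochs * steps_per_epoch
  t <- 0
  for (e in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1) * cfg$batch_size + 1):min(s * cfg$batch_size, n)]
      idx <- idx[!is.na(idx)]
      lr <- cfg$lr0 / 2 * (1 + cos(pi * t / total))   # cosine decay
      eta <- drop(x[idx, , drop = FALSE] %*% w) + b
      g <- stats::plogis(eta) - y[idx]                # d(sigmoid CE)/d(eta)
      w <- w - lr * drop(crossprod(x[idx, , drop = FALSE], g)) / length(idx)
      b <- b - lr * mean(g)
      t <- t + 1
    }
  }
  list(w = w, b = b)
}

#' Fit the grid of per-slice models
#'
#' One model instance per (backbone, slice offset) pair: 3 backbones x 5
#' offsets = 15 models under the default registry. Each slice model is
#' trained on that offset's slices with the patient-level label as weak
#' slice label.
#'
#' @param stacks List of `slice_stack`s.
#' @param labels Binary patient labels (same order as `stacks`).
#' @param backbones A [backbone_registry()] subset.
#' @param config A [slice_train_config()].
#' @return A `slice_models` object.
#' @export
fit_slice_models <- function(stacks, labels,
                             backbones = backbone_registry(),
                             config = slice_train_config()) {
  if (length(unique(labels)) < 2L) stop("need both classes to train")
  n_off <- length(stacks[[1]]$offsets)
  models <- list()
  for (bk in backbones) {
    filters <- backbone_filters(bk)
    # featurize all slices once per backbone
    feats <- lapply(seq_len(n_off), function(s)
      stack_feature_matrix(stacks, bk, filters, s))
    per_off <- list()
    for (s in seq_len(n_off)) {
      x <- feats[[s]]
      mu <- colMeans(x); sdv <- pmax(apply(x, 2, stats::sd), 1e-8)
      xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
      fit <- sgd_logistic(xs, as.numeric(labels), config,
                          seed = config$seed + bk$seed_offset + s)
      per_off[[s]] <- list(fit = fit, center = mu, scale = sdv)
    }
    models[[bk$name]] <- list(backbone = bk, filters = filters,
                              offsets = per_off)
  }
  structure(list(models = models, n_offsets = n_off, config = config),
            class = "slice_models")
}

#' @export
print.slice_models <- function(x, ...) {
  cat("<slice_models> ", length(x$models), " backbones x ", x$n_offsets,
      " offsets = ", length(x$models) * x$n_offsets, " model instances\n",
      sep = "")
  invisible(x)
}

#' Per-patient backbone-by-slice prediction matrix
#'
#' @param models A `slice_models` fit.
#' @param stacks List of `slice_stack`s.
#' @return Tidy tibble: `patient_id`, `backbone`, `offset`, `prob`,
#'   `label` (hard label at the 0.5 threshold).
#' @export
predict_matrix <- function(models, stacks) {
  rows <- list()
  for (bk_name in names(models$models)) {
    mdl <- models$models[[bk_name]]
    for (s in seq_len(models$n_offsets)) {
      x <- stack_feature_matrix(stacks, mdl$backbone, mdl$filters, s)
      ms <- mdl$offsets[[s]]
      xs <- sweep(sweep(x, 2, ms$center), 2, ms$scale, `/`)
      prob <- stats::plogis(drop(xs %*% ms$fit$w) + ms$fit$b)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = vapply(stacks, function(st)
          if (is.null(st$id)) NA_character_ else st$id, character(1)),
        backbone = bk_name,
        offset = stacks[[1]]$offsets[s],
        prob = prob,
        label = as.integer(prob >= 0.5))
    }
  }
  dplyr::bind_rows(rows)
}

#' Predict-likelihood-histogram (PLH) features
#'
#' Per backbone: the histogram of its slice probabilities over equal-width
#' bins on \[0, 1\] (half-open, closed at the top) plus the count of positive
#' hard labels, concatenated across backbones.
#'
#' @param pred A [predict_matrix()] tibble.
#' @param bins Number of histogram bins.
#' @return Tibble: `patient_id` plus `plh_<backbone>_bin*` and
#'   `plh_<backbone>_npos` columns.
#' @export
plh_features <- function(pred, bins = 5L) {
  bin_of <- function(p) pmin(floor(p * bins) + 1L, bins)
  pred |>
    dplyr::group_by(.data$patient_id, .data$backbone) |>
    dplyr::summarise(
      tibble::as_tibble(t(c(tabulate(bin_of(.data$prob), nbins = bins),
                            sum(.data$label))),
                        .name_repair = ~ c(paste0("bin", seq_len(bins)),
                                           "npos")),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "backbone",
                       values_from = dplyr::all_of(c(paste0("bin",
                                                            seq_len(bins)),
                                                     "npos")),
                       names_glue = "plh_{backbone}_{.value}")
}

#' Bag-of-words TF-IDF features over slice predictions
#'
#' Each patient is a document whose tokens are (backbone, probability-decile)
#' pairs from its backbone-by-slice outcomes. Term frequency is the token
#' count, idf = ln((1 + N) / (1 + df)) + 1 fitted on the training patients
#' only, and rows are L2-normalized.
#'
#' @param pred_train Training [predict_matrix()] tibble.
#' @param pred_test Optional held-out tibble encoded with the training
#'   vocabulary and idf.
#' @param deciles Number of probability bins defining the vocabulary.
#' @return List with `train` (tibble), `test` (tibble or NULL), `vocabulary`,
#'   `idf`.
#' @export
bow_features <- function(pred_train, pred_test = NULL, deciles = 10L) {
  if (length(unique(pred_train$patient_id)) < 2L)
    stop("need at least 2 patients to fit a vocabulary")
  tokenize <- function(pred) {
    pred |>
      dplyr::mutate(token = paste0("bow_", .data$backbone, "_d",
                                   pmin(floor(.data$prob * deciles) + 1L,
                                        deciles)))
  }
  tr <- tokenize(pred_train)
  vocab <- sort(unique(tr$token))
  n_docs <- length(unique(tr$patient_id))
  df <- tr |>
    dplyr::distinct(.data$patient_id, .data$token) |>
    dplyr::count(.data$token)
  dfv <- stats::setNames(rep(0L, length(vocab)), vocab)
  dfv[df$token] <- df$n
  idf <- log((1 + n_docs) / (1 + dfv)) + 1

  encode <- function(tk) {
    ids <- sort(unique(tk$patient_id))
    m <- matrix(0, length(ids), length(vocab),
                dimnames = list(ids, vocab))
    cnt <- dplyr::count(tk, .data$patient_id, .data$token)
    cnt <- cnt[cnt$token %in% vocab, ]
    m[cbind(match(cnt$patient_id, ids), match(cnt$token, vocab))] <- cnt$n
    m <- sweep(m, 2, idf, `*`)
    nrm <- sqrt(rowSums(m^2))
    m <- m / pmax(nrm, 1e-12)
    tibble::as_tibble(m) |>
      dplyr::mutate(patient_id = ids, .before = 1)
  }
  list(train = encode(tr),
       test = if (!is.null(pred_test)) encode(tokenize(pred_test)) else NULL,
       vocabulary = vocab, idf = idf)
}

#' Fuse PLH and BoW features into the MIL feature table
#'
#' Column-wise concatenation by patient; names are already namespaced
#' (`plh_*`, `bow_*`), so the result has unique columns.
#'
#' @param plh A [plh_features()] tibble.
#' @param bow A [bow_features()] `train` or `test` tibble.
#' @return Tibble with `provenance` attribute `"MIL"`.
#' @export
fuse_mil <- function(plh, bow) {
  if (!setequal(plh$patient_id, bow$patient_id))
    stop("PLH and BoW patient sets differ")
  out <- dplyr::inner_join(plh, bow, by = "patient_id")
  attr(out, "provenance") <- "MIL"
  out
}
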