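#' The 20-image derived-image filter bank
#'
#' Derived images from which intensity and texture features are extracted:
#' the original image; the 8 sub-bands of a one-level undecimated separable
#' Haar wavelet transform (LLL..HHH); Laplacian-of-Gaussian at six scales
#' (sigma 1..6 mm, scale-normalized); four intensity transforms (square,
#' square root, logarithm, exponential of the range-shifted image); and the
#' gradient magnitude. 20 images in total.
#'
#' @param filters Either `"all"` (the full 20-image bank), `"original"`
#'   (the unfiltered image only), or a character vector of bank entry names.
#' @return A `filter_bank`: named list of filter descriptors.
#' @export
filter_bank <- function(filters = "all") {
  wavelets <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                    1, function(r) paste0(r[3], r[2], r[1]))
  all_names <- c("original", paste0("wavelet_", wavelets),
                 paste0("log_sigma_", 1:6),
                 "square", "squareroot", "logarithm", "exponential",
                 "gradient")
  if (identical(filters, "all")) filters <- all_names
  if (identical(filters, "original")) filters <- "original"
  bad <- setdiff(filters, all_names)
  if (length(bad)) stop("unknown filters: ", paste(bad, collapse = ", "))
  structure(as.list(filters), names = filters, class = "filter_bank")
}

haar_lo <- function() c(1, 1) / sqrt(2)
haar_hi <- function() c(1, -1) / sqrt(2)

apply_filter_values <- function(name, values, spacing) {
  d <- dim(values)
  if (name == "original") return(values)
  if (startsWith(name, "wavelet_")) {
    code <- strsplit(sub("wavelet_", "", name), "")[[1]]
    ks <- lapply(code, function(ch) if (ch == "L") haar_lo() else haar_hi())
    # code is ZYX order; convolution kernels are passed x, y, z
    out <- cpp_sep_conv3d(values, as.integer(d), ks[[3]], ks[[2]], ks[[1]])
    return(array(out, d))
  }
  if (startsWith(name, "log_sigma_")) {
    sigma_mm <- as.numeric(sub("log_sigma_", "", name))
    ks <- lapply(1:3, function(ax) gaussian_kernel(sigma_mm / spacing[ax]))
    sm <- array(cpp_sep_conv3d(values, as.integer(d),
                               ks[[1]], ks[[2]], ks[[3]]), d)
    return(sigma_mm^2 * laplacian3d(sm, spacing))
  }
  s <- values - min(values)
  switch(name,
    square = s^2,
    squareroot = sqrt(s),
    logarithm = log1p(s),
    exponential = if (max(s) > 0) exp(4 * s / max(s)) else array(1, d),
    gradient = gradient_magnitude(values, spacing),
    stop("unknown filter: ", name))
}

laplacian3d <- function(values, spacing) {
  d <- dim(values)
  out <- array(0, d)
  for (ax in 1:3) {
    fwd <- shift_num(values, ax, 1L)
    bwd <- shift_num(values, ax, -1L)
    out <- out + (fwd + bwd - 2 * values) / spacing[ax]^2
  }
  out
}

gradient_magnitude <- function(values, spacing) {
  g2 <- array(0, dim(values))
  for (ax in 1:3) {
    g <- (shift_num(values, ax, 1L) - shift_num(values, ax, -1L)) /
      (2 * spacing[ax])
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

# shift with edge replication (numeric arrays)
shift_num <- function(m, ax, by) {
  d <- dim(m)
  idx <- lapply(d, seq_len)
  n <- d[ax]
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  idx[[ax]] <- src
  m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
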