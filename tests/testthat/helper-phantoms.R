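# Geometric phantoms used across the suite. Everything is built in code.

make_sphere_mask <- function(radius = 10, dims = rep(2 * radius + 9, 3),
                             spacing = c(1, 1, 1)) {
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  r2 <- ((g$x - ctr[1]) * spacing[1])^2 + ((g$y - ctr[2]) * spacing[2])^2 +
    ((g$z - ctr[3]) * spacing[3])^2
  mask_volume(array(as.integer(r2 <= radius^2), dims), spacing)
}

make_cube_mask <- function(side = 12, dims = rep(side + 8, 3)) {
  m <- array(0L, dims)
  lo <- (dims - side) %/% 2 + 1L
  m[lo[1]:(lo[1] + side - 1), lo[2]:(lo[2] + side - 1),
    lo[3]:(lo[3] + side - 1)] <- 1L
  mask_volume(m)
}

# small noisy CT volume paired with a sphere mask
make_noisy_volume <- function(mask, mean_hu = 60, sd_hu = 20, seed = 1) {
  set.seed(seed)
  d <- dim(mask$values)
  ct_volume(array(stats::rnorm(prod(d), mean_hu, sd_hu), d), mask$spacing)
}

# one default-condition synthetic patient, memoized per session
phantom_patient <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_config(n_patients = 1, seed = 42))
      cache <<- co[[1]]
    }
    cache
  }
})

# tiny cohort for pipeline plumbing tests, memoized
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_patients = 24, seed = 77, volume_shape = c(40L, 40L, 40L),
        tumor_radius_mm = c(6.5, 9)))
    }
    cache
  }
})
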