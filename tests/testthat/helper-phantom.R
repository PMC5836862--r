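# Shared fixtures, built in code at test time.

# Small, fast acquisition geometry for unit tests.
small_params <- function() {
  acq_params(matrix_size = c(16L, 8L, 6L), fov_mm = c(32, 16, 24))
}

# Default-geometry phantom spec with selective overrides.
quiet_study <- function(...) {
  suppressMessages(generate_study(phantom_spec(...)))
}

# A smooth 3D test image with zero margins (band-limited enough that
# Fourier-shift round trips are clean).
smooth_test_volume <- function(dims = c(16, 12, 6), seed = 42) {
  set.seed(seed)
  arr <- array(0, dims)
  core <- lapply(dims, function(n) seq(floor(n / 4) + 1, ceiling(3 * n / 4)))
  arr[core[[1]], core[[2]], core[[3]]] <-
    abs(stats::rnorm(prod(lengths(core))))
  gaussian_blur(arr, 3)
}

# Strictly band-limited volume (harmonics well below Nyquist on every
# axis), on which Fourier shifting is exact to machine precision.
bandlimited_volume <- function(dims = c(16, 12, 6)) {
  i <- slice.index(array(0, dims), 1)
  j <- slice.index(array(0, dims), 2)
  k <- slice.index(array(0, dims), 3)
  2 + sin(2 * pi * 2 * i / dims[1]) * cos(2 * pi * j / dims[2]) +
    0.5 * cos(2 * pi * 3 * i / dims[1] + 1) * sin(2 * pi * k / dims[3]) +
    0.3 * sin(2 * pi * 2 * j / dims[2] + 0.5)
}

run_default_correction <- local({
  cache <- new.env(parent = emptyenv())
  function(seed) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      spec <- phantom_spec(seed = seed)
      st <- suppressMessages(generate_study(spec))
      res <- suppressWarnings(suppressMessages(
        correct_study(st$up, st$down, pipeline_config(spec$params))))
      cache[[key]] <- list(study = st, result = res)
    }
    cache[[key]]
  }
})
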