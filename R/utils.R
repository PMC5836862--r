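# Internal array helpers shared by the distortion, estimation and
# resampling code. All heavy per-column operations work on a matrix view
# with the phase-encode axis as rows and every other voxel index as a
# column, so they vectorise over columns.

# Reorder a 3D array so that `axis` becomes the first dimension and
# flatten the rest; returns list(mat, perm, dims) for round-tripping.
.pe_view <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  list(mat = matrix(a, nrow = d[axis]), perm = perm, dims = d[perm])
}

.pe_unview <- function(mat, view) {
  a <- array(mat, view$dims)
  aperm(a, order(view$perm))
}

# Linear interpolation of each column of `mat` (n x k) at positions
# `pos` (n x k, 1-based fractional row indices). The profile is treated
# as 0 outside the column, so samples in the half-open edge intervals
# [0, 1) and [n, n + 1) keep their partial weight and mass leaves the
# field of view continuously.
.interp_cols <- function(mat, pos) {
  n <- nrow(mat)
  i0 <- floor(pos)
  w <- pos - i0
  col <- (col(mat) - 1L) * n
  i0c <- pmin(pmax(i0, 1), n - 1)
  lo <- mat[as.vector(col + i0c)]
  hi <- mat[as.vector(col + i0c + 1L)]
  out <- (1 - w) * lo + w * hi
  lo_edge <- i0 == 0
  out[lo_edge] <- w[lo_edge] * mat[as.vector(col)[lo_edge] + 1L]
  hi_edge <- i0 == n
  out[hi_edge] <- (1 - w[hi_edge]) * mat[as.vector(col)[hi_edge] + n]
  out[i0 < 0 | i0 > n] <- 0
  dim(out) <- dim(mat)
  out
}

# Slope of the piecewise-linear interpolant of each column at `pos`
# (derivative per voxel); 0 outside [0, n + 1).
.interp_cols_slope <- function(mat, pos) {
  n <- nrow(mat)
  i0 <- floor(pos)
  col <- (col(mat) - 1L) * n
  i0c <- pmin(pmax(i0, 1), n - 1)
  out <- mat[as.vector(col + i0c + 1L)] - mat[as.vector(col + i0c)]
  lo_edge <- i0 == 0
  out[lo_edge] <- mat[as.vector(col)[lo_edge] + 1L]
  hi_edge <- i0 == n
  out[hi_edge] <- -mat[as.vector(col)[hi_edge] + n]
  out[i0 < 0 | i0 > n] <- 0
  dim(out) <- dim(mat)
  out
}

# Central-difference matrix (n x n) with one-sided differences at the
# ends; used for d(shift)/dx in the Jacobian intensity modulation.
.diff_matrix <- function(n) {
  D <- matrix(0, n, n)
  if (n == 1) return(D)
  for (i in seq_len(n)) {
    if (i == 1) { D[1, 1] <- -1; D[1, 2] <- 1 }
    else if (i == n) { D[n, n - 1] <- -1; D[n, n] <- 1 }
    else { D[i, i - 1] <- -0.5; D[i, i + 1] <- 0.5 }
  }
  D
}

# Discrete 3D Laplacian with zero (Dirichlet) boundaries. Symmetric as
# an operator, so it is its own adjoint -- required by the conjugate
# gradient solver in the field estimation.
.laplacian3d <- function(arr) {
  d <- dim(arr)
  out <- -2 * length(d) * arr
  for (ax in seq_along(d)) {
    n <- d[ax]
    idx <- lapply(d, seq_len)
    if (n > 1) {
      up <- idx; up[[ax]] <- c(2:n, n); down <- idx; down[[ax]] <- c(1, 1:(n - 1))
      plus <- do.call(`[`, c(list(arr), up))
      minus <- do.call(`[`, c(list(arr), down))
      # zero outside the volume: drop the replicated edge samples
      edge_hi <- idx; edge_hi[[ax]] <- n
      edge_lo <- idx; edge_lo[[ax]] <- 1
      plus <- array(plus, d); minus <- array(minus, d)
      eh <- slice.index(arr, ax) == n
      el <- slice.index(arr, ax) == 1
      plus[eh] <- 0
      minus[el] <- 0
      out <- out + plus + minus
    }
    # n == 1: both neighbours are outside (zero), nothing to add
  }
  out
}

# Rician magnitude noise: |signal + complex Gaussian noise of scale sigma|.
.add_rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  re <- signal + stats::rnorm(n, sd = sigma)
  im <- stats::rnorm(n, sd = sigma)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(signal)
  out
}

# Robust Rayleigh scale from magnitude background voxels: raw median
# absolute deviation divided by the Rayleigh MAD/sigma ratio (0.4485,
# computed from the Rayleigh quantile function).
.rayleigh_sigma <- function(x) {
  stats::mad(x, constant = 1) / 0.4485
}

.axis_letter <- function(ax) c("x", "y", "z")[ax]

# Separable Gaussian blur with circular (wrap-around) boundaries; used
# where the blur must commute with circular Fourier shifting.
.gauss_blur_circular <- function(image, fwhm_px) {
  if (fwhm_px <= 0) return(image)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(image)
  out <- image
  for (ax in seq_along(d)) {
    if (d[ax] == 1) next
    v <- .pe_view_nd(out, ax)
    n <- d[ax]
    acc <- matrix(0, n, ncol(v$mat))
    for (j in -r:r) {
      idx <- ((seq_len(n) + j - 1) %% n) + 1L
      acc <- acc + k[j + r + 1] * v$mat[idx, , drop = FALSE]
    }
    out <- .pe_unview(acc, v)
  }
  out
}
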