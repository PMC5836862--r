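#' Sub-voxel translation by a Fourier-domain phase ramp
#'
#' Translates an image by a (possibly fractional) number of voxels along
#' one axis by multiplying its Fourier transform by
#' `exp(-2 pi i k s / N)`. Integer shifts reproduce exact circular index
#' shifts; fractional shifts are the band-limited interpolation. Content
#' wraps circularly, so objects should not touch the edge of the field
#' of view. The real part is returned (inputs are magnitude images); at
#' the unpaired Nyquist frequency of even-length axes this truncation
#' makes fractional shifts band-limiting, as is standard.
#'
#' @param image Finite numeric array (any dimensionality).
#' @param shift Signed shift in voxels; `|shift|` must be below the axis
#'   length.
#' @param axis Axis to shift along.
#' @return Shifted array of the same shape.
#' @examples
#' x <- array(rnorm(64), c(8, 8))
#' max(abs(fourier_shift(x, 3, 1) - x[c(6:8, 1:5), ]))  # integer = circular
#' @export
fourier_shift <- function(image, shift, axis = 1L) {
  if (!all(is.finite(image))) stop("image must be finite")
  d <- dim(image)
  if (is.null(d)) { d <- length(image); dim(image) <- d }
  n <- d[axis]
  if (abs(shift) >= n) stop("|shift| must be smaller than the axis length")
  if (shift == 0) return(image)
  if (length(d) == 1) {
    v <- list(mat = matrix(image, ncol = 1), perm = 1L, dims = d)
  } else {
    v <- .pe_view_nd(image, axis)
  }
  k <- ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
  phase <- exp(-2i * pi * k * shift / n)
  out <- Re(stats::mvfft(stats::mvfft(v$mat) * phase, inverse = TRUE)) / n
  if (length(d) == 1) return(array(out, d))
  .pe_unview(out, v)
}

# .pe_view generalised to arrays of any rank.
.pe_view_nd <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  list(mat = matrix(a, nrow = d[axis]), perm = perm, dims = d[perm])
}

#' Mutual information between two images
#'
#' Shannon mutual information (natural log) of the joint histogram of
#' two equally shaped images, using equal-width bins over each image's
#' range. Used as the similarity score for bulk-shift and residual
#' translation registration, following the standard practice for images
#' whose intensity scales are unrelated.
#'
#' @param a,b Numeric arrays of identical shape.
#' @param bins Number of histogram bins per image (>= 2, default 32).
#' @return Mutual information in nats (>= 0 up to estimator noise).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  if (!all(dim(a) == dim(b)) || length(a) != length(b))
    stop("images must have the same shape")
  if (bins < 2) stop("bins must be >= 2")
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image: mutual information is 0")
    return(0)
  }
  ia <- pmin(pmax(findInterval(a, seq(ra[1], ra[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, seq(rb[1], rb[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(a)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Estimate the bulk translation between blip-up and blip-down images
#'
#' Finds the relative translation `s` (voxels) that maximizes the mutual
#' information between the two images after shifting each halfway toward
#' the other (`-s/2` to the first, `+s/2` to the second), by an integer
#' grid search over `[-bound, bound]` followed by scalar refinement to
#' `tol`. The symmetric split privileges neither image: both end up in
#' the frame midway between the polarities. The refined optimum is kept
#' only if it strictly improves on the best integer, so noise-free
#' integer translations are recovered exactly.
#'
#' @param up,down 3D arrays of identical shape (typically temporally
#'   summed images of one metabolite).
#' @param axis Axis of the search (default 1; bulk frequency-shift
#'   translations are conventionally along the readout axis for this
#'   sequence family, but the axis is configurable).
#' @param bound Maximum `|s|` searched, voxels (<= axis length / 2).
#' @param tol Refinement tolerance, voxels.
#' @param bins Histogram bins for [mutual_information()].
#' @param smooth_fwhm Gaussian FWHM (voxels) applied to working copies
#'   of both images before scoring (default 2). Mutual information of
#'   sharp-edged images is biased toward integer shifts, where the
#'   Fourier interpolation is ringing-free; a mild low-pass removes the
#'   bias. Set 0 to score the raw images.
#' @return List of class `shift_estimate`: `shift_voxels`, `axis`,
#'   `score` (MI at the optimum), `flat` (TRUE when an input was
#'   constant and 0 was returned).
#' @export
estimate_bulk_shift <- function(up, down, axis = 1L, bound = 5, tol = 0.05,
                                bins = 32L, smooth_fwhm = 2) {
  if (!all(dim(up) == dim(down))) stop("images must have the same shape")
  n <- dim(up)[axis]
  if (bound > n / 2) stop("bound must be at most half the axis length")
  if (stats::sd(up) == 0 || stats::sd(down) == 0) {
    warning("flat image: bulk shift set to 0")
    return(structure(list(shift_voxels = 0, axis = axis, score = 0,
                          flat = TRUE), class = "shift_estimate"))
  }
  if (smooth_fwhm > 0) {
    # circular blur, so low-passing commutes exactly with the circular
    # Fourier shifts being scored: a noise-free integer translation then
    # scores as a perfect match and is recovered exactly
    up <- .gauss_blur_circular(up, smooth_fwhm)
    down <- .gauss_blur_circular(down, smooth_fwhm)
  }
  score <- function(s)
    mutual_information(fourier_shift(up, -s / 2, axis),
                       fourier_shift(down, +s / 2, axis), bins)
  grid <- seq(-floor(bound), floor(bound))
  mi <- vapply(grid, score, numeric(1))
  best <- grid[which.max(mi)]
  best_mi <- max(mi)
  lo <- max(best - 1, -bound); hi <- min(best + 1, bound)
  ref <- stats::optimize(score, c(lo, hi), maximum = TRUE, tol = tol)
  if (ref$objective > best_mi + 1e-12) {
    best <- ref$maximum; best_mi <- ref$objective
  }
  structure(list(shift_voxels = best, axis = axis, score = best_mi,
                 flat = FALSE), class = "shift_estimate")
}

#' Remove per-metabolite bulk frequency-shift translations
#'
#' For each metabolite, estimates the bulk translation between the
#' temporally summed blip-up and blip-down images (the shift is constant
#' over the timecourse, so summing over time maximizes SNR) and applies
#' half of it to every frame of each polarity with [fourier_shift()].
#'
#' @param up,down [metabolite_stack()]s of opposite polarity.
#' @param axis Search axis; defaults to the readout axis.
#' @param bound,tol,bins,smooth_fwhm Passed to [estimate_bulk_shift()].
#' @return List with aligned `up` and `down` stacks and `shifts`, the
#'   per-metabolite estimates.
#' @export
prealign_stacks <- function(up, down, axis = NULL, bound = 5, tol = 0.05,
                            bins = 32L, smooth_fwhm = 2) {
  stopifnot(inherits(up, "metabolite_stack"), inherits(down, "metabolite_stack"))
  if (up$polarity == down$polarity) stop("stacks must have opposite polarity")
  if (is.null(axis)) axis <- up$params$ro_axis
  d <- dim(up$data)
  M <- d[5]
  shifts <- vector("list", M)
  out_up <- up$data; out_down <- down$data
  for (m in seq_len(M)) {
    sum_up <- apply(up$data[, , , , m, drop = FALSE], 1:3, sum)
    sum_down <- apply(down$data[, , , , m, drop = FALSE], 1:3, sum)
    est <- estimate_bulk_shift(sum_up, sum_down, axis, bound, tol, bins,
                               smooth_fwhm)
    shifts[[m]] <- est
    s <- est$shift_voxels
    if (s != 0) {
      for (t in seq_len(d[4])) {
        out_up[, , , t, m] <- fourier_shift(up$data[, , , t, m], -s / 2, axis)
        out_down[, , , t, m] <- fourier_shift(down$data[, , , t, m], +s / 2, axis)
      }
    }
  }
  names(shifts) <- up$params$metabolites
  list(up = metabolite_stack(pmax(out_up, 0), up$polarity, up$params),
       down = metabolite_stack(pmax(out_down, 0), down$polarity, down$params),
       shifts = shifts)
}
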