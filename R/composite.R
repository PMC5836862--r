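#' Estimate per-frame relative noise from background corners
#'
#' Hyperpolarized frames differ enormously in SNR across time and
#' metabolite, so each frame `(t, m)` gets its own relative noise scale:
#' a robust Rayleigh scale estimate from the eight corner patches of the
#' volume (assumed signal-free) divided by the frame maximum. Noise-free
#' frames are floored at a relative scale of 1e-6; all-zero frames get
#' an infinite sigma so that downstream weights vanish.
#'
#' @param stack A [metabolite_stack()].
#' @param background Fraction of each spatial dimension taken from each
#'   corner as background (default 0.15); the patches must contain at
#'   least 50 voxels in total.
#' @return List of class `noise_estimate` with `sigma` (T x M matrix of
#'   relative scales) and `method`.
#' @export
estimate_noise_sigma <- function(stack, background = 0.15) {
  stopifnot(inherits(stack, "metabolite_stack"))
  d <- dim(stack$data)
  ms <- d[1:3]
  w <- pmax(1L, floor(background * ms))
  corner_idx <- function(n, k) list(seq_len(k), seq(n - k + 1L, n))
  bg_mask <- array(FALSE, ms)
  for (ix in corner_idx(ms[1], w[1])) for (iy in corner_idx(ms[2], w[2]))
    for (iz in corner_idx(ms[3], w[3])) bg_mask[ix, iy, iz] <- TRUE
  if (sum(bg_mask) < 50)
    stop("background patches contain fewer than 50 voxels; increase `background`")
  sigma <- matrix(0, d[4], d[5])
  for (m in seq_len(d[5])) for (t in seq_len(d[4])) {
    frame <- stack$data[, , , t, m]
    fmax <- max(frame)
    if (fmax == 0) {
      sigma[t, m] <- Inf
      message(sprintf("all-zero frame (t=%d, m=%d): weight set to 0", t, m))
    } else {
      sigma[t, m] <- max(.rayleigh_sigma(frame[bg_mask]) / fmax, 1e-6)
    }
  }
  structure(list(sigma = sigma, method = "corner-MAD (Rayleigh)",
                 background = background),
            class = "noise_estimate")
}

#' SNR-weighted composite of a metabolite timecourse stack
#'
#' Collapses a `[x, y, z, t, m]` stack to one 3D image carrying
#' information from every metabolite: each metabolite's timecourse is
#' first rescaled to unit maximum (so bright pyruvate cannot drown the
#' downstream metabolites), then averaged over time with inverse-variance
#' weights `1 / sigma_tm^2`, and the per-metabolite results are averaged
#' with equal weight. The composite is the support image from which the
#' displacement field is estimated.
#'
#' @param stack A [metabolite_stack()].
#' @param noise A matching [estimate_noise_sigma()] result.
#' @param normalization `"per_metabolite"` (default): weights normalized
#'   within each metabolite, then an equal `1/M` average;
#'   `"global"`: a single `sum(1/sigma^2)` normalization over all frames.
#' @return List of class `composite`: `image` (3D array) and `weights`
#'   (T x M, normalized as used; columns of dropped metabolites are 0).
#' @export
snr_weighted_mean <- function(stack, noise,
                              normalization = c("per_metabolite", "global")) {
  stopifnot(inherits(stack, "metabolite_stack"),
            inherits(noise, "noise_estimate"))
  normalization <- match.arg(normalization)
  d <- dim(stack$data)
  if (!all(dim(noise$sigma) == d[4:5]))
    stop("noise estimate does not match stack frames")
  M <- d[5]
  if (M == 0) stop("no metabolites")
  w <- 1 / noise$sigma^2            # T x M, Inf sigma -> 0 weight
  img <- array(0, d[1:3])
  weights <- matrix(0, d[4], M)
  scaled <- vector("list", M)
  for (m in seq_len(M)) {
    xm <- stack$data[, , , , m, drop = FALSE]
    mx <- max(xm)
    scaled[[m]] <- if (mx > 0) xm / mx else xm
  }
  if (normalization == "per_metabolite") {
    kept <- 0
    for (m in seq_len(M)) {
      wm <- w[, m]
      if (!any(wm > 0)) {
        warning(sprintf("metabolite %d has no usable frames; dropped", m))
        next
      }
      wm <- wm / sum(wm)
      weights[, m] <- wm
      acc <- array(0, d[1:3])
      for (t in seq_len(d[4]))
        if (wm[t] > 0) acc <- acc + wm[t] * scaled[[m]][, , , t, 1]
      img <- img + acc
      kept <- kept + 1
    }
    if (kept == 0) stop("all metabolites dropped: no usable frames")
    img <- img / kept
  } else {
    tot <- sum(w[is.finite(w)])
    if (tot == 0) stop("all frames have zero weight")
    for (m in seq_len(M)) for (t in seq_len(d[4])) {
      wt <- w[t, m] / tot
      weights[t, m] <- wt
      if (wt > 0) img <- img + wt * scaled[[m]][, , , t, 1]
    }
  }
  structure(list(image = img, weights = weights,
                 normalization = normalization), class = "composite")
}

#' Build the blip-up / blip-down composite image pair
#'
#' Applies [snr_weighted_mean()] independently to each polarity,
#' producing the image pair whose residual disagreement drives the
#' displacement-field estimation.
#'
#' @param up,down [metabolite_stack()]s with opposite polarity.
#' @param noise_up,noise_down Optional precomputed noise estimates
#'   (computed with [estimate_noise_sigma()] defaults when `NULL`).
#' @param normalization Passed to [snr_weighted_mean()].
#' @return List of class `composite_pair`: `f_up`, `f_down` (3D arrays)
#'   and `weights_up`, `weights_down`.
#' @export
build_composite_pair <- function(up, down, noise_up = NULL, noise_down = NULL,
                                 normalization = c("per_metabolite", "global")) {
  stopifnot(inherits(up, "metabolite_stack"), inherits(down, "metabolite_stack"))
  if (up$polarity == down$polarity)
    stop("composite pair needs opposite blip polarities")
  normalization <- match.arg(normalization)
  if (is.null(noise_up)) noise_up <- estimate_noise_sigma(up)
  if (is.null(noise_down)) noise_down <- estimate_noise_sigma(down)
  cu <- snr_weighted_mean(up, noise_up, normalization)
  cd <- snr_weighted_mean(down, noise_down, normalization)
  structure(list(f_up = cu$image, f_down = cd$image,
                 weights_up = cu$weights, weights_down = cd$weights,
                 pe_axis = up$params$pe_axis, params = up$params),
            class = "composite_pair")
}
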