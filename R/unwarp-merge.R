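#' Homogeneous 4x4 affine transform
#'
#' @param matrix 4x4 numeric matrix with last row `(0, 0, 0, 1)`,
#'   invertible. Coordinates are 1-based voxel indices.
#' @return Object of class `homogeneous_transform` (the matrix).
#' @export
homogeneous_transform <- function(matrix = diag(4)) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(4, 4)))
    stop("need a 4x4 matrix")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row must be (0, 0, 0, 1)")
  if (abs(det(matrix)) < 1e-12) stop("transform must be invertible")
  structure(matrix, class = c("homogeneous_transform", "matrix", "array"))
}

#' Pure translation transform
#' @param t Length-3 translation in voxels.
#' @return A [homogeneous_transform()].
#' @export
translation_transform <- function(t) {
  M <- diag(4)
  M[1:3, 4] <- t
  homogeneous_transform(M)
}

#' Principal matrix square root of an affine transform
#'
#' Returns the principal square root `S` (eigenvalues in the right half
#' plane) with `S %*% S` equal to the input, computed by the
#' Denman-Beavers product iteration. The root exists when no eigenvalue
#' lies on the closed negative real axis; such eigenvalues raise an
#' error naming the offending value so callers can fall back to a
#' half-translation.
#'
#' @param transform A [homogeneous_transform()] or 4x4 matrix.
#' @return A [homogeneous_transform()] square root.
#' @examples
#' matrix_sqrt(diag(c(4, 9, 1, 1)))
#' @export
matrix_sqrt <- function(transform) {
  M <- unclass(transform)
  ev <- eigen(M, only.values = TRUE)$values
  bad <- Re(ev) < 0 & abs(Im(ev)) < 1e-12 * max(abs(ev))
  bad <- bad | (Re(ev) <= 0 & Im(ev) == 0)
  if (any(bad))
    stop(sprintf("matrix square root does not exist: eigenvalue %s lies on the closed negative real axis",
                 format(ev[which(bad)[1]], digits = 6)))
  S <- pracma::sqrtm(M, kmax = 60, tol = .Machine$double.eps / 2)$B
  homogeneous_transform(S)
}

# Resample a 3D volume through a homogeneous transform: the output voxel
# at x takes the value of the input at M^{-1} x (trilinear, zero
# outside). M maps input coordinates to output coordinates, so a pure
# translation t moves content by +t voxels.
.apply_transform_volume <- function(vol, M) {
  M <- unclass(M)
  d <- dim(vol)
  if (max(abs(M - diag(4))) == 0) return(vol)
  Minv <- solve(M)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  src <- t(Minv[1:3, 1:3] %*% t(g)) +
    matrix(Minv[1:3, 4], nrow(g), 3, byrow = TRUE)
  out <- numeric(nrow(g))
  i0 <- floor(src)
  w <- src - i0
  ok <- rep(TRUE, nrow(g))
  for (ax in 1:3) {
    top <- src[, ax] == d[ax]
    i0[top, ax] <- d[ax] - 1
    w[top, ax] <- 1
    ok <- ok & i0[, ax] >= 1 & i0[, ax] <= d[ax] - 1
  }
  if (any(ok)) {
    i0k <- i0[ok, , drop = FALSE]
    wk <- w[ok, , drop = FALSE]
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wt <- (if (cx) wk[, 1] else 1 - wk[, 1]) *
            (if (cy) wk[, 2] else 1 - wk[, 2]) *
            (if (cz) wk[, 3] else 1 - wk[, 3])
      acc <- acc + wt * vol[cbind(i0k[, 1] + cx, i0k[, 2] + cy, i0k[, 3] + cz)]
    }
    out[ok] <- acc
  }
  array(out, d)
}

#' Unwarp a stack with an estimated displacement field
#'
#' Inverts the forward distortion of [apply_distortion()] for each
#' phase-encode column by exact inversion of the monotone 1D
#' displacement map `T(x) = x + polarity * b(x)`: the acquired column is
#' sampled at `T^{-1}` and multiplied by the inverse-map Jacobian, so
#' compressions and expansions are undone with their intensity pile-up.
#' The returned stack has polarity 0 (corrected).
#'
#' @param stack A [metabolite_stack()] with polarity +1 or -1.
#' @param field The estimated [displacement_field()].
#' @param jacobian Apply Jacobian intensity modulation (default TRUE).
#' @return An undistorted [metabolite_stack()] (polarity 0).
#' @export
unwarp_stack <- function(stack, field, jacobian = TRUE) {
  stopifnot(inherits(stack, "metabolite_stack"),
            inherits(field, "displacement_field"))
  d <- dim(stack$data)
  if (!all(dim(field$shift_voxels) == d[1:3]))
    stop("field shape does not match stack spatial dimensions")
  s <- stack$polarity
  if (s == 0) return(stack)
  pe <- stack$params$pe_axis
  samp <- .inverse_map_sampler(field$shift_voxels, pe, s)
  out <- stack$data
  for (m in seq_len(d[5])) for (t in seq_len(d[4])) {
    v <- .pe_view(stack$data[, , , t, m], pe)
    u <- v$mat
    n <- nrow(u)
    col <- (col(u) - 1L) * n
    lo <- u[as.vector(col + samp$i0)]
    hi <- u[as.vector(col + samp$i0 + 1L)]
    res <- (1 - samp$w) * lo + samp$w * hi
    res[!samp$inb] <- 0
    if (jacobian) res <- res * samp$dxdy
    dim(res) <- dim(u)
    out[, , , t, m] <- .pe_unview(res, v)
  }
  metabolite_stack(out, 0, stack$params)
}

# Precompute, per phase-encode column, the interpolation indices/weights
# of the inverse displacement map and its Jacobian. Shared across all
# frames of a stack (the field is static).
.inverse_map_sampler <- function(shift, pe, s) {
  fv <- .pe_view(shift, pe)
  B <- fv$mat
  n <- nrow(B)
  k <- ncol(B)
  X <- matrix(NA_real_, n, k)
  idx <- seq_len(n)
  for (c in seq_len(k)) {
    Tv <- idx + s * B[, c]
    for (j in 2:n) if (Tv[j] <= Tv[j - 1]) Tv[j] <- Tv[j - 1] + 1e-6
    X[, c] <- stats::approx(Tv, idx, xout = idx, rule = 1)$y
  }
  dxdy <- matrix(0, n, k)
  if (n >= 2) {
    dxdy[1, ] <- X[2, ] - X[1, ]
    dxdy[n, ] <- X[n, ] - X[n - 1, ]
    if (n > 2) dxdy[2:(n - 1), ] <- (X[3:n, ] - X[1:(n - 2), ]) / 2
  }
  inb <- !is.na(X)
  dxdy[!inb | !is.finite(dxdy)] <- 0
  Xc <- X
  Xc[!inb] <- 1
  i0 <- floor(Xc)
  w <- Xc - i0
  top <- Xc == n
  i0[top] <- n - 1
  w[top] <- 1
  i0 <- pmin(pmax(i0, 1), n - 1)
  list(i0 = i0, w = w, inb = inb, dxdy = dxdy)
}

#' Affine registration of residual alternating translations
#'
#' Estimates the residual translation mapping `moving` onto `fixed` by
#' maximizing mutual information, with a multi-start integer translation
#' grid followed by per-axis scalar refinement. Degrees of freedom are
#' restricted to translations along the given axes (the residual
#' artefact after unwarping is an alternating translation); the reverse
#' map is obtained by swapping the roles of the two images.
#'
#' @param fixed,moving 3D arrays of identical shape.
#' @param axes Axes allowed to translate (default `c(1, 2)`:
#'   readout and phase encode).
#' @param bound Integer search bound in voxels.
#' @param tol Refinement tolerance in voxels.
#' @param bins Histogram bins for [mutual_information()].
#' @param smooth_fwhm Gaussian FWHM applied to scoring copies of both
#'   images (default 2), removing the integer-shift bias of mutual
#'   information on sharp-edged images; 0 scores the raw images.
#' @return A [homogeneous_transform()]; attribute `flat` is TRUE when an
#'   input was constant and the identity was returned.
#' @export
affine_register <- function(fixed, moving, axes = c(1L, 2L), bound = 4L,
                            tol = 0.05, bins = 32L, smooth_fwhm = 2) {
  if (!all(dim(fixed) == dim(moving))) stop("images must have the same shape")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    warning("flat image: returning identity transform")
    out <- homogeneous_transform(diag(4))
    attr(out, "flat") <- TRUE
    return(out)
  }
  if (smooth_fwhm > 0) {
    fixed <- gaussian_blur(fixed, smooth_fwhm)
    moving <- gaussian_blur(moving, smooth_fwhm)
  }
  score <- function(tv) {
    t3 <- numeric(3)
    t3[axes] <- tv
    mutual_information(fixed, .apply_transform_volume(moving,
                                                      translation_transform(t3)),
                       bins)
  }
  grid <- as.matrix(expand.grid(lapply(axes, function(a) -bound:bound)))
  mi <- apply(grid, 1, score)
  best <- grid[which.max(mi), ]
  best_mi <- max(mi)
  cur <- as.numeric(best)
  for (pass in 1:2) for (j in seq_along(axes)) {
    f1 <- function(v) { tv <- cur; tv[j] <- v; score(tv) }
    ref <- stats::optimize(f1, c(cur[j] - 1, cur[j] + 1), maximum = TRUE,
                           tol = tol)
    if (ref$objective > best_mi + 1e-12) {
      cur[j] <- ref$maximum
      best_mi <- ref$objective
    }
  }
  t3 <- numeric(3)
  t3[axes] <- cur
  out <- translation_transform(t3)
  attr(out, "flat") <- FALSE
  attr(out, "score") <- best_mi
  out
}

#' Residual inter-series transforms per metabolite
#'
#' After unwarping, registers the temporally summed blip-up and
#' blip-down series of each metabolite to obtain the forward map `c`
#' (up onto down) and reverse map `d` (down onto up).
#'
#' @param up_unwarped,down_unwarped Unwarped [metabolite_stack()]s.
#' @param axes,bound,tol,bins,smooth_fwhm Passed to [affine_register()].
#' @return List with per-metabolite lists `c` and `d`.
#' @export
residual_affines <- function(up_unwarped, down_unwarped, axes = NULL,
                             bound = 4L, tol = 0.05, bins = 32L,
                             smooth_fwhm = 2) {
  stopifnot(inherits(up_unwarped, "metabolite_stack"))
  if (is.null(axes))
    axes <- c(up_unwarped$params$ro_axis, up_unwarped$params$pe_axis)
  M <- dim(up_unwarped$data)[5]
  cs <- ds <- vector("list", M)
  for (m in seq_len(M)) {
    su <- apply(up_unwarped$data[, , , , m, drop = FALSE], 1:3, sum)
    sd_ <- apply(down_unwarped$data[, , , , m, drop = FALSE], 1:3, sum)
    cs[[m]] <- affine_register(fixed = sd_, moving = su, axes = axes,
                               bound = bound, tol = tol, bins = bins,
                               smooth_fwhm = smooth_fwhm)
    ds[[m]] <- affine_register(fixed = su, moving = sd_, axes = axes,
                               bound = bound, tol = tol, bins = bins,
                               smooth_fwhm = smooth_fwhm)
  }
  names(cs) <- names(ds) <- up_unwarped$params$metabolites
  list(c = cs, d = ds)
}

#' Merge unwarped series with the geometric-mean interpolator
#'
#' Lands both unwarped series in the common midway frame and interleaves
#' them into a single timecourse: each blip-up frame is resampled
#' through `sqrt(c)` and each blip-down frame through `sqrt(d)` (the
#' principal square roots of the residual maps), so both series move
#' halfway toward each other. When a square root does not exist the
#' transform falls back to halving the translation component, with a
#' warning. Mode `"literal"` instead applies the single composed matrix
#' `sqrt(c) %*% sqrt(d)` to the blip-down series only.
#'
#' @param up_unwarped,down_unwarped Unwarped [metabolite_stack()]s
#'   (polarity 0) with equal frame counts.
#' @param transforms A [residual_affines()] result (or a compatible list
#'   with per-metabolite `c` and `d`).
#' @param mode `"split"` (default) or `"literal"`.
#' @return A merged [metabolite_stack()] (polarity 0) whose time axis
#'   interleaves the two series in acquisition order: up(1), down(1),
#'   up(2), ...
#' @export
geometric_mean_merge <- function(up_unwarped, down_unwarped, transforms,
                                 mode = c("split", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(up_unwarped, "metabolite_stack"),
            inherits(down_unwarped, "metabolite_stack"))
  d <- dim(up_unwarped$data)
  if (!all(dim(down_unwarped$data) == d))
    stop("series must have identical shapes")
  M <- d[5]; T <- d[4]
  out <- array(0, c(d[1:3], 2 * T, M))
  half <- function(Mx) {
    H <- unclass(Mx)
    H[1:3, 4] <- H[1:3, 4] / 2
    homogeneous_transform(H)
  }
  safe_sqrt <- function(Mx) {
    tryCatch(matrix_sqrt(Mx), error = function(e) {
      warning("square root unavailable (", conditionMessage(e),
              "); falling back to half-translation")
      half(Mx)
    })
  }
  for (m in seq_len(M)) {
    sc <- safe_sqrt(transforms$c[[m]])
    sd_ <- safe_sqrt(transforms$d[[m]])
    if (mode == "split") {
      up_m <- sc
      down_m <- sd_
    } else {
      up_m <- homogeneous_transform(diag(4))
      down_m <- homogeneous_transform(unclass(sc) %*% unclass(sd_))
    }
    for (t in seq_len(T)) {
      out[, , , 2 * t - 1, m] <-
        .apply_transform_volume(up_unwarped$data[, , , t, m], up_m)
      out[, , , 2 * t, m] <-
        .apply_transform_volume(down_unwarped$data[, , , t, m], down_m)
    }
  }
  metabolite_stack(out, 0, up_unwarped$params)
}
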