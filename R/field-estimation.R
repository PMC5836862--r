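#' Separable Gaussian blur
#'
#' Blurs an array with a separable Gaussian kernel specified by its full
#' width at half maximum (`sigma = fwhm / 2.3548`), using reflective
#' (symmetric) boundaries so the total intensity is conserved.
#' `fwhm_px = 0` is the identity.
#'
#' @param image Numeric array (2D or 3D).
#' @param fwhm_px Full width at half maximum in voxels (>= 0).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(image, fwhm_px) {
  if (fwhm_px < 0) stop("fwhm_px must be >= 0")
  if (fwhm_px == 0) return(image)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  # 5-sigma support keeps kernel truncation below composition tolerances
  r <- max(1L, ceiling(5 * sigma))
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
      idx <- .reflect_index(seq_len(n) + j, n)
      acc <- acc + k[j + r + 1] * v$mat[idx, , drop = FALSE]
    }
    out <- .pe_unview(acc, v)
  }
  out
}

# Reflect out-of-range indices back into 1..n (symmetric, edge-inclusive;
# handles indices any number of folds outside).
.reflect_index <- function(i, n) {
  i <- (i - 1) %% (2 * n)
  i[i >= n] <- 2 * n - 1 - i[i >= n]
  i + 1L
}

#' Block-mean subsampling
#'
#' Downsamples an array by averaging non-overlapping blocks of
#' `factor` voxels per axis; edge blocks that do not divide evenly are
#' averaged over the voxels available.
#'
#' @param image Numeric array.
#' @param factor Positive integer subsampling factor (1 = identity).
#' @return Downsampled array.
#' @export
subsample <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(image)
  out <- image
  d <- dim(out)
  for (ax in seq_along(d)) {
    v <- .pe_view_nd(out, ax)
    grp <- ceiling(seq_len(d[ax]) / factor)
    sums <- rowsum(v$mat, grp)
    cnt <- as.vector(table(grp))
    v$dims[1] <- length(cnt)
    out <- .pe_unview(sums / cnt, v)
    d <- dim(out)
  }
  out
}

#' Multi-resolution estimation schedule
#'
#' The coarse-to-fine schedule of the field estimation: per level, a
#' subsampling factor, a Gaussian pre-blur FWHM in (full-resolution)
#' voxels, and the roughness penalty weight lambda. The defaults are
#' three levels with factors 4/2/1, FWHM 8/4/0 and lambda 50/20/2 —
#' heavy smoothing and regularization first, so slowly varying field
#' components are locked in before fine structure is fit.
#'
#' @param subsample_factors Positive, non-increasing integers.
#' @param blur_fwhm_px Per-level blur FWHM (voxels, >= 0).
#' @param lambdas Per-level penalty weights (> 0), interpreted per
#'   mean-squared unit of the data term (see [estimate_field()]).
#' @param max_iter_per_level Gauss-Newton iteration cap per level.
#' @param step_tol Convergence tolerance on the voxel displacement step.
#' @return Object of class `estimation_schedule`.
#' @export
estimation_schedule <- function(subsample_factors = c(4L, 2L, 1L),
                                blur_fwhm_px = c(8, 4, 0),
                                lambdas = c(50, 20, 2),
                                max_iter_per_level = 20L,
                                step_tol = 0.01) {
  nf <- length(subsample_factors)
  if (length(blur_fwhm_px) != nf || length(lambdas) != nf)
    stop("subsample_factors, blur_fwhm_px and lambdas must have equal length")
  subsample_factors <- as.integer(subsample_factors)
  if (any(subsample_factors < 1) || is.unsorted(rev(subsample_factors)))
    stop("subsample_factors must be positive and non-increasing")
  if (any(lambdas <= 0)) stop("lambdas must be positive")
  if (any(blur_fwhm_px < 0)) stop("blur_fwhm_px must be >= 0")
  structure(list(subsample_factors = subsample_factors,
                 blur_fwhm_px = blur_fwhm_px, lambdas = lambdas,
                 max_iter_per_level = as.integer(max_iter_per_level),
                 step_tol = step_tol),
            class = "estimation_schedule")
}

# Penalty operators (self-adjoint, zero boundary): value and normal-matrix
# application for the bending (Laplacian) and membrane (gradient) choices.
.penalty_value <- function(b, penalty) {
  if (penalty == "laplacian") return(sum(.laplacian3d(b)^2))
  v <- 0
  d <- dim(b)
  for (ax in seq_along(d)) {
    if (d[ax] == 1) next
    vw <- .pe_view_nd(b, ax)
    v <- v + sum(diff(vw$mat)^2)
  }
  v
}

.penalty_op <- function(b, penalty) {
  if (penalty == "laplacian") return(.laplacian3d(.laplacian3d(b)))
  out <- array(0, dim(b))
  d <- dim(b)
  for (ax in seq_along(d)) {
    if (d[ax] == 1) next
    vw <- .pe_view_nd(b, ax)
    df <- diff(vw$mat)                       # (n-1) x k
    adj <- rbind(-df[1, , drop = FALSE],
                 if (nrow(df) > 1) -diff(df) else NULL,
                 df[nrow(df), , drop = FALSE])
    out <- out + .pe_unview(adj, vw)
  }
  out
}

#' Blip-reversed consistency objective for a displacement field
#'
#' The cost the field estimation minimizes: both composites are unwarped
#' toward the midpoint frame (the blip-up image with `+b`, the blip-down
#' image with `-b`, Jacobian-modulated), and the summed squared
#' disagreement over all phase-encode columns is penalized by
#' `lambda` times the squared roughness of the field. The cost is zero
#' iff the unwarped pair agrees exactly and the field has zero roughness.
#'
#' @param field A [displacement_field()] or 3D array of voxel shifts.
#' @param f_up,f_down 3D composite images, same shape as the field.
#' @param lambda Roughness penalty weight (>= 0).
#' @param pe_axis Phase-encode axis (taken from `field` when it is a
#'   `displacement_field`).
#' @param penalty `"laplacian"` (bending energy, default) or
#'   `"gradient"` (membrane energy).
#' @return Scalar cost, with attributes `data` and `penalty_value`.
#' @export
field_objective <- function(field, f_up, f_down, lambda, pe_axis = 2L,
                            penalty = c("laplacian", "gradient")) {
  penalty <- match.arg(penalty)
  if (inherits(field, "displacement_field")) {
    pe_axis <- field$pe_axis
    field <- field$shift_voxels
  }
  if (!all(dim(field) == dim(f_up)) || !all(dim(f_up) == dim(f_down)))
    stop("field and composites must share one shape")
  vb <- .pe_view(field, pe_axis)
  vu <- .pe_view(f_up, pe_axis)
  vd <- .pe_view(f_down, pe_axis)
  D <- .diff_matrix(nrow(vb$mat))
  r <- .sym_residual(vu$mat, vd$mat, vb$mat, D)$r
  dat <- sum(r^2)
  pen <- .penalty_value(field, penalty)
  structure(dat + lambda * pen, data = dat, penalty_value = pen)
}

# Symmetric small-deformation unwarp residual and its Gauss-Newton
# ingredients, on PE-view matrices. The first-order inverse errors of
# the two half-unwarps cancel, so the true field is a residual zero to
# second order in the displacement.
.sym_residual <- function(FU, FD, B, D) {
  rw <- row(B)
  DB <- D %*% B
  pu <- rw - B
  pd <- rw + B
  vu <- .interp_cols(FU, pu)
  vd <- .interp_cols(FD, pd)
  su <- .interp_cols_slope(FU, pu)
  sd_ <- .interp_cols_slope(FD, pd)
  r <- vu * (1 - DB) - vd * (1 + DB)
  g <- -(su * (1 - DB) + sd_ * (1 + DB))   # local (diagonal) Jacobian term
  h <- -(vu + vd)                          # term entering through d(shift)/dx
  list(r = r, g = g, h = h)
}

#' Estimate the displacement field from a composite pair
#'
#' Coarse-to-fine regularized least squares: at each schedule level the
#' two composites are Gaussian-blurred, block-mean subsampled, and the
#' voxel-wise field minimizing [field_objective()] is sought by
#' Gauss-Newton with a conjugate-gradient inner solve and Armijo
#' backtracking (the recorded cost trace is non-increasing within each
#' level by construction). Between levels the field is upsampled by
#' linear interpolation and its voxel-unit values rescaled by the
#' resolution ratio. The printed lambda values are made scale-free by
#' multiplying them with the mean squared data disagreement at zero
#' field, so the penalty competes with the data term on equal units
#' regardless of image intensity scale.
#'
#' @param pair A [build_composite_pair()] result, or a list with `f_up`,
#'   `f_down` and `pe_axis`.
#' @param schedule An [estimation_schedule()].
#' @param penalty `"laplacian"` (default) or `"gradient"` roughness.
#' @param verbose Print per-level final costs.
#' @return Object of class `field_solution`: `field` (a
#'   [displacement_field()] at full resolution), `cost_trace` (list of
#'   per-level numeric vectors), `level_fields` (list of intermediate
#'   fields), `converged` (per-level flags).
#' @export
estimate_field <- function(pair, schedule = estimation_schedule(),
                           penalty = c("laplacian", "gradient"),
                           verbose = FALSE) {
  penalty <- match.arg(penalty)
  stopifnot(is.list(pair), !is.null(pair$f_up), !is.null(pair$f_down))
  pe <- pair$pe_axis %||% 2L
  f_up <- pair$f_up; f_down <- pair$f_down
  if (!all(is.finite(f_up)) || !all(is.finite(f_down)))
    stop("composites must be finite")
  if (!all(dim(f_up) == dim(f_down))) stop("composites must share one shape")
  # common intensity normalization: a pure global scale difference
  # between the polarities is not a distortion, and must not be soaked
  # up by the Jacobian modulation term; the mean is a stabler level
  # estimate than the maximum (noise spikes cancel)
  if (mean(f_up) > 0) f_up <- f_up / mean(f_up)
  if (mean(f_down) > 0) f_down <- f_down / mean(f_down)
  nlev <- length(schedule$subsample_factors)
  b <- NULL
  prev_factor <- NA
  cost_trace <- level_fields <- vector("list", nlev)
  converged <- logical(nlev)
  for (L in seq_len(nlev)) {
    f <- schedule$subsample_factors[L]
    fu <- subsample(gaussian_blur(f_up, schedule$blur_fwhm_px[L]), f)
    fd <- subsample(gaussian_blur(f_down, schedule$blur_fwhm_px[L]), f)
    if (is.null(b)) {
      b <- array(0, dim(fu))
    } else {
      b <- .upsample_field(b, dim(fu), prev_factor, f, pe)
    }
    data0 <- sum((fu - fd)^2)
    lam_eff <- schedule$lambdas[L] * data0 / length(fu)
    res <- .gn_level(fu, fd, b, pe, lam_eff, penalty,
                     schedule$max_iter_per_level, schedule$step_tol)
    b <- res$b
    cost_trace[[L]] <- res$trace
    converged[L] <- res$converged
    level_fields[[L]] <- b
    prev_factor <- f
    if (verbose)
      message(sprintf("level %d (factor %d): cost %.6g after %d iterations%s",
                      L, f, utils::tail(res$trace, 1), length(res$trace) - 1,
                      if (res$converged) "" else " (iteration cap reached)"))
  }
  if (schedule$subsample_factors[nlev] != 1)
    b <- .upsample_field(b, dim(pair$f_up), prev_factor, 1L, pe)
  structure(list(field = displacement_field(b, pe), cost_trace = cost_trace,
                 level_fields = level_fields, converged = converged,
                 schedule = schedule, penalty = penalty),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution>", length(x$cost_trace), "levels;",
      "max |shift| =", signif(max(abs(x$field$shift_voxels)), 4), "voxels\n")
  for (L in seq_along(x$cost_trace))
    cat(sprintf("  level %d: cost %.4g -> %.4g (%d iterations)%s\n", L,
                x$cost_trace[[L]][1], utils::tail(x$cost_trace[[L]], 1),
                length(x$cost_trace[[L]]) - 1,
                if (x$converged[L]) "" else " [not converged]"))
  invisible(x)
}

# One Gauss-Newton multi-iteration pass at a single resolution level.
.gn_level <- function(fu, fd, b, pe, lam_eff, penalty, max_iter, step_tol) {
  vu <- .pe_view(fu, pe); vd <- .pe_view(fd, pe)
  FU <- vu$mat; FD <- vd$mat
  vb <- .pe_view(b, pe)
  D <- .diff_matrix(nrow(FU))
  to_arr <- function(M) .pe_unview(M, vb)
  to_mat <- function(a) .pe_view(a, pe)$mat
  costf <- function(Bm) {
    r <- .sym_residual(FU, FD, Bm, D)$r
    sum(r^2) + lam_eff * .penalty_value(to_arr(Bm), penalty)
  }
  B <- vb$mat
  trace <- costf(B)
  if (sum((fu - fd)^2) == 0)
    return(list(b = to_arr(B), trace = trace, converged = TRUE))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sr <- .sym_residual(FU, FD, B, D)
    Jt <- function(y) sr$g * y + crossprod(D, sr$h * y)
    J <- function(x) sr$g * x + sr$h * (D %*% x)
    pen_b <- to_mat(.penalty_op(to_arr(B), penalty))
    rhs <- -(Jt(sr$r) + lam_eff * pen_b)
    mu <- 1e-9 * (mean(sr$g^2) + lam_eff + 1e-30)
    Aop <- function(x)
      Jt(J(x)) + lam_eff * to_mat(.penalty_op(to_arr(x), penalty)) + mu * x
    delta <- .cg_solve(Aop, rhs, max_iter = 60, tol = 1e-4)
    gdot <- sum(rhs * delta)
    if (!is.finite(gdot) || gdot <= 0) { converged <- TRUE; break }
    cost <- utils::tail(trace, 1)
    t <- 1
    accepted <- FALSE
    while (t > 1e-6) {
      cand <- B + t * delta
      cc <- costf(cand)
      if (cc <= cost - 1e-4 * t * gdot) {
        B <- cand; trace <- c(trace, cc); accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) break
    if (max(abs(t * delta)) < step_tol) { converged <- TRUE; break }
  }
  list(b = to_arr(B), trace = trace, converged = converged)
}

# Conjugate gradients for the (SPD) Gauss-Newton normal equations.
.cg_solve <- function(Aop, rhs, max_iter = 60, tol = 1e-4) {
  x <- rhs * 0
  r <- rhs
  p <- r
  rs <- sum(r * r)
  rs0 <- rs
  if (rs0 == 0) return(x)
  for (i in seq_len(max_iter)) {
    Ap <- Aop(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (rs_new / rs0 < tol^2) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# Linearly upsample a field array from subsampling factor f_c to f_f
# (f_c >= f_f), rescaling the voxel-unit displacements by f_c / f_f.
.upsample_field <- function(b, dims_f, f_c, f_f, pe) {
  out <- b
  for (ax in 1:3) {
    n_f <- dims_f[ax]
    pos <- ((seq_len(n_f) - 0.5) * f_f + 0.5 - 0.5) / f_c + 0.5
    out <- .interp_axis_clamped(out, pos, ax)
  }
  out * (f_c / f_f)
}

# 1D linear interpolation along one axis at given positions, clamping
# samples beyond the ends to the edge value.
.interp_axis_clamped <- function(arr, pos, axis) {
  v <- .pe_view_nd(arr, axis)
  n <- nrow(v$mat)
  i0 <- pmin(pmax(floor(pos), 1), max(n - 1, 1))
  w <- pmin(pmax(pos - i0, 0), 1)
  if (n == 1) { i0 <- rep(1, length(pos)); w <- rep(0, length(pos)) }
  hi <- pmin(i0 + 1, n)
  out <- (1 - w) * v$mat[i0, , drop = FALSE] + w * v$mat[hi, , drop = FALSE]
  v$dims[1] <- length(pos)
  .pe_unview(out, v)
}
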