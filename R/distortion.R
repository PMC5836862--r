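#' Dense one-column EPI distortion matrix
#'
#' Builds the dense matrix form of the forward susceptibility distortion
#' acting on a single phase-encode column: row `i` holds the linear
#' interpolation weights that read the true profile at displaced position
#' `i + polarity * shift[i]`, optionally scaled by the local Jacobian
#' `1 + polarity * d(shift)/dx` so compressed signal brightens and
#' stretched signal dims. Signal displaced outside the column is dropped.
#' This dense form is the oracle against which the fast per-column
#' implementation in [apply_distortion()] is verified.
#'
#' @param shift_column Numeric vector of per-voxel displacements (voxels)
#'   along the column; length n >= 2, all `|shift| < n`.
#' @param polarity Blip polarity, +1 or -1.
#' @param jacobian Apply Jacobian intensity modulation (default TRUE).
#' @return List of class `distortion_matrix` with `entries` (n x n) and `n`.
#' @examples
#' K <- build_distortion_matrix(rep(0, 8), +1)
#' all(K$entries == diag(8))
#' @export
build_distortion_matrix <- function(shift_column, polarity, jacobian = TRUE) {
  n <- length(shift_column)
  if (n < 2) stop("column length must be >= 2")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (any(abs(shift_column) >= n))
    stop("unphysical shift: |shift| must be < column length")
  pos <- seq_len(n) + polarity * shift_column
  jf <- if (jacobian) 1 + polarity * as.vector(.diff_matrix(n) %*% shift_column)
        else rep(1, n)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- pos[i]
    j0 <- floor(p)
    w <- p - j0
    if (j0 >= 1 && j0 <= n - 1) {
      K[i, j0] <- (1 - w) * jf[i]
      K[i, j0 + 1] <- w * jf[i]
    } else if (j0 == 0) {
      K[i, 1] <- w * jf[i]        # partial weight at the lower edge
    } else if (j0 == n) {
      K[i, n] <- (1 - w) * jf[i]  # partial weight at the upper edge
    }
  }
  structure(list(entries = K, n = n), class = "distortion_matrix")
}

# Forward-distort a PE-first matrix view (rows = PE) with per-column
# shifts B (same shape), polarity s; vectorised over columns.
.distort_mat <- function(mat, B, s, jacobian, D) {
  pos <- row(mat) + s * B
  out <- .interp_cols(mat, pos)
  if (jacobian) out <- out * (1 + s * (D %*% B))
  out
}

#' Apply the forward susceptibility distortion to a stack
#'
#' Distorts every phase-encode column of every frame (x-position, slice,
#' timepoint, metabolite) of a [metabolite_stack()] according to the
#' displacement field, with the stack's blip polarity setting the sign of
#' the displacement. This is the forward model: it maps an undistorted
#' object to what the scanner acquires at that polarity.
#'
#' @param stack A [metabolite_stack()].
#' @param field A [displacement_field()] with the stack's spatial shape.
#' @param jacobian Apply Jacobian intensity modulation (default TRUE).
#' @return A [metabolite_stack()] with the same polarity and metadata.
#' @export
apply_distortion <- function(stack, field, jacobian = TRUE) {
  if (!inherits(stack, "metabolite_stack")) stop("stack must be a metabolite_stack")
  if (!inherits(field, "displacement_field")) stop("field must be a displacement_field")
  d <- dim(stack$data)
  if (!all(dim(field$shift_voxels) == d[1:3]))
    stop("field shape does not match stack spatial dimensions")
  s <- stack$polarity
  if (s == 0) stop("stack polarity is 0 (already corrected); nothing to distort")
  pe <- stack$params$pe_axis
  fv <- .pe_view(field$shift_voxels, pe)
  D <- .diff_matrix(nrow(fv$mat))
  out <- stack$data
  for (m in seq_len(d[5])) for (t in seq_len(d[4])) {
    v <- .pe_view(stack$data[, , , t, m], pe)
    v$mat <- .distort_mat(v$mat, fv$mat, s, jacobian, D)
    out[, , , t, m] <- .pe_unview(v$mat, v)
  }
  metabolite_stack(out, stack$polarity, stack$params)
}

# Forward-distort a single 3D volume (internal; used by the phantom
# generator and tests).
.distort_volume <- function(vol, shift, pe, s, jacobian = TRUE) {
  fv <- .pe_view(shift, pe)
  v <- .pe_view(vol, pe)
  D <- .diff_matrix(nrow(fv$mat))
  .pe_unview(.distort_mat(v$mat, fv$mat, s, jacobian, D), v)
}
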