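#' Threshold an image into a binary mask
#'
#' Mask of voxels at or above a fraction of the image maximum. The
#' default fraction 0.2 matches the display threshold conventionally
#' used for temporally summed hyperpolarized images.
#'
#' @param image Numeric array.
#' @param frac Fraction of the maximum, strictly between 0 and 1.
#' @return Object of class `binary_mask`: `voxels` (logical array),
#'   `threshold_frac`, and `empty` (TRUE for an all-zero image).
#' @export
threshold_mask <- function(image, frac = 0.2) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  mx <- max(image)
  if (mx <= 0) {
    warning("all-zero image: empty mask")
    return(structure(list(voxels = array(FALSE, dim(image)),
                          threshold_frac = frac, empty = TRUE),
                     class = "binary_mask"))
  }
  structure(list(voxels = image >= frac * mx, threshold_frac = frac,
                 empty = FALSE), class = "binary_mask")
}

#' Jaccard overlap of two binary masks
#'
#' Intersection over union: 1 for identical masks, 0 for disjoint ones.
#' Two empty masks score 1 (flagged via a warning), since they agree.
#'
#' @param a,b [threshold_mask()] results or logical arrays of one shape.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  va <- if (inherits(a, "binary_mask")) a$voxels else a
  vb <- if (inherits(b, "binary_mask")) b$voxels else b
  if (!all(dim(va) == dim(vb))) stop("masks must have the same shape")
  u <- sum(va | vb)
  if (u == 0) {
    warning("both masks empty: Jaccard defined as 1")
    return(1)
  }
  sum(va & vb) / u
}

#' Odd/even-frame Jaccard overlap per metabolite
#'
#' The reference-free quality score for blip-reversed timecourses:
#' odd-indexed and even-indexed frames (which alternate blip polarity in
#' a merged, acquisition-ordered timecourse) are summed separately over
#' time, thresholded, and their masks compared. With no distortion the
#' two sums differ only through bolus kinetics and should overlap almost
#' perfectly; susceptibility distortion displaces them apart.
#'
#' @param stack A [metabolite_stack()] with at least 2 timepoints (e.g.
#'   a [geometric_mean_merge()] output, or a raw interleaved stack for
#'   the uncorrected baseline).
#' @param frac Threshold fraction, see [threshold_mask()].
#' @return Named numeric vector, one Jaccard value per metabolite
#'   (0 when either mask is empty, with a warning).
#' @export
odd_even_jaccard <- function(stack, frac = 0.2) {
  stopifnot(inherits(stack, "metabolite_stack"))
  d <- dim(stack$data)
  if (d[4] < 2) stop("need at least 2 timepoints")
  odd <- seq(1, d[4], by = 2)
  even <- seq(2, d[4], by = 2)
  M <- d[5]
  out <- numeric(M)
  for (m in seq_len(M)) {
    so <- apply(stack$data[, , , odd, m, drop = FALSE], 1:3, sum)
    se <- apply(stack$data[, , , even, m, drop = FALSE], 1:3, sum)
    mo <- suppressWarnings(threshold_mask(so, frac))
    me <- suppressWarnings(threshold_mask(se, frac))
    if (mo$empty || me$empty) {
      warning(sprintf("metabolite %d: empty odd or even mask, Jaccard 0", m))
      out[m] <- 0
    } else {
      out[m] <- jaccard(mo, me)
    }
  }
  names(out) <- stack$params$metabolites
  out
}

#' Interleave raw blip-up/blip-down stacks in acquisition order
#'
#' Builds the uncorrected baseline timecourse against which a corrected
#' merge is scored: frames alternate up(1), down(1), up(2), ...
#'
#' @param up,down [metabolite_stack()]s with equal frame counts.
#' @return A [metabolite_stack()] with `2 T` frames (polarity 0 label;
#'   the frames themselves remain distorted).
#' @export
interleave_stacks <- function(up, down) {
  d <- dim(up$data)
  if (!all(dim(down$data) == d)) stop("stacks must have identical shapes")
  out <- array(0, c(d[1:3], 2 * d[4], d[5]))
  out[, , , seq(1, 2 * d[4], by = 2), ] <- up$data
  out[, , , seq(2, 2 * d[4], by = 2), ] <- down$data
  metabolite_stack(out, 0, up$params)
}
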