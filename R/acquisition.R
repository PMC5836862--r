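#' Acquisition parameters for a blip-reversed EPI study
#'
#' Bundles the geometric and spectral metadata needed to interpret a
#' metabolite image stack: which array axis carries phase encoding (where
#' susceptibility displacement acts), which carries the frequency-encode
#' readout, the per-voxel bandwidth along phase encode (which converts a
#' B0 offset in Hz into a displacement in voxels), and the metabolite
#' labels with their bulk transmitter-frequency errors.
#'
#' @param pe_axis Phase-encode axis index (1-3, array axis).
#' @param ro_axis Readout (frequency-encode) axis index (1-3); must differ
#'   from `pe_axis`.
#' @param pixel_bandwidth_pe Bandwidth per voxel along phase encode, in Hz
#'   (> 0). A B0 offset of `pixel_bandwidth_pe` Hz displaces signal by
#'   exactly one voxel along the phase-encode axis.
#' @param matrix_size Integer vector of length 3, voxel counts per axis.
#' @param fov_mm Numeric vector of length 3, field of view in mm.
#' @param metabolites Character vector of metabolite labels, in
#'   acquisition order.
#' @param metabolite_offsets_hz Per-metabolite transmitter frequency error
#'   in Hz; same length as `metabolites`.
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params()
#' p$matrix_size
#' @export
acq_params <- function(pe_axis = 2L,
                       ro_axis = 1L,
                       pixel_bandwidth_pe = 15,
                       matrix_size = c(32L, 16L, 12L),
                       fov_mm = c(64, 32, 48),
                       metabolites = c("pyruvate", "bicarbonate", "lactate"),
                       metabolite_offsets_hz = NULL) {
  pe_axis <- as.integer(pe_axis)
  ro_axis <- as.integer(ro_axis)
  if (!pe_axis %in% 1:3 || !ro_axis %in% 1:3)
    stop("pe_axis and ro_axis must be in 1..3")
  if (pe_axis == ro_axis)
    stop("pe_axis must differ from ro_axis")
  if (!is.numeric(pixel_bandwidth_pe) || length(pixel_bandwidth_pe) != 1 ||
      !is.finite(pixel_bandwidth_pe) || pixel_bandwidth_pe <= 0)
    stop("pixel_bandwidth_pe must be a single positive number (Hz/voxel)")
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3 || any(matrix_size < 1))
    stop("matrix_size must be three voxel counts >= 1")
  if (length(fov_mm) != 3 || any(!is.finite(fov_mm)) || any(fov_mm <= 0))
    stop("fov_mm must be three positive lengths in mm")
  metabolites <- as.character(metabolites)
  if (is.null(metabolite_offsets_hz))
    metabolite_offsets_hz <- rep(0, length(metabolites))
  if (length(metabolite_offsets_hz) != length(metabolites))
    stop("metabolite_offsets_hz must have one entry per metabolite")
  structure(
    list(pe_axis = pe_axis, ro_axis = ro_axis,
         pixel_bandwidth_pe = pixel_bandwidth_pe,
         matrix_size = matrix_size, fov_mm = fov_mm,
         metabolites = metabolites,
         metabolite_offsets_hz = as.numeric(metabolite_offsets_hz)),
    class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> matrix", paste(x$matrix_size, collapse = "x"),
      " FOV", paste(x$fov_mm, collapse = "x"), "mm\n")
  cat("  PE axis:", x$pe_axis, " RO axis:", x$ro_axis,
      " PE bandwidth:", x$pixel_bandwidth_pe, "Hz/voxel\n")
  cat("  metabolites:", paste(x$metabolites, collapse = ", "), "\n")
  invisible(x)
}

#' Metabolite image stack with blip polarity
#'
#' A 5-dimensional magnitude image array `[x, y, z, t, m]` (space, time,
#' metabolite) together with its acquisition metadata and the sign of the
#' phase-encode blips used for the acquisition. Opposite polarities carry
#' equal-magnitude, opposite-sign susceptibility displacements; polarity 0
#' marks an undistorted (corrected) stack.
#'
#' @param data Finite numeric 5D array `[x, y, z, t, m]` of magnitude
#'   intensities (arbitrary units, >= 0 up to noise).
#' @param polarity Blip polarity: +1, -1, or 0 for corrected data.
#' @param params An [acq_params()] object whose `matrix_size` matches the
#'   spatial dimensions of `data`.
#' @return An object of class `metabolite_stack`.
#' @export
metabolite_stack <- function(data, polarity, params) {
  if (!inherits(params, "acq_params")) stop("params must be acq_params")
  d <- dim(data)
  if (is.null(d) || length(d) != 5)
    stop("data must be a 5D array [x, y, z, t, m]")
  if (!all(d[1:3] == params$matrix_size))
    stop("spatial dimensions of data do not match params$matrix_size")
  if (d[4] < 1 || d[5] < 1) stop("need at least one timepoint and metabolite")
  if (d[5] != length(params$metabolites))
    stop("metabolite dimension does not match params$metabolites")
  if (!all(is.finite(data))) stop("data must be finite everywhere")
  if (!polarity %in% c(-1, 0, 1)) stop("polarity must be +1, -1 or 0")
  structure(list(data = data, polarity = polarity, params = params),
            class = "metabolite_stack")
}

#' @export
print.metabolite_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<metabolite_stack> %s, %d timepoints, %d metabolites, polarity %+d\n",
              paste(d[1:3], collapse = "x"), d[4], d[5], x$polarity))
  invisible(x)
}

#' Phase-encode displacement field
#'
#' Per-voxel signed displacement along the phase-encode axis, in voxel
#' units, for the +1 blip polarity; the -1 polarity experiences the
#' negated field. Equivalent to the B0 offset map divided by the
#' per-voxel phase-encode bandwidth.
#'
#' @param shift_voxels Finite numeric 3D array of displacements (voxels).
#' @param pe_axis Phase-encode axis the displacement acts along.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(shift_voxels, pe_axis = 2L) {
  d <- dim(shift_voxels)
  if (is.null(d) || length(d) != 3) stop("shift_voxels must be a 3D array")
  if (!all(is.finite(shift_voxels))) {
    bad <- which(!is.finite(shift_voxels), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite displacement at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }
  structure(list(shift_voxels = shift_voxels, pe_axis = as.integer(pe_axis)),
            class = "displacement_field")
}

#' Convert a B0 field map to a phase-encode displacement field
#'
#' Off-resonance of `b0_hz` Hz displaces signal along the phase-encode
#' axis by `b0_hz / pixel_bandwidth_pe` voxels (for the +1 polarity).
#'
#' @param b0_hz Finite 3D array of B0 offsets in Hz, shape
#'   `params$matrix_size`.
#' @param params An [acq_params()] object.
#' @return A [displacement_field()].
#' @examples
#' p <- acq_params(matrix_size = c(8, 8, 2), fov_mm = c(8, 8, 2))
#' f <- displacement_from_field(array(30, c(8, 8, 2)), p)
#' unique(as.vector(f$shift_voxels))  # 30 Hz / 15 Hz per voxel = 2 voxels
#' @export
displacement_from_field <- function(b0_hz, params) {
  if (!inherits(params, "acq_params")) stop("params must be acq_params")
  d <- dim(b0_hz)
  if (is.null(d) || length(d) != 3) stop("b0_hz must be a 3D array")
  mism <- which(d != params$matrix_size)
  if (length(mism))
    stop(sprintf("b0_hz shape mismatch on axis %d (got %d, expected %d)",
                 mism[1], d[mism[1]], params$matrix_size[mism[1]]))
  if (!all(is.finite(b0_hz))) stop("b0_hz contains non-finite values")
  displacement_field(b0_hz / params$pixel_bandwidth_pe, params$pe_axis)
}
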