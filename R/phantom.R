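#' Gamma-variate bolus curve
#'
#' Standard first-pass bolus kinetic shape: zero before arrival, rising
#' as a power law and decaying exponentially, normalized so the peak
#' value is exactly 1 at `t = t0 + alpha * beta`.
#'
#' @param t Time in seconds (vectorized).
#' @param t0 Arrival time in seconds.
#' @param alpha Shape parameter (> 0); larger is a more symmetric peak.
#' @param beta Timescale in seconds (> 0); controls the decay.
#' @return Intensity fraction in `[0, 1]`.
#' @examples
#' gamma_variate(c(0, 7.5, 30), t0 = 0, alpha = 3, beta = 2.5)
#' @export
gamma_variate <- function(t, t0, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  tau <- t - t0
  out <- numeric(length(t))
  up <- tau > 0
  out[up] <- (tau[up] / (alpha * beta))^alpha * exp(alpha - tau[up] / beta)
  out
}

#' Synthetic phantom object: chest ellipse with a heart-like annulus
#'
#' Builds a deterministic (seeded) 3D intensity map mimicking a rodent
#' thorax slice stack: a dim ellipsoidal "chest" (intensity 0.3)
#' containing a bright annular "myocardium" (intensity 1) whose lumen is
#' signal-free. Intensities lie in `[0, 1]`; the object mask is
#' `intensity > 0`.
#'
#' @param params An [acq_params()]; the phase-encode dimension must be at
#'   least 4 voxels.
#' @param seed RNG seed controlling a small jitter of the annulus centre.
#' @return List with `intensity` (3D array), `mask` (logical 3D array),
#'   and `geometry` (the centres and radii used, for analytic checks).
#' @export
make_phantom_object <- function(params = acq_params(), seed = 1L) {
  ms <- params$matrix_size
  if (ms[params$pe_axis] < 4)
    stop("degenerate matrix: need >= 4 voxels along the phase-encode axis")
  nx <- ms[1]; ny <- ms[2]; nz <- ms[3]
  set.seed(seed)
  jit <- stats::runif(2, -0.5, 0.5)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.42 * nx; ay <- 0.40 * ny; az <- 0.44 * nz
  # heart annulus: in-plane circle (x and y voxels are isotropic for the
  # default FOV), slightly off-centre, spanning the central slices
  hx <- cx + 1.5 + jit[1]; hy <- cy + jit[2]
  r_out <- 0.16 * nx; r_in <- 0.48 * r_out
  z_lo <- max(1, round(cz - 0.28 * nz)); z_hi <- min(nz, round(cz + 0.28 * nz))
  x <- slice.index(array(0, ms), 1)
  y <- slice.index(array(0, ms), 2)
  z <- slice.index(array(0, ms), 3)
  chest <- ((x - cx) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2 <= 1
  r2 <- (x - hx)^2 + (y - hy)^2
  in_slab <- z >= z_lo & z <= z_hi
  ring <- r2 <= r_out^2 & r2 > r_in^2 & in_slab
  lumen <- r2 <= r_in^2 & in_slab
  intensity <- array(0, ms)
  intensity[chest] <- 0.3
  intensity[ring] <- 1
  intensity[lumen] <- 0
  list(intensity = intensity, mask = intensity > 0,
       geometry = list(chest_center = c(cx, cy, cz),
                       chest_semiaxes = c(ax, ay, az),
                       heart_center = c(hx, hy),
                       r_outer = r_out, r_inner = r_in,
                       z_range = c(z_lo, z_hi)))
}

#' Specification of a synthetic blip-reversed hyperpolarized study
#'
#' Collects every ground-truth ingredient of a simulated study: the
#' acquisition geometry, metabolite bolus kinetics and peak SNR, the B0
#' field model, per-metabolite bulk frequency-shift translations, and the
#' Rician noise scale. Defaults reproduce the study conditions this
#' package is designed around: a 32 x 16 x 12 matrix, 20 timepoints at
#' 1.2 s per frame pair, three metabolites with widely differing SNR
#' (pyruvate 10x brighter than bicarbonate, the weakest metabolite
#' peaking at SNR 10), and a smooth Gaussian-bump field peaking at
#' 3 voxels of displacement.
#'
#' @param params An [acq_params()].
#' @param n_timepoints Frames per polarity (default 20).
#' @param frame_interval_s Time between successive same-polarity frames
#'   of one metabolite, seconds; the opposite polarity is acquired half a
#'   frame later.
#' @param bolus Per-metabolite list of `t0` (arrival, s), `alpha` (shape)
#'   and `beta` (timescale, s) for [gamma_variate()].
#' @param relative_snr Per-metabolite peak SNR (peak object intensity in
#'   units of the noise scale).
#' @param field_model List with `type` in
#'   `c("zero", "uniform", "gaussian_bump", "polynomial")`, `amplitude_hz`,
#'   and for the bump `center_frac` / `sigma_vox`.
#' @param bulk_shift_voxels Per-metabolite bulk translation of blip-up
#'   relative to blip-down (voxels, split evenly between the two).
#' @param bulk_shift_axis Axis the bulk shift acts along (default the
#'   readout axis).
#' @param noise_sigma Rician noise scale in image units (0 = noiseless).
#' @param seed RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(params = acq_params(),
                         n_timepoints = 20L,
                         frame_interval_s = 1.2,
                         bolus = list(
                           pyruvate    = list(t0 = 2, alpha = 3, beta = 2.5),
                           bicarbonate = list(t0 = 5, alpha = 3, beta = 3),
                           lactate     = list(t0 = 4, alpha = 3, beta = 3)),
                         relative_snr = c(100, 10, 30),
                         field_model = list(type = "gaussian_bump",
                                            amplitude_hz = 45,
                                            center_frac = c(0.45, 0.5, 0.5),
                                            sigma_vox = c(6, 4, 3)),
                         bulk_shift_voxels = c(1, -1.5, 2),
                         bulk_shift_axis = NULL,
                         noise_sigma = 1,
                         seed = 1L) {
  M <- length(params$metabolites)
  if (n_timepoints < 1) stop("n_timepoints must be >= 1")
  if (length(relative_snr) != M || any(relative_snr <= 0))
    stop("relative_snr must be positive, one value per metabolite")
  if (length(bolus) != M) stop("bolus must have one entry per metabolite")
  if (length(bulk_shift_voxels) != M)
    stop("bulk_shift_voxels must have one entry per metabolite")
  if (is.null(bulk_shift_axis)) bulk_shift_axis <- params$ro_axis
  if (!field_model$type %in% c("zero", "uniform", "gaussian_bump", "polynomial"))
    stop("unknown field model type")
  amp_vox <- abs(field_model$amplitude_hz %||% 0) / params$pixel_bandwidth_pe
  if (amp_vox >= params$matrix_size[params$pe_axis] / 4)
    stop("field amplitude out of bounds: |shift| must stay below a quarter ",
         "of the phase-encode matrix size")
  structure(list(params = params, n_timepoints = as.integer(n_timepoints),
                 frame_interval_s = frame_interval_s, bolus = bolus,
                 relative_snr = relative_snr, field_model = field_model,
                 bulk_shift_voxels = bulk_shift_voxels,
                 bulk_shift_axis = as.integer(bulk_shift_axis),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate the spec's B0 model on the acquisition grid, in Hz.
.phantom_b0 <- function(spec) {
  ms <- spec$params$matrix_size
  fm <- spec$field_model
  if (fm$type == "zero") return(array(0, ms))
  if (fm$type == "uniform") return(array(fm$amplitude_hz, ms))
  x <- slice.index(array(0, ms), 1)
  y <- slice.index(array(0, ms), 2)
  z <- slice.index(array(0, ms), 3)
  if (fm$type == "gaussian_bump") {
    cf <- fm$center_frac; sg <- fm$sigma_vox
    cx <- 1 + cf[1] * (ms[1] - 1); cy <- 1 + cf[2] * (ms[2] - 1)
    cz <- 1 + cf[3] * (ms[3] - 1)
    return(fm$amplitude_hz *
             exp(-0.5 * (((x - cx) / sg[1])^2 + ((y - cy) / sg[2])^2 +
                           ((z - cz) / sg[3])^2)))
  }
  # polynomial: linear-in-x plus quadratic-in-z trend, peak = amplitude
  xt <- 2 * (x - 1) / (ms[1] - 1) - 1
  zt <- 2 * (z - 1) / (ms[3] - 1) - 1
  fm$amplitude_hz * (0.5 * xt + 0.5 * zt^2)
}

#' Generate a synthetic blip-reversed study with full ground truth
#'
#' Builds the phantom object, scales it by each metabolite's bolus curve
#' and peak SNR, applies the per-metabolite bulk frequency-shift
#' translation (split evenly between polarities), forward-distorts each
#' frame at both blip polarities with the true displacement field, and
#' finally adds Rician noise. Blip-down frames are acquired half a frame
#' interval after blip-up frames, so the kinetics differ slightly between
#' the members of each pair.
#'
#' @param spec A [phantom_spec()].
#' @return List with `up` and `down` ([metabolite_stack()]s, polarity +1
#'   and -1) and `truth`: the true [displacement_field()], bulk shifts,
#'   noise-free stacks, object mask, and the kinetic scaling matrices.
#' @export
generate_study <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  p <- spec$params
  ms <- p$matrix_size
  M <- length(p$metabolites); T <- spec$n_timepoints
  obj <- make_phantom_object(p, spec$seed)
  b0 <- .phantom_b0(spec)
  true_field <- displacement_from_field(b0, p)
  noise_ref <- if (spec$noise_sigma > 0) spec$noise_sigma else 1
  t_up <- (seq_len(T) - 1) * spec$frame_interval_s
  t_down <- t_up + spec$frame_interval_s / 2
  kin_up <- kin_down <- matrix(0, T, M)
  for (m in seq_len(M)) {
    b <- spec$bolus[[m]]
    kin_up[, m] <- gamma_variate(t_up, b$t0, b$alpha, b$beta)
    kin_down[, m] <- gamma_variate(t_down, b$t0, b$alpha, b$beta)
  }
  clean_up <- clean_down <- array(0, c(ms, T, M))
  for (m in seq_len(M)) {
    amp <- spec$relative_snr[m] * noise_ref
    base <- obj$intensity * amp
    s <- spec$bulk_shift_voxels[m]
    base_up <- if (s != 0) fourier_shift(base, +s / 2, spec$bulk_shift_axis) else base
    base_dn <- if (s != 0) fourier_shift(base, -s / 2, spec$bulk_shift_axis) else base
    dist_up <- .distort_volume(base_up, true_field$shift_voxels, p$pe_axis, +1)
    dist_dn <- .distort_volume(base_dn, true_field$shift_voxels, p$pe_axis, -1)
    for (t in seq_len(T)) {
      clean_up[, , , t, m] <- dist_up * kin_up[t, m]
      clean_down[, , , t, m] <- dist_dn * kin_down[t, m]
    }
  }
  set.seed(spec$seed + 1L)
  noisy_up <- .add_rician(clean_up, spec$noise_sigma)
  noisy_down <- .add_rician(clean_down, spec$noise_sigma)
  truth <- list(
    true_field = true_field,
    true_bulk_shifts = spec$bulk_shift_voxels,
    bulk_shift_axis = spec$bulk_shift_axis,
    clean_up = metabolite_stack(clean_up, +1, p),
    clean_down = metabolite_stack(clean_down, -1, p),
    mask = obj$mask,
    object = obj,
    kinetics_up = kin_up, kinetics_down = kin_down,
    b0_hz = b0)
  list(up = metabolite_stack(noisy_up, +1, p),
       down = metabolite_stack(noisy_down, -1, p),
       truth = truth)
}
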