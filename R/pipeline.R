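#' Pipeline configuration
#'
#' Collects every tunable of the correction pipeline with its default.
#' Any entry can be overridden via `...`; unknown names are rejected.
#'
#' @param params An [acq_params()] describing the acquisition.
#' @param ... Overrides among: `shift_axis` (bulk-shift search axis,
#'   `NULL` = readout axis), `shift_bound` (voxels, default 5),
#'   `shift_tol` (default 0.05), `bins` (MI histogram bins, 32),
#'   `normalization` (composite weighting, `"per_metabolite"` or
#'   `"global"`), `schedule` (an [estimation_schedule()]), `penalty`
#'   (`"laplacian"` or `"gradient"`), `affine_bound` (4), `merge_mode`
#'   (`"split"` or `"literal"`), `threshold` (mask fraction, 0.2),
#'   `seed` (recorded in provenance), `verbose` (FALSE).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(params = acq_params(), ...) {
  cfg <- list(params = params,
              shift_axis = NULL, shift_bound = 5, shift_tol = 0.05,
              bins = 32L,
              normalization = "per_metabolite",
              schedule = estimation_schedule(),
              penalty = "laplacian",
              affine_bound = 4L,
              merge_mode = "split",
              threshold = 0.2,
              seed = 1L,
              verbose = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full correction on in-memory stacks
#'
#' Executes the whole pipeline: per-metabolite bulk-shift prealignment,
#' SNR-weighted composite construction, multi-resolution field
#' estimation, unwarping of both polarities, residual affine
#' registration, geometric-mean merging, and odd/even Jaccard scoring of
#' the uncorrected versus corrected timecourses.
#'
#' @param up,down [metabolite_stack()]s of opposite polarity.
#' @param config A [pipeline_config()].
#' @return List of class `correction_result`: `merged` (corrected,
#'   interleaved stack), `field_solution`, `prealign` (per-metabolite
#'   shift estimates), `composites`, `transforms`, `jaccard`
#'   (data frame with pre/post per metabolite).
#' @export
correct_study <- function(up, down, config = pipeline_config(up$params)) {
  stopifnot(inherits(up, "metabolite_stack"), inherits(down, "metabolite_stack"))
  pre <- prealign_stacks(up, down, axis = config$shift_axis,
                         bound = config$shift_bound, tol = config$shift_tol,
                         bins = config$bins)
  pair <- build_composite_pair(pre$up, pre$down,
                               normalization = config$normalization)
  sol <- estimate_field(pair, config$schedule, penalty = config$penalty,
                        verbose = config$verbose)
  uu <- unwarp_stack(pre$up, sol$field)
  dd <- unwarp_stack(pre$down, sol$field)
  tr <- residual_affines(uu, dd, bound = config$affine_bound,
                         tol = config$shift_tol, bins = config$bins)
  merged <- geometric_mean_merge(uu, dd, tr, mode = config$merge_mode)
  j_pre <- odd_even_jaccard(interleave_stacks(up, down), config$threshold)
  j_post <- odd_even_jaccard(merged, config$threshold)
  jac <- data.frame(metabolite = up$params$metabolites,
                    jaccard_pre = as.numeric(j_pre),
                    jaccard_post = as.numeric(j_post),
                    threshold = config$threshold,
                    stringsAsFactors = FALSE)
  structure(list(merged = merged, field_solution = sol, prealign = pre$shifts,
                 composites = pair, transforms = tr, jaccard = jac,
                 config = config),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result>\n")
  cat("  max |field| =", signif(max(abs(x$field_solution$field$shift_voxels)), 4),
      "voxels\n")
  print(x$jaccard, row.names = FALSE)
  invisible(x)
}

.write_nii <- function(arr, path, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Simulate a study and write it to disk
#'
#' Runs [generate_study()] and writes one 5D NIfTI per blip polarity,
#' the true displacement field (voxels and Hz), the object mask, and a
#' JSON ground-truth sidecar (bulk shifts, kinetics, seed, geometry).
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of files written plus the in-memory study.
#' @export
run_simulate <- function(spec = phantom_spec(), out_dir) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(spec)
  f_up <- file.path(out_dir, "blip_up.nii.gz")
  f_down <- file.path(out_dir, "blip_down.nii.gz")
  f_field <- file.path(out_dir, "true_field_voxels.nii.gz")
  f_hz <- file.path(out_dir, "true_field_hz.nii.gz")
  f_mask <- file.path(out_dir, "object_mask.nii.gz")
  f_truth <- file.path(out_dir, "ground_truth.json")
  .write_nii(study$up$data, f_up)
  .write_nii(study$down$data, f_down)
  .write_nii(study$truth$true_field$shift_voxels, f_field)
  .write_nii(study$truth$b0_hz, f_hz)
  .write_nii(study$truth$mask * 1, f_mask)
  truth <- list(seed = spec$seed,
                matrix_size = spec$params$matrix_size,
                metabolites = spec$params$metabolites,
                pe_axis = spec$params$pe_axis,
                ro_axis = spec$params$ro_axis,
                pixel_bandwidth_pe = spec$params$pixel_bandwidth_pe,
                n_timepoints = spec$n_timepoints,
                frame_interval_s = spec$frame_interval_s,
                noise_sigma = spec$noise_sigma,
                bulk_shift_voxels = spec$bulk_shift_voxels,
                bulk_shift_axis = spec$bulk_shift_axis,
                field_model = spec$field_model,
                kinetics_up = study$truth$kinetics_up,
                kinetics_down = study$truth$kinetics_down)
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(files = c(up = f_up, down = f_down, field = f_field,
                           field_hz = f_hz, mask = f_mask, truth = f_truth),
                 study = study))
}

# Read a 5D NIfTI as a plain array, keeping the image for header reuse.
.read_stack_nii <- function(path, polarity, params) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4) { dim(arr) <- c(d, 1); d <- dim(arr) }
  if (length(d) != 5) stop(path, ": expected a 5D [x,y,z,t,m] NIfTI")
  list(stack = metabolite_stack(arr, polarity, params), img = img)
}

#' Run the correction on NIfTI inputs and write all outputs
#'
#' Reads the blip-up and blip-down 5D NIfTIs, runs [correct_study()],
#' and writes: the composite pair, the estimated field (voxel and Hz
#' units), the per-metabolite residual transforms as 4x4 text matrices,
#' the merged corrected stack, the odd/even Jaccard report CSV, and a
#' JSON provenance record. Output volumes reuse the input NIfTI header.
#'
#' @param up_path,down_path Paths to the two 5D NIfTI stacks.
#' @param config A [pipeline_config()] (its `params` must match the
#'   file dimensions).
#' @param out_dir Output directory.
#' @return Invisibly, the [correct_study()] result with `files` attached.
#' @export
run_correct <- function(up_path, down_path, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  up <- .read_stack_nii(up_path, +1, p)
  down <- .read_stack_nii(down_path, -1, p)
  if (!all(dim(up$stack$data) == dim(down$stack$data)))
    stop("blip-up and blip-down stacks have mismatched dimensions")
  res <- correct_study(up$stack, down$stack, config)
  ref <- up$img
  files <- c(
    f_up = .write_nii(res$composites$f_up, file.path(out_dir, "composite_up.nii.gz"), ref),
    f_down = .write_nii(res$composites$f_down, file.path(out_dir, "composite_down.nii.gz"), ref),
    field = .write_nii(res$field_solution$field$shift_voxels,
                       file.path(out_dir, "field_voxels.nii.gz"), ref),
    field_hz = .write_nii(res$field_solution$field$shift_voxels * p$pixel_bandwidth_pe,
                          file.path(out_dir, "field_hz.nii.gz"), ref),
    merged = .write_nii(res$merged$data, file.path(out_dir, "corrected_merged.nii.gz"), ref))
  for (m in seq_along(p$metabolites)) {
    fc <- file.path(out_dir, sprintf("transform_c_%s.txt", p$metabolites[m]))
    fd <- file.path(out_dir, sprintf("transform_d_%s.txt", p$metabolites[m]))
    utils::write.table(unclass(res$transforms$c[[m]]), fc,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(unclass(res$transforms$d[[m]]), fd,
                       row.names = FALSE, col.names = FALSE)
  }
  csv <- file.path(out_dir, "evaluation.csv")
  utils::write.csv(res$jaccard, csv, row.names = FALSE)
  prov <- list(package_version = as.character(utils::packageVersion("hpepi")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = config$seed,
               inputs = c(up = up_path, down = down_path),
               shift_axis = config$shift_axis %||% p$ro_axis,
               shift_bound = config$shift_bound,
               normalization = config$normalization,
               penalty = config$penalty,
               merge_mode = config$merge_mode,
               threshold = config$threshold,
               schedule = unclass(config$schedule),
               prealign_shifts = vapply(res$prealign, function(s) s$shift_voxels,
                                        numeric(1)),
               level_final_costs = vapply(res$field_solution$cost_trace,
                                          function(x) utils::tail(x, 1),
                                          numeric(1)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(res, "files") <- c(files, evaluation = csv)
  invisible(res)
}

#' Score corrected versus uncorrected timecourses from NIfTI files
#'
#' Computes the per-metabolite odd/even Jaccard index of two interleaved
#' timecourse NIfTIs (typically the merged output of [run_correct()] and
#' the raw interleaved input) and writes a CSV report.
#'
#' @param corrected_path,uncorrected_path 5D NIfTI paths with matching
#'   frame counts.
#' @param config A [pipeline_config()].
#' @param out_csv Report path.
#' @return The report data frame, invisibly.
#' @export
run_evaluate <- function(corrected_path, uncorrected_path, config, out_csv) {
  p <- config$params
  co <- .read_stack_nii(corrected_path, 0, p)$stack
  un <- .read_stack_nii(uncorrected_path, 0, p)$stack
  if (dim(co$data)[4] != dim(un$data)[4])
    stop("frame-count mismatch between corrected and uncorrected stacks")
  j_post <- odd_even_jaccard(co, config$threshold)
  j_pre <- odd_even_jaccard(un, config$threshold)
  rep_ <- data.frame(metabolite = p$metabolites,
                     jaccard_pre = as.numeric(j_pre),
                     jaccard_post = as.numeric(j_post),
                     threshold = config$threshold,
                     stringsAsFactors = FALSE)
  utils::write.csv(rep_, out_csv, row.names = FALSE)
  invisible(rep_)
}
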