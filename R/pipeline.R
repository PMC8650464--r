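#' Run configuration for the end-to-end pipeline
#'
#' A single nested configuration drives every stage so a full experiment is
#' reproducible from one file. Each block is validated against the formal
#' arguments of the stage constructor it feeds; unknown keys are an error
#' naming the key.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @param phantom arguments for [phantom_spec()].
#' @param artifacts arguments for [artifact_spec()].
#' @param acquisition arguments for [acquisition_params()].
#' @param thresholds arguments for [segmentation_thresholds()].
#' @param mesh list with `factor` or `target_cells` for [build_mesh()].
#' @param solver arguments for [solver_config()].
#' @param source arguments for [source_spec()] (location defaults to the
#'   phantom injection site).
#' @param true_deff ground-truth diffusivity triplet used to simulate the
#'   phantom (named BT / PAS_Surf / PAS_Branch).
#' @param fit list: either `grid` (data.frame) or `center`/`factor`/`n`
#'   for [deff_grid()], plus optional `injection_radius`, `max_time`.
#' @param constants arguments for [transport_constants()].
#' @return A validated `run_config` object.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, phantom = list(),
                       artifacts = list(), acquisition = list(),
                       thresholds = list(), mesh = list(factor = 1L),
                       solver = list(), source = list(),
                       true_deff = c(BT = 0.10, PAS_Surf = 95,
                                     PAS_Branch = 60),
                       fit = list(), constants = list()) {
  chk <- function(block, fun, name, extra = character(0)) {
    bad <- setdiff(names(block), c(names(formals(fun)), extra))
    if (length(bad))
      stop_bt("unknown key(s) in config$%s: %s", name,
              paste(bad, collapse = ", "))
    block
  }
  chk(phantom, phantom_spec, "phantom")
  chk(artifacts, artifact_spec, "artifacts")
  chk(acquisition, acquisition_params, "acquisition")
  chk(thresholds, segmentation_thresholds, "thresholds")
  bad <- setdiff(names(mesh), c("factor", "target_cells"))
  if (length(bad))
    stop_bt("unknown key(s) in config$mesh: %s", paste(bad, collapse = ", "))
  chk(solver, solver_config, "solver")
  chk(source, source_spec, "source")
  bad <- setdiff(names(fit),
                 c("grid", "center", "factor", "n", "injection_radius",
                   "max_time"))
  if (length(bad))
    stop_bt("unknown key(s) in config$fit: %s", paste(bad, collapse = ", "))
  chk(constants, transport_constants, "constants")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 phantom = phantom, artifacts = artifacts,
                 acquisition = acquisition, thresholds = thresholds,
                 mesh = mesh, solver = solver, source = source,
                 true_deff = true_deff, fit = fit, constants = constants),
            class = "run_config")
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes, in order: phantom generation, ground-truth transport
#' simulation, DCE-MRI signal synthesis with artifacts, variable-flip-angle
#' T1 mapping, signal-to-concentration conversion, threshold segmentation,
#' mesh construction and tagging, interpolation of the concentration data
#' onto the mesh, the diffusivity grid search, and the physical metrics
#' report. When `config$out_dir` is set, every intermediate is written
#' there (NIfTI volumes, CSV tables, JSON reports) together with a
#' provenance record (full config, seed, package version).
#'
#' @param config a [run_config()] object.
#' @return List with all stage outputs (`ground_truth`, `signal`,
#'   `t1_fit`, `concentration`, `labels_est`, `mesh`, `fit`, `metrics`,
#'   `amount`), invisibly writable via `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ph_args <- config$phantom
  ph_args$seed <- config$seed
  spec <- do.call(phantom_spec, ph_args)
  gt <- build_phantom(spec)

  cfg <- do.call(solver_config, config$solver)
  src_args <- config$source
  if (is.null(src_args$location)) src_args$location <- spec$injection_site
  src <- do.call(source_spec, src_args)
  acq <- do.call(acquisition_params, config$acquisition)
  tru <- transport_params(config$true_deff)
  mesh_factor <- if (!is.null(config$mesh$factor)) config$mesh$factor else 1L
  gt <- simulate_truth(gt, tru, src, acq$frame_times,
                       mesh_factor = mesh_factor, cfg = cfg)

  art_args <- config$artifacts
  if (is.null(art_args$seed)) art_args$seed <- config$seed + 1000L
  art <- do.call(artifact_spec, art_args)
  sig <- synthesize_signal(gt$concentration, gt$t1_map, gt$brain_mask, acq,
                           art)

  t1fit <- fit_t1_vfa(sig$baseline_low, sig$baseline_high, acq)
  conc <- signal_to_concentration(sig, t1fit, acq)

  thr <- do.call(segmentation_thresholds, config$thresholds)
  labels_est <- segment_transport_regions(t1fit, conc, gt$brain_mask, thr,
                                          gt$artery_class_map)

  mesh <- attr(gt, "mesh")                 # same discretization as truth
  mesh <- tag_subdomains(mesh, labels_est)
  data_nodal <- interpolate_idw(conc, mesh)

  fit_args <- config$fit
  grid <- if (!is.null(fit_args$grid)) fit_args$grid else
    do.call(deff_grid, fit_args[intersect(names(fit_args),
                                          c("center", "factor", "n"))])
  mask_spec <- error_mask_spec(
    injection_radius = if (!is.null(fit_args$injection_radius))
      fit_args$injection_radius else 0.5,
    max_time = if (!is.null(fit_args$max_time)) fit_args$max_time else 52)
  fit <- grid_search(data_nodal, mesh, grid, src, cfg, mask_spec)

  cst <- do.call(transport_constants, config$constants)
  metrics <- metrics_report(fit$optimum, cst)
  amount <- total_amount(conc, gt$brain_mask)

  result <- list(config = config, ground_truth = gt, signal = sig,
                 t1_fit = t1fit, concentration = conc,
                 labels_est = labels_est, mesh = mesh, fit = fit,
                 metrics = metrics, amount = amount)
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- result$ground_truth$spec$voxel_size
  p <- function(...) file.path(out_dir, ...)
  write_nifti(result$ground_truth$labels$data, p("labels_true.nii"), vs,
              datatype = "int16")
  write_nifti(result$labels_est$data, p("labels_est.nii"), vs,
              datatype = "int16")
  t1 <- result$t1_fit$t1
  t1[is.na(t1)] <- 0
  write_nifti(t1, p("t1_map.nii"), vs)
  write_nifti(result$concentration$data, p("concentration.nii"), vs,
              time_step = diff(result$concentration$times)[1])
  utils::write.csv(result$amount, p("amount.csv"), row.names = FALSE)
  utils::write.csv(result$fit$surface, p("error_surface.csv"),
                   row.names = FALSE)
  write_metrics_report(result$metrics, p("metrics.json"))
  sidecar <- list(labels = as.list(label_codes()),
                  thresholds = result$labels_est$provenance)
  jsonlite::write_json(sidecar, p("labels_est.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  prov <- list(package = "braintransport",
               version = as.character(utils::packageVersion("braintransport")),
               seed = result$config$seed,
               config = unclass(result$config),
               r_version = R.version.string)
  prov$config$out_dir <- NULL
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
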