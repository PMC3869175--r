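# End-to-end pipeline: (1) shape analysis and template tailoring,
# (2) LoD-scheduled non-rigid registration, (3) variational mesh warping,
# (4) transmural linearization and quality/accuracy reporting.

#' Pipeline configuration
#'
#' @param input path to a NIfTI/MetaImage binary mask, or a
#'   [binary_mask()].
#' @param topology `"lv"` or `"biv"` (case-insensitive).
#' @param resolution element counts (radial, circ, long); defaults to the
#'   cohort configurations 1,12,6 (LV) and 2,9,8 (BiV).
#' @param apex_style `"collapsed"` or `"hole"`.
#' @param lod level of detail 1..5 (registration passes / node spacing).
#' @param truncate_base truncate basal anatomy below the basal plane.
#' @param basal_offset truncation offset (mm).
#' @param quad_order Gauss points per axis.
#' @param registration list of overrides passed to [register()]
#'   (`sigma_vox`, `reg_weight`, `max_iter`, `band_vox`, `node_spacings`).
#' @param output_ex,output_vtk,report optional output paths.
#' @param vtk_subdivision cells per element per axis for the VTK output.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic).
#' @param verbose log per-stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, topology = "lv",
                            resolution = NULL,
                            apex_style = "collapsed", lod = 3L,
                            truncate_base = TRUE, basal_offset = 5,
                            quad_order = 4L, registration = list(),
                            output_ex = NULL, output_vtk = NULL,
                            report = NULL, vtk_subdivision = 3L,
                            seed = 1L, verbose = FALSE) {
  topology <- toupper(topology)
  topology <- if (topology %in% c("BIV", "BIVENTRICULAR")) "BiV" else "LV"
  if (is.null(resolution))
    resolution <- if (topology == "BiV") c(2L, 9L, 8L) else c(1L, 12L, 6L)
  lod <- as.integer(lod)
  if (lod < 1L || lod > 5L) stop("lod must be in 1..5")
  if (any(resolution < 1L)) stop("resolution must be positive")
  structure(list(
    input = input, topology = topology,
    resolution = stats::setNames(as.integer(resolution),
                                 c("radial", "circ", "long")),
    apex_style = apex_style, lod = lod, truncate_base = truncate_base,
    basal_offset = basal_offset, quad_order = quad_order,
    registration = registration, output_ex = output_ex,
    output_vtk = output_vtk, report = report,
    vtk_subdivision = as.integer(vtk_subdivision),
    seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

# compact representation of a sparse mask: only the data slices, with the
# axial spacing equal to the interslice distance (world positions kept)
.compact_sparse <- function(mask) {
  if (is.null(mask$data_slices)) return(mask)
  ax <- mask$slice_axis
  sl <- sort(mask$data_slices)
  step <- if (length(sl) > 1) mean(diff(sl)) else 1
  vox <- switch(ax, mask$voxels[sl, , ], mask$voxels[, sl, ],
                mask$voxels[, , sl])
  spacing <- mask$spacing
  spacing[ax] <- spacing[ax] * step
  origin <- mask$origin
  origin[ax] <- origin[ax] + (sl[1] - 1) * mask$spacing[ax]
  binary_mask(vox, spacing, origin,
              data_slices = seq_len(dim(vox)[ax]), slice_axis = ax)
}

#' Run the full mesh personalization pipeline
#'
#' Executes shape analysis, template tailoring and synthesis, initial
#' affine alignment, template rasterization, LoD-scheduled non-rigid
#' registration (restricted to the data slices for sparse stacks),
#' variational projection of the displacement field onto the mesh DOFs,
#' transmural linearization, and metric reporting. Fully deterministic for
#' a fixed configuration.
#'
#' @param config a [pipeline_config()] (or a [binary_mask()], taken as the
#'   input with defaults).
#' @param ... when `config` is a mask: overrides forwarded to
#'   [pipeline_config()].
#' @return list with `mesh` (final), `mesh_prelinear`, `report`
#'   (a `quality_report`), `descriptor`, `template_spec`, `field`,
#'   `target_mask`, `timings` (seconds), `config`.
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "binary_mask"))
    config <- pipeline_config(input = config, ...)
  log_ <- function(fmt, ...) if (config$verbose)
    message(sprintf(paste0("[ventmesh] ", fmt), ...))
  tic <- function() Sys.time()
  secs <- function(t0) as.numeric(Sys.time() - t0, units = "secs")
  timings <- list()
  mask <- config$input
  if (is.character(mask)) mask <- read_mask(mask)
  if (!inherits(mask, "binary_mask")) stop("input must be a mask or a path")

  # --- stage 1: shape analysis + template tailoring -----------------------
  t0 <- tic()
  sparse <- !is.null(mask$data_slices) &&
    length(mask$data_slices) < dim(mask$voxels)[mask$slice_axis]
  ana_mask <- if (sparse) .compact_sparse(mask) else mask
  descriptor <- analyze_shape(ana_mask)
  target <- mask
  if (config$truncate_base) {
    target <- truncate_base(mask, descriptor$basal_plane,
                            config$basal_offset)
    ana2 <- if (sparse) .compact_sparse(target) else target
    descriptor <- analyze_shape(ana2)
  }
  base_spec <- template_spec(
    topology = config$topology, resolution = config$resolution,
    apex_style = config$apex_style, truncate_base = config$truncate_base,
    basal_offset = config$basal_offset)
  tspec <- tailor_template(descriptor, base_spec)
  template <- synthesize_template(tspec)
  aff <- initial_affine(.template_descriptor(tspec), descriptor)
  mesh0 <- transform_mesh(template, aff)
  timings$shape_analysis <- secs(t0)
  log_("shape analysis: wall %.1f mm, extent %.1f mm, axes ok (%.1fs)",
       descriptor$wall_thickness, descriptor$lv_extent_long,
       timings$shape_analysis)

  # --- stage 2: registration ---------------------------------------------
  t0 <- tic()
  domain <- NULL
  reg_target <- target
  if (sparse) {
    sd <- build_sparse_domain(target)
    reg_target <- sd$mask
    domain <- sd$domain
  }
  moving <- rasterize_mesh(mesh0, reg_target)
  reg_args <- c(list(fixed = reg_target, moving = moving,
                     config = lod_schedule(config$lod,
                       node_spacings = config$registration$node_spacings),
                     domain = domain,
                     sparse_axis = if (sparse) mask$slice_axis else NULL),
                config$registration[setdiff(names(config$registration),
                                            "node_spacings")])
  field <- do.call(register, reg_args)
  timings$registration <- secs(t0)
  log_("registration: %d passes, SSD %.0f -> %.0f (%.1fs)",
       field$config$passes, field$ssd_initial,
       utils::tail(field$ssd_pass, 1), timings$registration)

  # --- stage 3: variational warping --------------------------------------
  t0 <- tic()
  mesh1 <- project_displacement(mesh0, field,
                                quad_order = config$quad_order)
  timings$warp <- secs(t0)
  log_("variational warp: L2 residual %.3f mm (%.1fs)",
       attr(mesh1, "l2_residual"), timings$warp)

  # --- stage 4: quality enhancement + metrics ----------------------------
  t0 <- tic()
  mesh2 <- linearize_transmural(mesh1)
  metric_mask <- if (sparse) .compact_sparse(target) else target
  report <- quality_report(mesh2, metric_mask,
                           quad_order = config$quad_order)
  timings$postprocess <- secs(t0)
  log_("postprocess: error %.2f mm, quality %.3f, success %s (%.1fs)",
       report$fitting_error_mean, report$mesh_quality_mean,
       report$success, timings$postprocess)

  if (!is.null(config$output_ex)) write_ex(mesh2, config$output_ex)
  if (!is.null(config$output_vtk))
    write_vtk(mesh2, config$output_vtk, config$vtk_subdivision)
  result <- list(mesh = mesh2, mesh_prelinear = mesh1, report = report,
                 descriptor = descriptor, template_spec = tspec,
                 field = field, target_mask = target,
                 timings = timings, config = config)
  if (!is.null(config$report)) {
    rep_out <- list(
      success = report$success,
      fitting_error_mean = report$fitting_error_mean,
      fitting_error_max = report$fitting_error_max,
      fitting_error_weighted = report$fitting_error_weighted,
      mesh_quality_mean = report$mesh_quality_mean,
      mesh_quality_min = report$mesh_quality_min,
      per_element_q = report$per_element_q,
      thresholds = report$thresholds,
      lod = config$lod, topology = config$topology,
      resolution = as.list(config$resolution),
      seed = config$seed,
      timings = timings
    )
    jsonlite::write_json(rep_out, config$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  result
}

#' Command-line entry point
#'
#' Parses CLI flags and runs the pipeline; see `inst/scripts/ventmesh.R`
#' for a ready-to-use Rscript wrapper.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return invisibly, the [run_pipeline()] result.
#' @export
ventmesh_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "ventmesh --input mask.nii.gz [options]",
    option_list = list(
      optparse::make_option("--input", type = "character"),
      optparse::make_option("--topology", type = "character",
                            default = "lv"),
      optparse::make_option("--resolution", type = "character",
                            default = NULL,
                            help = "R,C,L element counts"),
      optparse::make_option("--apex", type = "character",
                            default = "collapsed"),
      optparse::make_option("--lod", type = "integer", default = 3L),
      optparse::make_option("--truncate-base", dest = "truncate_base",
                            action = "store_true", default = TRUE),
      optparse::make_option("--no-truncate-base", dest = "truncate_base",
                            action = "store_false"),
      optparse::make_option("--basal-offset", dest = "basal_offset",
                            type = "double", default = 5),
      optparse::make_option("--config", type = "character", default = NULL,
                            help = "key=value config file (flags override)"),
      optparse::make_option("--output-ex", dest = "output_ex",
                            type = "character", default = NULL),
      optparse::make_option("--output-vtk", dest = "output_vtk",
                            type = "character", default = NULL),
      optparse::make_option("--report", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--verbose", action = "store_true",
                            default = FALSE)
    ))
  opt <- optparse::parse_args(parser, args = args)
  file_opts <- list()
  if (!is.null(opt$config)) {
    ln <- readLines(opt$config)
    ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
    kv <- strsplit(ln, "=", fixed = TRUE)
    file_opts <- stats::setNames(lapply(kv, function(p) trimws(p[2])),
                                 vapply(kv, function(p) trimws(p[1]), ""))
  }
  pick <- function(flag, name, cast = identity) {
    if (!is.null(flag)) return(flag)
    if (!is.null(file_opts[[name]])) return(cast(file_opts[[name]]))
    NULL
  }
  input <- pick(opt$input, "input")
  if (is.null(input)) {
    optparse::print_help(parser)
    stop("--input is required")
  }
  res <- pick(opt$resolution, "resolution")
  if (!is.null(res)) res <- as.integer(strsplit(res, ",")[[1]])
  cfg <- pipeline_config(
    input = input,
    topology = pick(opt$topology, "topology"),
    resolution = res,
    apex_style = pick(opt$apex, "apex"),
    lod = pick(opt$lod, "lod", as.integer),
    truncate_base = pick(opt$truncate_base, "truncate_base", as.logical),
    basal_offset = pick(opt$basal_offset, "basal_offset", as.numeric),
    output_ex = pick(opt$output_ex, "output_ex"),
    output_vtk = pick(opt$output_vtk, "output_vtk"),
    report = pick(opt$report, "report"),
    seed = pick(opt$seed, "seed", as.integer),
    verbose = opt$verbose)
  invisible(run_pipeline(cfg))
}
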