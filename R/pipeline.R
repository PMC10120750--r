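#' Pipeline configuration
#'
#' Collects every step's parameters plus provenance (package version and
#' timestamp); the exact configuration used is attached to every run report
#' so results are regenerable.
#'
#' @param flow a [flow_config()] for the reference-surface cMCF.
#' @param relax a [relax_config()] for the spherical relaxation.
#' @param N UV grid rows (cols = 2N).
#' @param alpha topographic step size (voxels).
#' @param upsample signed-distance grid upsampling for the topographic space.
#' @param D_in inward topographic steps (NULL = auto).
#' @param remesh_fraction ACVD fraction for the reference surface.
#' @param topo_fraction ACVD fraction for the topographic mesh.
#' @param dilation_radius voxelization closing radius.
#' @param direct_unwrap skip the reference-surface step for genus-0 inputs.
#' @param seed seed for the stochastic metrics.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(flow = flow_config(), relax = relax_config(),
                            N = 128, alpha = 0.5, upsample = 2, D_in = NULL,
                            remesh_fraction = 0.9, topo_fraction = 0.5,
                            dilation_radius = 5, direct_unwrap = FALSE,
                            seed = 1) {
  structure(list(flow = flow, relax = relax, N = N, alpha = alpha,
                 upsample = upsample,
                 D_in = D_in, remesh_fraction = remesh_fraction,
                 topo_fraction = topo_fraction,
                 dilation_radius = dilation_radius,
                 direct_unwrap = direct_unwrap, seed = seed,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("cellwrap")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "pipeline_config")
}

#' Pipeline configuration tuned for protrusion quantification
#'
#' For measuring protrusion heights the reference surface should be the
#' cortical shape with protrusions fully absorbed; residual bumps in the
#' reference suppress the height signal `h = d - d_ref`. This preset
#' therefore runs the reference cMCF past the automatic elbow
#' (`t_min = 25`) and uses the default protrusion-segmentation chart size.
#'
#' @param N UV grid rows.
#' @param ... further arguments to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
segmentation_pipeline_config <- function(N = 128, ...) {
  pipeline_config(flow = flow_config(t_min = 25, max_iters = 40), N = N, ...)
}

#' Run the full unwrapping pipeline
#'
#' Executes the six mapping steps on an input surface: (1) cMCF to the
#' automatic stop plus voxelization/remeshing into a genus-0 reference
#' surface, with bijectivity restored by nearest-neighbour mesh matching
#' (skipped when the input is genus-0 and `direct_unwrap` is set); (2-3)
#' quasi-conformal spherical parameterization and equiareal relaxation;
#' (4) weighted-PCA unwrapping axis (|H| weights) and equirectangular UV
#' chart; (5) topographic space construction and volume resampling; (6)
#' topographic mesh with its Cartesian twin. Every representation plus a
#' distortion report is returned; failures surface as a structured result
#' (`success = FALSE`, failed stage, message), not as crashes.
#'
#' @param input a `surface_mesh` or binary `volume_image`.
#' @param config a [pipeline_config()].
#' @return list of class `unwrap_result` with `success`, `stage`,
#'   `reference`, `sphere`, `uv`, `topo_space`, `topo_binary`, `topo_mesh`,
#'   `report`, `config`.
#' @export
run_unwrap <- function(input, config = pipeline_config()) {
  stage <- "input"
  res <- list(success = FALSE, stage = stage, config = config)
  fail <- function(stage, msg) {
    res$stage <- stage
    res$message <- msg
    structure(res, class = "unwrap_result")
  }
  mesh <- if (inherits(input, "volume_image"))
    tryCatch(remesh(input, 0.9, dilation_radius = config$dilation_radius),
             error = function(e) NULL)
  else input
  if (is.null(mesh)) return(fail("input", "could not mesh the input binary"))
  topo_in <- euler_genus(mesh)
  # --- Step 1: genus-0 reference ------------------------------------------
  stage <- "reference"
  if (config$direct_unwrap && topo_in$watertight && topo_in$genus == 0) {
    ref <- mesh
    ref_match <- seq_len(nrow(mesh$vertices))
    flow <- NULL
  } else {
    flow <- tryCatch(cmcf(mesh, config$flow), error = function(e) NULL)
    if (is.null(flow)) return(fail(stage, "cMCF failed"))
    inter <- flow_mesh(flow)
    # restore the input's scale and position (the flow normalizes both);
    # volumes are matched rather than areas so the smooth reference stays on
    # the cortex instead of inflating outside it
    sc <- (mesh_volume(mesh) / mesh_volume(inter))^(1 / 3)
    inter$vertices <- inter$vertices * sc
    ctr_in <- colMeans(mesh$vertices)
    inter$vertices <- sweep(inter$vertices, 2, -ctr_in + colMeans(inter$vertices))
    ref <- tryCatch(remesh(inter, config$remesh_fraction,
                           dilation_radius = config$dilation_radius),
                    error = function(e) NULL)
    if (is.null(ref))
      return(fail(stage, "voxelization/remeshing of the flowed surface failed"))
    rt <- euler_genus(ref)
    if (!rt$watertight || rt$genus != 0)
      return(fail(stage, sprintf(
        "reference surface is not genus-0 (genus %d, %d boundaries): holes or handles too large for closing",
        rt$genus, rt$n_boundaries)))
    ref_match <- restore_bijectivity(inter, ref)$index
  }
  res$reference <- ref
  res$input_mesh <- mesh
  # --- Steps 2-3: sphere ---------------------------------------------------
  stage <- "sphere"
  sp <- tryCatch(conformal_sphere_map(ref), error = function(e) NULL)
  if (is.null(sp)) return(fail(stage, "spherical parameterization failed"))
  rel <- tryCatch(relax_area_distortion(sp, config$relax),
                  error = function(e) NULL)
  if (is.null(rel)) return(fail(stage, "area-distortion relaxation failed"))
  res$sphere <- rel
  # --- Step 4: axis + UV ---------------------------------------------------
  stage <- "uv"
  cellb <- tryCatch(voxelize(mesh, config$dilation_radius),
                    error = function(e) NULL)
  if (is.null(cellb)) return(fail(stage, "cell voxelization failed"))
  Href <- tryCatch(as.numeric(mean_curvature_from_sdf(ref,
                     dilation_radius = config$dilation_radius)),
                   error = function(e) NULL)
  rot <- if (is.null(Href)) optimal_axis(rel)
         else optimal_axis(rel, abs(Href))
  uv <- tryCatch(uv_map(rel, N = config$N, rotation = rot),
                 error = function(e) NULL)
  if (is.null(uv)) return(fail(stage, "UV mapping failed"))
  res$uv <- uv
  # --- Step 5: topographic space ------------------------------------------
  stage <- "topography"
  ts <- tryCatch(build_topographic_space(uv, cellb, alpha = config$alpha,
                                         D_in = config$D_in,
                                         upsample = config$upsample),
                 error = function(e) NULL)
  if (is.null(ts)) return(fail(stage, "topographic space construction failed"))
  tb <- resample_volume(ts, cellb)
  res$topo_space <- ts
  res$topo_binary <- (tb >= 0.5) * 1
  # --- Step 6: topographic mesh -------------------------------------------
  stage <- "topo_mesh"
  tm <- tryCatch(topographic_mesh(res$topo_binary, ts,
                                  target_fraction = config$topo_fraction),
                 error = function(e) NULL)
  if (is.null(tm)) return(fail(stage, "topographic meshing failed"))
  res$topo_mesh <- tm
  # --- report --------------------------------------------------------------
  cmp <- compare_meshes(tm$cartesian_twin, mesh, seed = config$seed)
  res$report <- list(
    input_genus = topo_in$genus, input_watertight = topo_in$watertight,
    flow_stop = if (!is.null(flow)) flow$stop_iteration else NA_integer_,
    conformal_error_step2 = sp$conformal_error,
    area_distortion_step3 = rel$area_distortion,
    relax_iterations = rel$stop_iteration,
    uv_fallback_pixels = uv$n_fallback,
    topo_nonmonotone = ts$n_nonmonotone,
    stopo_vs_input = cmp)
  res$success <- TRUE
  res$stage <- "done"
  structure(res, class = "unwrap_result")
}

#' @export
print.unwrap_result <- function(x, ...) {
  if (x$success) {
    cat("unwrap_result: all steps completed\n")
    cat(sprintf("  Q (step 2) %.4f | lambda (step 3) %.4f in %d iters\n",
                x$report$conformal_error_step2, x$report$area_distortion_step3,
                x$report$relax_iterations))
    cat(sprintf("  Stopo vs input: CD %.2f vox, dA %.1f%%\n",
                x$report$stopo_vs_input$chamfer,
                x$report$stopo_vs_input$delta_area_pct))
  } else {
    cat("unwrap_result: FAILED at stage", x$stage, "-", x$message, "\n")
  }
  invisible(x)
}

#' Restore vertex correspondence between a remeshed and an original surface
#'
#' Matches every vertex of the remeshed surface to its nearest point on the
#' source mesh (nearest vertex), giving the index map through which fields
#' are transferred; the composition input <-> flowed intermediate <->
#' remeshed reference is the declared bijection of the pipeline.
#'
#' @param intermediate the source `surface_mesh` (e.g. the cMCF output).
#' @param remeshed the remeshed `surface_mesh`.
#' @param warn_distance distance (voxels) above which matches are
#'   considered poor.
#' @return list: `index` (per-remeshed-vertex source index), `distance`,
#'   `transfer(field)` closure interpolating per-vertex fields.
#' @export
restore_bijectivity <- function(intermediate, remeshed, warn_distance = 3) {
  nn <- .cpp_nn_index(remeshed$vertices, intermediate$vertices)
  frac_bad <- mean(nn$distance > warn_distance)
  if (frac_bad > 0.01)
    warning(sprintf("%.1f%% of vertices matched farther than %g voxels",
                    100 * frac_bad, warn_distance))
  list(index = nn$index, distance = nn$distance,
       transfer = function(field) field[nn$index])
}

#' Robustness harness over a battery of phantom specifications
#'
#' Runs the full pipeline over a list of phantom specs (including defective
#' ones) and reports the fraction completing all steps, mirroring a
#' success-rate audit at phantom scale.
#'
#' @param specs list of [phantom_spec()]s.
#' @param config a [pipeline_config()].
#' @return list: `success_rate`, `results` (per-spec `unwrap_result`s).
#' @export
unwrap_battery <- function(specs, config = pipeline_config()) {
  results <- lapply(specs, function(sp) {
    mesh <- make_cell_mesh(sp)
    tryCatch(run_unwrap(mesh, config),
             error = function(e) structure(list(success = FALSE,
                                                stage = "error",
                                                message = conditionMessage(e)),
                                           class = "unwrap_result"))
  })
  list(success_rate = mean(vapply(results, function(r) r$success, TRUE)),
       results = results)
}
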