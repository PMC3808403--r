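# ---------------------------------------------------------------------------
# End-to-end pipeline: mesh -> boundary conditions -> solve -> balance check
# -> seed -> trace -> smooth -> metrics -> artifacts. Deterministic: same
# config, same outputs.
# ---------------------------------------------------------------------------

#' Build a validated pipeline configuration
#'
#' @param mesh_file optional path to a Gmsh MSH file; mutually exclusive
#'   with `geometry`.
#' @param geometry optional list `list(shape = , ...)` with `shape` one of
#'   `"rect2d"`, `"fan2d"`, `"annulus_sector2d"`, `"box3d"` and the shape
#'   parameters of the corresponding generator.
#' @param patch_map named map from MSH physical-group names to patch labels.
#' @param total_flux total attachment flux magnitude (default 1; only scales
#'   the field).
#' @param inner_rtol,outer_tol,max_outer,pin_element,pin_value solver
#'   settings, see [solve_potential()].
#' @param seed_patch patch the tracts are seeded on (default `"insertion"`,
#'   where pennation is measured).
#' @param direction tracing direction from the seed patch (default
#'   `"upstream"`: seeds on the outflow attachment).
#' @param per_face seeds per patch face.
#' @param n_points,subsample_target,smoothing resampling settings, see
#'   [smooth_resample()]; `n_points` must be at least 6 (the pennation
#'   procedure needs five points past the seed).
#' @param out_dir output directory (created); `NULL` disables file output.
#' @param seed integer seed for any randomized option (the default pipeline
#'   is fully deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(mesh_file = NULL, geometry = NULL,
                       patch_map = NULL, total_flux = 1,
                       inner_rtol = 1e-8, outer_tol = 1e-8, max_outer = 50L,
                       pin_element = 1L, pin_value = 0,
                       seed_patch = "insertion",
                       direction = c("upstream", "downstream"),
                       per_face = 1L, n_points = 100L,
                       subsample_target = 30L, smoothing = NULL,
                       out_dir = NULL, seed = 1L) {
  direction <- match.arg(direction)
  if (is.null(mesh_file) == is.null(geometry))
    stop("config error: give exactly one of mesh_file or geometry")
  if (inner_rtol <= 0 || outer_tol <= 0)
    stop("config error: tolerances must be positive")
  if (n_points < 6L)
    stop("config error: n_points must be >= 6 for the pennation procedure")
  structure(list(
    mesh_file = mesh_file, geometry = geometry, patch_map = patch_map,
    total_flux = total_flux, inner_rtol = inner_rtol, outer_tol = outer_tol,
    max_outer = max_outer, pin_element = pin_element, pin_value = pin_value,
    seed_patch = seed_patch, direction = direction, per_face = per_face,
    n_points = n_points, subsample_target = subsample_target,
    smoothing = smoothing, out_dir = out_dir, seed = seed
  ), class = "run_config")
}

build_geometry <- function(g) {
  shape <- g$shape
  switch(shape,
    rect2d = make_rect2d(g$L %||% 10, g$W %||% 1, g$h %||% 0.25),
    fan2d = make_fan2d(g$base_width %||% 4, g$tip_width %||% 1,
                       g$height %||% 3, g$h %||% 0.15),
    annulus_sector2d = make_annulus_sector2d(
      g$r_inner %||% 1, g$r_outer %||% 2, g$Theta %||% (pi / 2),
      g$h %||% 0.05),
    box3d = make_box3d(g$L %||% 10, g$W %||% 4, g$H %||% 4, g$h %||% 0.6),
    stop("config error: unknown shape '", shape, "'")
  )
}

#' Run the full fascicle-reconstruction pipeline
#'
#' Reads or generates the mesh, imposes the boundary conditions, solves the
#' Laplace field, verifies conservation (aborting before tracing on
#' failure), seeds and traces fascicle tracts, smooths and resamples them,
#' computes fascicle length and pennation angle per tract, and (when
#' `out_dir` is set) writes VTK mesh + vectors, tract polylines, a metrics
#' CSV, the resolved config, and a JSON run report.
#'
#' @param config a `run_config`.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with `mesh`, `bc`, `field`, `balance`,
#'   `tracts`, `smoothed`, `metrics`, `summary`, `report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  t0 <- proc.time()[["elapsed"]]

  say("mesh", "building mesh")
  mesh <- if (!is.null(config$mesh_file))
    read_gmsh_msh(config$mesh_file, config$patch_map)
  else build_geometry(config$geometry)

  say("bc", "uniform attachment flux, total ", config$total_flux)
  bc <- if (!is.null(config$geometry) &&
            identical(config$geometry$shape, "annulus_sector2d") &&
            isTRUE(config$geometry$oracle_bc))
    annulus_sector_bc(mesh, config$geometry$c_const %||% 1)
  else make_uniform_flux_bc(mesh, "origin", "insertion", config$total_flux)

  say("solve", "finite-volume Laplace solve")
  field <- solve_potential(mesh, bc, inner_rtol = config$inner_rtol,
                           outer_tol = config$outer_tol,
                           max_outer = config$max_outer,
                           pin_element = config$pin_element,
                           pin_value = config$pin_value)
  balance <- check_balance(mesh, field, tol = config$outer_tol)
  say("balance", sprintf("||r||2/Q = %.3e", balance$two_norm))
  if (!balance$pass)
    stop("non-conservative flux field: balance check failed (",
         format(balance$two_norm), ")")

  say("trace", "seeding patch '", config$seed_patch, "'")
  seeds <- seed_patch_centroids(mesh, config$seed_patch, config$per_face)
  tracts <- lapply(seeds, function(s)
    trace_fascicle(mesh, field, s, direction = config$direction))
  ok <- vapply(tracts, function(tr) tr$status == "reached-attachment",
               logical(1))
  say("trace", sum(ok), "/", length(ok), " tracts reached an attachment")

  say("metrics", "smoothing, length, pennation")
  smoothed <- vector("list", length(tracts))
  rows <- vector("list", length(tracts))
  for (i in seq_along(tracts)) {
    tr <- tracts[[i]]
    len <- NA_real_; pen <- NA_real_
    if (ok[i]) {
      # tracts through very few elements cannot be splined; keep NA metrics
      sm <- tryCatch(
        smooth_resample(tr, n_points = config$n_points,
                        subsample_target = config$subsample_target,
                        smoothing = config$smoothing),
        error = function(e) {
          if (grepl("tract too short|degenerate", conditionMessage(e))) NULL
          else stop(e)
        })
      if (!is.null(sm)) {
        smoothed[[i]] <- sm
        len <- fascicle_length(sm)
        nhat <- seed_tangent_normal(mesh, tr$seed_face)
        pts <- sm$points
        if (tr$seed_at == "end")
          pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
        pen <- pennation_angle(pts, nhat)
      }
    }
    rows[[i]] <- data.frame(seed_id = tr$seed_id,
                            patch = config$seed_patch, status = tr$status,
                            length_mm = len, pennation_deg = pen)
  }
  metrics <- do.call(rbind, rows)
  summary_tab <- summarize_tracts(metrics[ok, , drop = FALSE])

  report <- list(
    n_elements = nrow(mesh$elements), n_tracts = length(tracts),
    tract_success_rate = mean(ok),
    residual_two_norm = balance$two_norm,
    boundary_balance = balance$boundary_balance,
    outer_iterations = field$report$outer_iterations,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    config = config[setdiff(names(config), "out_dir")]
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(config$out_dir, f)
    say("write", "artifacts -> ", config$out_dir)
    write_vtk(mesh, op("mesh.vtk"), tracts = tracts[ok],
              cell_vectors = field$vectors)
    has_sm <- !vapply(smoothed, is.null, logical(1))
    if (any(has_sm))
      write_vtk_polylines(smoothed[has_sm], op("tracts_smoothed.vtk"),
                          scalars = list(
                            length_mm = metrics$length_mm[has_sm],
                            pennation_deg = metrics$pennation_deg[has_sm]))
    write.csv(summary_tab, op("metrics.csv"), row.names = FALSE)
    jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    jsonlite::write_json(unclass(config), op("config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(mesh = mesh, bc = bc, field = field, balance = balance,
                 tracts = tracts, smoothed = smoothed, metrics = metrics,
                 summary = summary_tab, report = report))
}

#' Run a canonical synthetic demo
#'
#' Builds one of the bundled synthetic geometries with its canonical
#' boundary conditions, runs the full pipeline, and for 2D shapes
#' optionally writes a tract plot. The annulus demo uses the exact `c/r`
#' radial-edge flux and reports the maximum relative element-speed error
#' against the closed-form oracle.
#'
#' @param shape one of `"rect2d"`, `"fan2d"`, `"annulus_sector2d"`,
#'   `"box3d"`.
#' @param h target edge length; `NULL` for the shape's default.
#' @param out_dir optional output directory.
#' @param plot write a PDF tract plot (2D shapes with `out_dir` only).
#' @param quiet suppress stage messages.
#' @param ... overrides passed to [run_config()].
#' @return invisibly, the [run_pipeline()] result (with `oracle` errors
#'   added for the annulus).
#' @examples
#' res <- run_demo("rect2d", h = 0.5, quiet = TRUE)
#' res$report$tract_success_rate
#' subset(res$summary, row_type == "mean")
#' @export
run_demo <- function(shape = c("rect2d", "fan2d", "annulus_sector2d",
                               "box3d"),
                     h = NULL, out_dir = NULL, plot = FALSE, quiet = FALSE,
                     ...) {
  shape <- match.arg(shape)
  geom <- switch(shape,
    rect2d = list(shape = "rect2d", L = 10, W = 1, h = h %||% 0.25),
    fan2d = list(shape = "fan2d", base_width = 4, tip_width = 1, height = 3,
                 h = h %||% 0.15),
    annulus_sector2d = list(shape = "annulus_sector2d", r_inner = 1,
                            r_outer = 2, Theta = pi / 2, h = h %||% 0.05,
                            oracle_bc = TRUE, c_const = 1),
    box3d = list(shape = "box3d", L = 10, W = 4, H = 4, h = h %||% 0.6))
  cfg <- run_config(geometry = geom, out_dir = out_dir, ...)
  res <- run_pipeline(cfg, quiet = quiet)
  if (shape == "annulus_sector2d") {
    oracle <- annulus_closed_form(geom$r_inner, geom$r_outer, geom$Theta,
                                  geom$c_const)
    r_c <- sqrt(rowSums(res$mesh$elem_centroid^2))
    speed <- sqrt(rowSums(res$field$vectors^2))
    res$oracle <- list(
      max_speed_rel_error = max(abs(speed - oracle$speed(r_c)) /
                                  oracle$speed(r_c)))
    res$report$max_oracle_speed_error <- res$oracle$max_speed_rel_error
  }
  if (plot && !is.null(out_dir) && res$mesh$dim == 2L)
    plot_tracts_2d(res, file.path(out_dir, paste0(shape, "_tracts.pdf")))
  invisible(res)
}

plot_tracts_2d <- function(res, path) {
  grDevices::pdf(path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  mesh <- res$mesh
  bnd <- boundary_faces(mesh)
  rng <- apply(mesh$nodes, 2L, range)
  graphics::plot(NA, xlim = rng[, 1L], ylim = rng[, 2L], asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", main = "fascicle tracts")
  for (f in bnd) {
    p <- mesh$nodes[mesh$faces[f, ], ]
    graphics::lines(p[, 1L], p[, 2L], col = "grey60")
  }
  ok <- vapply(res$tracts, function(tr) tr$status == "reached-attachment",
               logical(1))
  for (tr in res$tracts[ok])
    graphics::lines(tr$points[, 1L], tr$points[, 2L], col = "firebrick")
  invisible(path)
}

#' Validate a mesh + boundary-condition setup without solving
#'
#' @param config a `run_config`.
#' @return list with the mesh summary and boundary-flux balance; errors
#'   propagate with stage context.
#' @export
check_setup <- function(config) {
  mesh <- if (!is.null(config$mesh_file))
    read_gmsh_msh(config$mesh_file, config$patch_map)
  else build_geometry(config$geometry)
  bc <- make_uniform_flux_bc(mesh, "origin", "insertion", config$total_flux)
  list(dim = mesh$dim, n_elements = nrow(mesh$elements),
       n_boundary_faces = length(boundary_faces(mesh)),
       patches = lengths(mesh$patches),
       balance = sum(bc$flux) / bc$total_inflow)
}

#' Load a pipeline configuration from a JSON file
#'
#' Flat JSON object whose keys mirror the arguments of [run_config()];
#' explicit `overrides` (e.g. from CLI flags) win over file values.
#'
#' @param path JSON file path.
#' @param overrides named list of overriding values.
#' @return a `run_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}
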