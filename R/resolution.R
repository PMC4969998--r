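# Resolution-versus-error analysis: remesh a model to a ladder of target
# mean edge lengths, recompute every measurement per rung, and express each
# as a relative error against the densest model (the input itself).

#' Relative measurement error against a reference model
#'
#' `|reference - model| / reference * 100`. The error of the densest model
#' against itself is 0 by construction. The absolute value is used so that a
#' coarse model slightly exceeding the reference still reports a positive
#' error percentage.
#'
#' @param reference_value measurement on the reference (densest) model;
#'   must be nonzero.
#' @param model_value measurement on the coarser model.
#' @return Error in percent.
#' @export
relative_error <- function(reference_value, model_value) {
  if (any(reference_value == 0))
    stop("reference value must be nonzero", call. = FALSE)
  abs(reference_value - model_value) / abs(reference_value) * 100
}

#' Remesh to a target mean edge length
#'
#' Isotropic remeshing (iterated long-edge split, short-edge collapse,
#' valence-equalising flips and tangential relaxation with vertices
#' projected back onto the input surface) until the mean edge length falls
#' within 10% of the target. Only coarsening is supported: the target must
#' be at least the current mean edge length, matching the use of mean vertex
#' spacing as the resolution dial of a scan-processing pipeline. Topology
#' (closedness, boundary loops) is preserved.
#'
#' @param mesh a manifold [trimesh()].
#' @param target_mean_edge target mean edge length in mm.
#' @param iterations maximum remeshing iterations (default 15).
#' @return A [trimesh()] with `mean_edge_length` within `[0.9, 1.1] *
#'   target_mean_edge`.
#' @export
remesh_to_resolution <- function(mesh, target_mean_edge, iterations = 15L) {
  stopifnot_mesh(mesh)
  cur <- mean_edge_length(mesh)
  if (target_mean_edge < cur * 0.999)
    stop(sprintf(
      "target mean edge (%.3g mm) below current mean (%.3g mm): only coarsening is supported",
      target_mean_edge, cur), call. = FALSE)
  res <- cpp_remesh(mesh$vertices, mesh$faces, target_mean_edge,
                    as.integer(iterations))
  if (!res$converged)
    stop(sprintf(
      "could not reach target %.3g mm in %d iterations (achieved mean %.3g mm); mesh too small?",
      target_mean_edge, as.integer(iterations), res$mean_edge),
      call. = FALSE)
  trimesh(res$vertices, res$faces)
}

#' Resolution ladder study
#'
#' Remeshes the input to each coarser target resolution, measures area,
#' volume (closed meshes only), S/V ratio and optionally a Dijkstra path
#' between two snapped endpoints on every rung, and reports each measurement
#' together with its relative error against the input mesh, which serves as
#' the densest reference model.
#'
#' For the path measurement the endpoints are carried across resolutions as
#' 3D coordinates and snapped to the nearest vertex of each remeshed rung.
#'
#' @param mesh the reference (densest) model.
#' @param targets coarse-to-fine target mean edge lengths (mm), all at least
#'   the mesh's own mean edge length.
#' @param path optional length-2 vector of vertex indices on `mesh` between
#'   which a Dijkstra distance is measured per rung.
#' @param iterations passed to [remesh_to_resolution()].
#' @return An object of class `"resolution_table"`: a data.frame with one
#'   row per model (coarsest first, reference last) and columns
#'   `target_mean_edge`, `mean_edge_length`, `vertices`, `faces`, `area`,
#'   `volume`, `sv_ratio`, `path_length`, plus `area_error`, `volume_error`,
#'   `sv_error`, `path_error` in percent. The reference row has all errors
#'   exactly 0. Attribute `"reference"` gives its row index.
#' @export
resolution_study <- function(mesh, targets, path = NULL, iterations = 15L) {
  stopifnot_mesh(mesh)
  targets <- as.numeric(targets)
  if (length(targets) == 0L) stop("no target resolutions", call. = FALSE)
  if (is.unsorted(rev(targets), strictly = FALSE))
    stop("targets must be ordered coarse to fine (decreasing)",
         call. = FALSE)
  closed <- validate_mesh(mesh)$is_closed
  if (!closed)
    warning("open mesh: volume and S/V columns not reported", call. = FALSE)
  endpoints <- NULL
  if (!is.null(path)) {
    stopifnot(length(path) == 2L)
    endpoints <- mesh$vertices[as.integer(path), , drop = FALSE]
  }
  meshes <- c(lapply(targets, function(tg)
    remesh_to_resolution(mesh, tg, iterations)), list(mesh))
  rows <- lapply(seq_along(meshes), function(i) {
    m <- meshes[[i]]
    area <- surface_area(m)
    vol <- if (closed) enclosed_volume(m) else NA_real_
    plen <- NA_real_
    if (!is.null(endpoints)) {
      s <- snap_to_vertex(m, endpoints[1L, ])
      e <- snap_to_vertex(m, endpoints[2L, ])
      plen <- dijkstra_path(m, s, e)$length
    }
    data.frame(
      target_mean_edge = if (i <= length(targets)) targets[i] else NA_real_,
      mean_edge_length = mean_edge_length(m),
      vertices = nrow(m$vertices),
      faces = nrow(m$faces),
      area = area,
      volume = vol,
      sv_ratio = if (closed) area / vol else NA_real_,
      path_length = plen)
  })
  tab <- do.call(rbind, rows)
  ref <- nrow(tab)
  tab$area_error <- relative_error(tab$area[ref], tab$area)
  tab$volume_error <- if (closed)
    relative_error(tab$volume[ref], tab$volume) else NA_real_
  tab$sv_error <- if (closed)
    relative_error(tab$sv_ratio[ref], tab$sv_ratio) else NA_real_
  tab$path_error <- if (!is.null(endpoints))
    relative_error(tab$path_length[ref], tab$path_length) else NA_real_
  attr(tab, "reference") <- ref
  class(tab) <- c("resolution_table", "data.frame")
  tab
}

#' Coarsest resolution meeting an error tolerance
#'
#' Scans the study table for the coarsest (largest) mean edge length whose
#' every reported error is at or below the tolerance; the answer to "how
#' coarse a model is still accurate enough?".
#'
#' @param table a `"resolution_table"` from [resolution_study()].
#' @param tolerance_percent error tolerance in percent.
#' @return The coarsest admissible mean edge length (mm).
#' @export
resolution_threshold <- function(table, tolerance_percent) {
  if (nrow(table) == 0L) stop("empty resolution table", call. = FALSE)
  err_cols <- intersect(c("area_error", "volume_error", "sv_error",
                          "path_error"), names(table))
  errs <- as.matrix(table[, err_cols, drop = FALSE])
  ok <- apply(errs, 1L, function(r) all(is.na(r) | r <= tolerance_percent))
  ok <- ok & apply(errs, 1L, function(r) any(!is.na(r)))
  if (!any(ok))
    stop("no resolution meets the ", tolerance_percent, "% tolerance",
         call. = FALSE)
  max(table$mean_edge_length[ok])
}

#' @export
print.resolution_table <- function(x, ...) {
  y <- as.data.frame(x)
  num <- c("area", "volume", "path_length")
  for (nm in intersect(num, names(y))) y[[nm]] <- round(y[[nm]])
  for (nm in grep("_error$", names(y), value = TRUE))
    y[[nm]] <- round(y[[nm]], 2L)
  print(y, ...)
  invisible(x)
}
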