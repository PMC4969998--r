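# Detection and filling of small holes left where thorns or prickles
# scattered the scanner's light, so that area (and, once every loop is
# closed, volume) can be recomputed on the repaired surface.

#' Detect thorn holes
#'
#' Boundary loops with perimeter at most `max_perimeter`, sorted by
#' perimeter ascending. Large loops -- the leaf margin, the cut where the
#' pot was removed -- are excluded by the threshold.
#'
#' @param mesh a manifold [trimesh()].
#' @param max_perimeter largest loop perimeter (mm) still considered a hole
#'   (default 50).
#' @return List of `"boundary_loop"` objects (possibly empty).
#' @export
detect_holes <- function(mesh, max_perimeter = 50) {
  loops <- boundary_loops(mesh)
  per <- vapply(loops, `[[`, numeric(1L), "perimeter")
  keep <- per <= max_perimeter
  loops[keep][order(per[keep])]
}

#' Fill boundary loops
#'
#' Closes each loop with a triangle fan from the loop centroid (added as a
#' new vertex). Existing vertices are never moved and existing faces never
#' altered, so the repair is purely additive; each filled loop removes one
#' boundary loop. Self-intersecting fills of highly non-planar loops are not
#' detected -- the method is meant for the small, nearly planar punctures
#' thorns leave behind.
#'
#' @param mesh a manifold [trimesh()].
#' @param loops list of `"boundary_loop"` objects belonging to `mesh`
#'   (from [detect_holes()] or [boundary_loops()]).
#' @return A [trimesh()] with the loops closed.
#' @export
fill_holes <- function(mesh, loops) {
  stopifnot_mesh(mesh)
  if (length(loops) == 0L) return(mesh)
  v <- mesh$vertices
  newf <- list()
  for (lp in loops) {
    cyc <- lp$vertices
    if (length(cyc) < 3L) stop("boundary loop with fewer than 3 vertices",
                               call. = FALSE)
    centroid <- colMeans(v[cyc, , drop = FALSE])
    v <- rbind(v, centroid)
    ci <- nrow(v)
    nxt <- c(cyc[-1L], cyc[1L])
    # loop edges a->b follow face winding; fan triangles traverse b->a
    newf[[length(newf) + 1L]] <- cbind(nxt, cyc, ci)
  }
  trimesh(v, rbind(mesh$faces, do.call(rbind, newf)))
}

#' Area accounting before and after repair
#'
#' @param before mesh with holes.
#' @param after the same mesh after [fill_holes()].
#' @return List with `area_before`, `area_after`, `filled_area` (mm^2);
#'   `filled_area = area_after - area_before`.
#' @export
area_report <- function(before, after) {
  a0 <- surface_area(before)
  a1 <- surface_area(after)
  list(area_before = a0, area_after = a1, filled_area = a1 - a0)
}
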