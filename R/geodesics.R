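#' Weighted edge graph of a mesh
#'
#' Converts the mesh into an undirected graph whose nodes are the vertices
#' and whose edge weights are the Euclidean edge lengths, the substrate for
#' shortest-route computation along the triangle edges.
#'
#' @param mesh a [trimesh()].
#' @return An object of class `"edge_graph"`: a list with `n_vertices` and an
#'   edge table `edges` (`v1`, `v2`, `length`).
#' @export
build_edge_graph <- function(mesh) {
  stopifnot_mesh(mesh)
  e <- mesh_edges(mesh)
  zero <- e$length == 0
  if (any(zero)) {
    i <- which(zero)[1L]
    stop(sprintf(
      "zero-length edge between vertices %d and %d (unwelded duplicates?)",
      e$v1[i], e$v2[i]), call. = FALSE)
  }
  structure(list(n_vertices = nrow(mesh$vertices),
                 edges = e[, c("v1", "v2", "length")]),
            class = "edge_graph")
}

#' Shortest edge path between two vertices (Dijkstra)
#'
#' The mesh-based distance between two points: the minimal-length route along
#' triangle edges, found with Dijkstra's algorithm on the edge graph. The
#' search stops as soon as the destination is settled. This distance always
#' overestimates the true surface geodesic (paths are restricted to edges)
#' and is never shorter than the straight-line chord between the endpoints.
#'
#' @param mesh a [trimesh()].
#' @param from,to vertex indices.
#' @return An object of class `"geodesic_path"`: list with `vertices` (ordered
#'   indices from `from` to `to`) and `length` (mm).
#' @export
dijkstra_path <- function(mesh, from, to) {
  g <- build_edge_graph(mesh)
  n <- g$n_vertices
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || from > n || to < 1L || to > n)
    stop("vertex index out of range", call. = FALSE)
  if (from == to)
    return(structure(list(vertices = from, length = 0),
                     class = "geodesic_path"))
  res <- cpp_dijkstra(n, g$edges$v1, g$edges$v2, g$edges$length, from, to)
  if (!is.finite(res$dist[to]))
    stop("no path: vertices ", from, " and ", to,
         " lie in different connected components", call. = FALSE)
  path <- to
  v <- to
  while (v != from) {
    v <- res$parent[v]
    path <- c(v, path)
  }
  structure(list(vertices = path, length = res$dist[to]),
            class = "geodesic_path")
}

#' @export
print.geodesic_path <- function(x, ...) {
  cat(sprintf("geodesic path: %d vertices, length %.6g mm\n",
              length(x$vertices), x$length))
  invisible(x)
}

#' Edge-graph distance field from a source set
#'
#' Full Dijkstra distance map from a set of source vertices; used internally
#' and as a comparison bound for the fast-marching field (edge-restricted
#' paths can only be longer than surface paths).
#'
#' @param mesh a [trimesh()].
#' @param sources vertex indices (distance 0).
#' @return Numeric vector of distances (mm), `Inf` where unreachable.
#' @export
dijkstra_field <- function(mesh, sources) {
  g <- build_edge_graph(mesh)
  sources <- as.integer(sources)
  if (length(sources) == 0L || any(sources < 1L | sources > g$n_vertices))
    stop("invalid source vertex set", call. = FALSE)
  cpp_dijkstra(g$n_vertices, g$edges$v1, g$edges$v2, g$edges$length,
               sources, 0L)$dist
}

#' Fast-marching geodesic distance field
#'
#' First-order approximation of the geodesic distance from a source vertex
#' set, computed by fast-marching front propagation over the triangles
#' (planar two-point eikonal update per triangle, one-point edge fallback
#' for obtuse configurations). Unlike edge-restricted Dijkstra distances the
#' front crosses triangle interiors, so the field is everywhere less than or
#' equal to the edge-graph distance and converges to the true geodesic
#' distance under mesh refinement.
#'
#' @param mesh a [trimesh()].
#' @param sources vertex indices with distance 0.
#' @return An object of class `"scalar_field"`: list with `values` (one mm
#'   value per vertex, `Inf` where unreachable), `sources`, and `provenance`
#'   (a short tag).
#' @export
fmm_distance <- function(mesh, sources) {
  stopifnot_mesh(mesh)
  sources <- unique(as.integer(sources))
  n <- nrow(mesh$vertices)
  if (length(sources) == 0L || any(sources < 1L | sources > n))
    stop("invalid source vertex set", call. = FALSE)
  vals <- cpp_fmm(mesh$vertices, mesh$faces, sources)
  unreached <- !is.finite(vals)
  structure(list(values = vals, sources = sources,
                 provenance = if (any(unreached))
                   "fmm (unreachable vertices present)" else "fmm"),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("scalar field (%s): %d vertices, range [%.4g, %.4g] mm\n",
              x$provenance, length(x$values),
              min(fin), max(fin)))
  invisible(x)
}

#' Write a per-vertex scalar field
#'
#' `write_scalar_field_csv()` writes `vertex_index,value` rows;
#' `write_mesh_with_quality()` writes an ASCII PLY with the field as the
#' per-vertex `quality` property for visualisation.
#'
#' @param field a `"scalar_field"`.
#' @param path output file.
#' @param mesh the mesh the field lives on (PLY export only).
#' @export
write_scalar_field_csv <- function(field, path) {
  utils::write.csv(
    data.frame(vertex_index = seq_along(field$values), value = field$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scalar_field_csv
#' @export
write_mesh_with_quality <- function(mesh, field, path) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    "property double quality",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(format_num(v[, 1L]), format_num(v[, 2L]),
                   format_num(v[, 3L]), format_num(field$values)), con)
  writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  invisible(path)
}
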