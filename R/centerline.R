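# Centerline leaf-length estimation for twisted leaves.
#
# The botanical "length" of a strap-shaped leaf is measured along its
# midline. On a twisted leaf the shortest surface path between base and tip
# cuts corners across the blade and underestimates that length, so the
# midline is recovered in five steps: (1) collect the outer edge (boundary)
# of the leaf, (2) map each vertex's distance to that edge by fast marching,
# (3) map the distance from the starting point and slice the leaf into k
# bands of equal distance, (4) in every interior band pick the vertex
# farthest from the edge, (5) chain shortest routes start -> waypoints ->
# end in band order and sum their lengths.

#' Outer-edge vertex set of a leaf mesh
#'
#' All vertices on boundary loops, optionally excluding those within a
#' graph-distance radius of the start and end points (so the attachment and
#' tip regions do not count as "edge" when they are artificial cuts).
#'
#' @param mesh an open [trimesh()].
#' @param start,end vertex indices of the measurement endpoints.
#' @param exclusion_radius graph distance (mm) around `start`/`end` to drop
#'   from the edge set; 0 keeps the whole margin.
#' @return Integer vector of boundary vertex indices.
#' @export
leaf_edge_set <- function(mesh, start, end, exclusion_radius = 0) {
  stopifnot_mesh(mesh)
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop("no outer edges: mesh is closed", call. = FALSE)
  edge_v <- unlist(lapply(loops, `[[`, "vertices"))
  if (exclusion_radius > 0) {
    d <- dijkstra_field(mesh, c(start, end))
    edge_v <- edge_v[d[edge_v] > exclusion_radius]
  }
  if (length(edge_v) == 0L)
    stop("exclusion radius removed the whole edge set; use a smaller radius",
         call. = FALSE)
  sort(unique(edge_v))
}

#' Distance-to-edge field
#'
#' Fast-marching distance from the leaf's outer edge; the midline of an
#' elongated leaf shows up as the ridge of this field.
#'
#' @param mesh a [trimesh()].
#' @param edges vertex indices forming the edge set (distance 0).
#' @return A `"scalar_field"` tagged `"edge map"`.
#' @export
edge_distance_field <- function(mesh, edges) {
  f <- fmm_distance(mesh, edges)
  f$provenance <- "edge map"
  f
}

#' Partition vertices into distance bands
#'
#' Slices the mesh into `k` bands of equal geodesic-distance width between
#' the start (distance 0) and the end point: band i (0-based) holds the
#' vertices whose source distance lies in `[i*D/k, (i+1)*D/k)` where `D` is
#' the source-field value at `end`; vertices farther than `D` join the last
#' band.
#'
#' @param source_field a `"scalar_field"` of distances from the start.
#' @param end end vertex index; the field must be finite there.
#' @param k number of bands (>= 3).
#' @return Integer vector of band labels `0..k-1`, one per vertex.
#' @export
band_partition <- function(source_field, end, k) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  vals <- source_field$values
  D <- vals[end]
  if (!is.finite(D) || D <= 0)
    stop("source field not finite and positive at the end vertex",
         call. = FALSE)
  band <- pmin(floor(vals / (D / k)), k - 1)
  band[!is.finite(vals)] <- k - 1
  band <- as.integer(band)
  end_band <- band[end]
  occupied <- tabulate(band + 1L, nbins = k) > 0L
  need <- seq.int(0L, end_band)
  empty <- need[!occupied[need + 1L]]
  if (length(empty) > 0L)
    stop("k too large for mesh resolution: band ", empty[1L], " is empty",
         call. = FALSE)
  band
}

#' Waypoints: farthest-from-edge vertex per interior band
#'
#' For every band except the one containing the start and the one containing
#' the end, selects the vertex maximising the edge-distance field; ties are
#' broken toward the lowest vertex index. These are the points the midline
#' passes through.
#'
#' @param edge_field a `"scalar_field"` of distances to the leaf edge.
#' @param bands band labels from [band_partition()].
#' @param start,end endpoint vertex indices.
#' @return Integer vector of waypoint vertex indices, ordered by band.
#' @export
band_waypoints <- function(edge_field, bands, start, end) {
  skip <- unique(c(bands[start], bands[end]))
  interior <- setdiff(sort(unique(bands)), skip)
  vapply(interior, function(b) {
    idx <- which(bands == b)
    vals <- edge_field$values[idx]
    idx[which.max(vals)]  # which.max returns first (lowest index) on ties
  }, integer(1L))
}

#' Centerline length of a leaf
#'
#' Runs the full five-step midline procedure and assembles the centerline as
#' chained shortest edge paths start -> waypoint 1 -> ... -> end, in band
#' order. The total is the leaf's length measured along its middle; it can
#' never be shorter than the direct shortest path between the endpoints.
#'
#' @param mesh an open [trimesh()] (a leaf surface with a margin).
#' @param start,end endpoint vertex indices (use [snap_to_vertex()] to go
#'   from coordinates to indices).
#' @param k number of distance bands (default 10).
#' @param exclusion_radius mm of margin to ignore around the endpoints when
#'   collecting the edge set (default 0: whole margin).
#' @return An object of class `"centerline"`: list with `length` (mm),
#'   `waypoints`, `path` (ordered vertex indices), `segment_lengths`,
#'   `band_count`, `edge_field`, `source_field`,
#'   `shortest_path_length` (direct Dijkstra distance for comparison).
#' @export
centerline_length <- function(mesh, start, end, k = 10, exclusion_radius = 0) {
  stopifnot_mesh(mesh)
  start <- as.integer(start); end <- as.integer(end)
  edges <- leaf_edge_set(mesh, start, end, exclusion_radius)
  efield <- edge_distance_field(mesh, edges)
  sfield <- fmm_distance(mesh, start)
  sfield$provenance <- "source map"
  bands <- band_partition(sfield, end, k)
  wp <- band_waypoints(efield, bands, start, end)
  chain <- c(start, wp, end)
  segs <- vector("list", length(chain) - 1L)
  for (i in seq_along(segs))
    segs[[i]] <- dijkstra_path(mesh, chain[i], chain[i + 1L])
  seg_len <- vapply(segs, `[[`, numeric(1L), "length")
  path <- chain[1L]
  for (s in segs) path <- c(path, s$vertices[-1L])
  direct <- dijkstra_path(mesh, start, end)$length
  structure(list(
    length = sum(seg_len),
    waypoints = wp,
    path = path,
    segment_lengths = seg_len,
    band_count = as.integer(k),
    edge_field = efield,
    source_field = sfield,
    shortest_path_length = direct
  ), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: length %.4f mm over %d bands (%d waypoints)\n",
              x$length, x$band_count, length(x$waypoints)))
  cat(sprintf("  direct shortest path: %.4f mm\n", x$shortest_path_length))
  invisible(x)
}
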