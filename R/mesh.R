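#' Construct a triangle mesh
#'
#' The basic surface representation used throughout phenomesh: a set of 3D
#' vertex positions (millimetres) and a set of triangular faces indexing into
#' them. This is the form in which structured-light scanning pipelines deliver
#' plant surfaces, and the substrate on which all measurements (lengths,
#' areas, volumes) are defined.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm), one row per
#'   vertex.
#' @param faces integer matrix with 3 columns of 1-based vertex indices, one
#'   row per triangle. No face may repeat a vertex.
#' @return An object of class `"trimesh"`: a list with elements `vertices`
#'   (n x 3 numeric matrix) and `faces` (m x 3 integer matrix).
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' surface_area(m)
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns (x, y, z)", call. = FALSE)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL

  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (ncol(faces) != 3L)
    stop("`faces` must have 3 columns of vertex indices", call. = FALSE)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL

  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > n)
      stop("face indices must lie in 1..", n, call. = FALSE)
    degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    if (any(degen))
      stop("topologically degenerate face (repeated vertex) at row ",
           which(degen)[1L], call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @rdname trimesh
#' @param x object to test or print.
#' @export
is_trimesh <- function(x) inherits(x, "trimesh")

#' @rdname trimesh
#' @param ... ignored.
#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0L) {
    e <- mesh_edges(x)
    cat(sprintf("  mean edge length: %.4g mm\n", mean(e$length)))
    b <- sum(e$face_count == 1L)
    cat(sprintf("  edges: %d (%d boundary)\n", nrow(e), b))
  }
  invisible(x)
}

stopifnot_mesh <- function(mesh) {
  if (!is_trimesh(mesh)) stop("not a trimesh object", call. = FALSE)
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh", call. = FALSE)
  invisible(mesh)
}

# Unique undirected edge table. Edge keys are encoded as min*(n+1)+max in
# doubles; exact for meshes up to ~60M vertices (well inside 2^53).
edge_key <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.numeric(lo) * (n + 1) + as.numeric(hi)
}

#' Edge table of a mesh
#'
#' Enumerates the unique undirected edges of a mesh with their Euclidean
#' lengths and the number of incident faces (1 = boundary edge, 2 = interior
#' manifold edge, >2 = non-manifold).
#'
#' @param mesh a [trimesh()].
#' @return A data.frame with columns `v1`, `v2` (vertex indices, `v1 < v2`),
#'   `length` (mm) and `face_count`.
#' @export
mesh_edges <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  key <- edge_key(a, b, n)
  o <- order(key)
  key <- key[o]; a <- a[o]; b <- b[o]
  first <- !duplicated(key)
  cnt <- as.integer(table(factor(key, levels = key[first])))
  v1 <- pmin(a[first], b[first])
  v2 <- pmax(a[first], b[first])
  len <- sqrt(rowSums((mesh$vertices[v1, , drop = FALSE] -
                         mesh$vertices[v2, , drop = FALSE])^2))
  data.frame(v1 = v1, v2 = v2, length = len, face_count = cnt)
}

#' Mean edge length (mesh resolution)
#'
#' The arithmetic mean of the unique undirected edge lengths, the "mean
#' distance between vertices" used as the mesh-resolution measure in
#' resolution-versus-error studies. Unique edges are used rather than
#' per-face half-edges so interior edges are not counted twice.
#'
#' @param mesh a [trimesh()] with at least one edge.
#' @return Mean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  mean(e$length)
}

#' Surface area of a triangle mesh
#'
#' Sum over faces of half the magnitude of the cross product of two edge
#' vectors. Invariant under rigid motion and face reordering; degenerate
#' (zero-area) faces contribute nothing.
#'
#' @param mesh a [trimesh()].
#' @return Total area in mm^2.
#' @export
surface_area <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

signed_volume <- function(mesh) {
  # tetrahedra are taken about the vertex centroid rather than the origin:
  # mathematically identical on a closed surface, but numerically stable for
  # meshes far from the origin
  v <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  # det(a, b, c)/6 summed over faces; origin-dependent terms cancel on a
  # closed surface.
  sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
        a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
        a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Absolute value of the sum of signed tetrahedron volumes (origin, v1, v2,
#' v3)/6 over all faces. Requires a closed, manifold surface; faces are
#' re-oriented consistently first (breadth-first flood fill across shared
#' edges), so the winding convention of the input does not matter. The result
#' is translation-invariant even though the tetrahedra share an arbitrary
#' origin, because the origin-dependent contributions cancel on a closed
#' surface.
#'
#' @param mesh a closed manifold [trimesh()].
#' @return Enclosed volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  e <- mesh_edges(mesh)
  nb <- sum(e$face_count == 1L)
  if (nb > 0L) {
    nloops <- length(boundary_loops(mesh))
    stop("volume undefined for open surface (", nloops,
         " boundary loop", if (nloops != 1L) "s", ")", call. = FALSE)
  }
  if (any(e$face_count > 2L))
    stop("volume undefined for non-manifold surface", call. = FALSE)
  m <- orient_mesh(mesh)
  abs(signed_volume(m))
}

#' Surface-to-volume ratio
#'
#' S/V in 1/mm, an ecophysiological descriptor of succulence: the lower the
#' ratio the better the water economy of the organ. Defined only for closed
#' meshes (volume must exist).
#'
#' @inheritParams enclosed_volume
#' @return S/V ratio in 1/mm.
#' @export
sv_ratio <- function(mesh) {
  surface_area(mesh) / enclosed_volume(mesh)
}

#' Re-orient faces consistently
#'
#' Breadth-first flood fill across shared edges flips faces so that every
#' interior edge is traversed in opposite directions by its two faces; if the
#' resulting signed volume is negative the whole component is flipped, giving
#' outward orientation for closed surfaces.
#'
#' @param mesh a manifold [trimesh()].
#' @return A [trimesh()] with consistently oriented faces.
#' @export
orient_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  nf <- nrow(f)
  n <- nrow(mesh$vertices)
  flip <- cpp_orient_faces(f, n)
  if (any(flip)) f[flip, ] <- f[flip, c(1L, 3L, 2L), drop = FALSE]
  out <- trimesh(mesh$vertices, f)
  if (signed_volume(out) < 0) out$faces <- out$faces[, c(1L, 3L, 2L), drop = FALSE]
  out
}

#' Boundary loops of an open mesh
#'
#' Finds all closed cycles of boundary edges (edges bordering exactly one
#' face): the outer margin of a leaf surface, or small holes where thorns
#' prevented the scanner from seeing the surface. Loops are oriented
#' following the winding of their adjacent faces.
#'
#' @param mesh a manifold [trimesh()].
#' @return A list of objects of class `"boundary_loop"`, each a list with
#'   `vertices` (ordered vertex indices around the cycle, first not repeated
#'   at the end) and `perimeter` (mm). Empty list for a closed mesh.
#' @export
boundary_loops <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  key <- edge_key(a, b, n)
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L][1L]
    k <- as.numeric(bad)
    stop(sprintf("non-manifold edge (%d, %d) borders more than 2 faces",
                 k %/% (n + 1), k %% (n + 1)), call. = FALSE)
  }
  is_boundary <- cnt[as.character(key)] == 1L
  ba <- a[is_boundary]; bb <- b[is_boundary]
  if (length(ba) == 0L) return(list())
  # directed boundary edges follow face winding; walk successor chains
  nxt <- integer(n); nxt[] <- NA_integer_
  if (anyDuplicated(ba))
    stop("boundary is non-manifold at vertex ", ba[anyDuplicated(ba)],
         call. = FALSE)
  nxt[ba] <- bb
  seen <- logical(n)
  loops <- list()
  for (s in ba) {
    if (seen[s]) next
    cyc <- integer(0)
    v <- s
    repeat {
      cyc <- c(cyc, v)
      seen[v] <- TRUE
      v <- nxt[v]
      if (is.na(v)) stop("open boundary chain: mesh is not manifold",
                         call. = FALSE)
      if (v == s) break
    }
    p <- mesh$vertices[cyc, , drop = FALSE]
    per <- sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2)))
    loops[[length(loops) + 1L]] <-
      structure(list(vertices = cyc, perimeter = per),
                class = "boundary_loop")
  }
  loops
}

#' Structural validation report
#'
#' Checks the structural preconditions that measurements rely on: volume
#' needs a closed, consistently oriented, manifold surface; boundary-based
#' algorithms (centerline, hole filling) need manifold boundaries.
#'
#' @param mesh a [trimesh()].
#' @return A list of class `"mesh_validation"`: `is_manifold`, `is_closed`,
#'   `is_consistently_oriented`, `boundary_edge_count`,
#'   `nonmanifold_edge_count`, `connected_component_count`,
#'   `euler_characteristic`, `degenerate_face_count` (zero-area faces),
#'   `vertex_count`, `face_count`, `edge_count`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  e <- mesh_edges(mesh)
  boundary <- sum(e$face_count == 1L)
  nonman <- sum(e$face_count > 2L)
  manifold <- nonman == 0L

  # orientation: every interior edge must appear once in each direction
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  dir_key <- as.numeric(a) * (n + 1) + as.numeric(b)
  oriented <- manifold && !anyDuplicated(dir_key)

  # connected components over the edge graph (union-find)
  comp <- cpp_components(e$v1, e$v2, n)
  used <- unique(as.vector(f))
  ncomp <- length(unique(comp[used]))

  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  ndeg <- sum(areas == 0)
  if (ndeg > 0L)
    warning(ndeg, " zero-area (degenerate) face(s) retained", call. = FALSE)

  structure(list(
    is_manifold = manifold,
    is_closed = manifold && boundary == 0L,
    is_consistently_oriented = oriented,
    boundary_edge_count = boundary,
    nonmanifold_edge_count = nonman,
    connected_component_count = ncomp,
    euler_characteristic = length(used) - nrow(e) + nrow(f),
    degenerate_face_count = ndeg,
    vertex_count = n,
    face_count = nrow(f),
    edge_count = nrow(e)
  ), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("mesh validation:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Morphometric report for one mesh
#'
#' One row of a resolution-study table: counts, resolution, area and (for
#' closed meshes) volume and S/V ratio. Open meshes get `NA` volume and S/V
#' with a warning, since enclosed volume is only defined for closed surfaces.
#'
#' @param mesh a [trimesh()].
#' @return A one-row data.frame with columns `vertices`, `faces`,
#'   `mean_edge_length` (mm), `area` (mm^2), `volume` (mm^3), `sv_ratio`
#'   (1/mm).
#' @export
morphometric_report <- function(mesh) {
  stopifnot_mesh(mesh)
  val <- validate_mesh(mesh)
  vol <- NA_real_
  if (val$is_closed && val$is_manifold) {
    vol <- enclosed_volume(mesh)
  } else {
    warning("open or non-manifold mesh: volume and S/V not reported",
            call. = FALSE)
  }
  area <- surface_area(mesh)
  data.frame(
    vertices = val$vertex_count,
    faces = val$face_count,
    mean_edge_length = mean_edge_length(mesh),
    area = area,
    volume = vol,
    sv_ratio = if (is.na(vol)) NA_real_ else area / vol
  )
}

#' Snap a 3D point to the nearest mesh vertex
#'
#' Convenience lookup for specifying measurement endpoints as coordinates
#' instead of vertex indices.
#'
#' @param mesh a [trimesh()].
#' @param point numeric length-3 coordinate (mm).
#' @return The index of the Euclidean-nearest vertex.
#' @export
snap_to_vertex <- function(mesh, point) {
  stopifnot_mesh(mesh)
  stopifnot(length(point) == 3L)
  d2 <- (mesh$vertices[, 1L] - point[1L])^2 +
    (mesh$vertices[, 2L] - point[2L])^2 +
    (mesh$vertices[, 3L] - point[3L])^2
  which.min(d2)
}
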