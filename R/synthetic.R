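#' Latitude-longitude (UV) triangulated sphere
#'
#' Deterministic sphere triangulation used to validate area and volume
#' computation against the closed forms 4*pi*r^2 and 4/3*pi*r^3: latitude
#' rings at multiples of the angular resolution (poles excluded), full
#' longitude circles at the same step, each quad split along the
#' (ring i, lon j)--(ring i+1, lon j+1) diagonal, and triangle fans at the
#' poles. All vertices lie exactly on the sphere, so the mesh is an
#' inscribed polyhedron: its area and volume are strictly below the analytic
#' values and converge to them as the resolution step shrinks.
#'
#' At 2 degrees and radius 50 mm the construction gives 16,022 vertices,
#' 32,040 faces and an equatorial vertex spacing of 2*r*sin(1 degree), about
#' 1.7 mm.
#'
#' @param radius sphere radius in mm.
#' @param resolution_deg angular step in degrees; must divide 180.
#' @return A closed, outward-oriented [trimesh()].
#' @export
uv_sphere <- function(radius = 50, resolution_deg = 2) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (resolution_deg <= 0 || 180 %% resolution_deg != 0)
    stop("resolution must be a positive divisor of 180 degrees",
         call. = FALSE)
  nring <- 180L %/% as.integer(resolution_deg) - 1L  # latitude rings
  nlon <- 360L %/% as.integer(resolution_deg)        # longitudes per ring
  theta <- (seq_len(nring)) * resolution_deg * pi / 180  # colatitude
  phi <- (seq_len(nlon) - 1L) * resolution_deg * pi / 180

  st <- rep(sin(theta), each = nlon)
  ct <- rep(cos(theta), each = nlon)
  cp <- rep(cos(phi), times = nring)
  sp <- rep(sin(phi), times = nring)
  ringv <- cbind(radius * st * cp, radius * st * sp, radius * ct)
  v <- rbind(c(0, 0, radius), ringv, c(0, 0, -radius))
  np <- 1L                      # north pole index
  sp_i <- nrow(v)               # south pole index
  ridx <- function(i, j) 1L + (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L

  faces <- vector("list", nring + 1L)
  j <- seq_len(nlon)
  # north cap: pole -> ring 1, outward (counter-clockwise from outside)
  faces[[1L]] <- cbind(np, ridx(1L, j), ridx(1L, j + 1L))
  if (nring > 1L) for (i in seq_len(nring - 1L)) {
    a <- ridx(i, j); b <- ridx(i, j + 1L)
    cc <- ridx(i + 1L, j); d <- ridx(i + 1L, j + 1L)
    # quad (a,b,d,cc) split along a--d
    faces[[i + 1L]] <- rbind(cbind(a, cc, d), cbind(a, d, b))
  }
  faces[[nring + 1L]] <- cbind(sp_i, ridx(nring, j + 1L), ridx(nring, j))
  m <- trimesh(v, do.call(rbind, faces))
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Twisted-ribbon leaf model
#'
#' Sweeps a straight segment of the given width along a straight axis while
#' rotating it about that axis, emulating the long twisted strap leaf of
#' *Welwitschia mirabilis*. Because the twist is about the midline axis, the
#' true centerline of the surface is the axis itself and has exactly
#' `length` mm of arc length, giving the centerline algorithm an analytic
#' ground truth; the ribbon margins trace helices that are strictly longer.
#'
#' Per-vertex surface parameters (fraction along the length and across the
#' width) are attached as attribute `"parameters"` (a data.frame with columns
#' `length_fraction`, `width_fraction`) for ground-truth testing.
#'
#' @param length axis length in mm.
#' @param width ribbon width in mm.
#' @param twist total twist in full turns (may be fractional or 0).
#' @param n_length,n_width number of sample points along/across
#'   (vertices per row/column, both >= 2).
#' @return An open [trimesh()] with a single boundary loop.
#' @export
twisted_ribbon <- function(length = 180, width = 30, twist = 0,
                           n_length = 181L, n_width = 31L) {
  n_length <- as.integer(n_length); n_width <- as.integer(n_width)
  if (n_length < 2L || n_width < 2L)
    stop("need at least 2 samples in each direction", call. = FALSE)
  s <- seq(0, 1, length.out = n_length)   # along axis
  t <- seq(0, 1, length.out = n_width)    # across width
  sg <- rep(s, each = n_width)
  tg <- rep(t, times = n_length)
  ang <- 2 * pi * twist * sg
  off <- (tg - 0.5) * width
  v <- cbind(sg * length, off * cos(ang), off * sin(ang))

  idx <- function(i, j) (i - 1L) * n_width + j
  i <- rep(seq_len(n_length - 1L), each = n_width - 1L)
  j <- rep(seq_len(n_width - 1L), times = n_length - 1L)
  a <- idx(i, j); b <- idx(i, j + 1L)
  cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
  f <- rbind(cbind(a, cc, d), cbind(a, d, b))
  m <- trimesh(v, f)
  attr(m, "parameters") <- data.frame(length_fraction = sg,
                                      width_fraction = tg)
  attr(m, "midline_length") <- length
  m
}

#' Ribbon perforated by small holes
#'
#' A [twisted_ribbon()] with faces removed where small discs (thorn "holes")
#' are punched out of the surface: every face whose three vertices all fall
#' inside a hole disc, measured in the flattened (length, width) parameter
#' plane in mm, is deleted. Each realised hole adds one boundary loop to the
#' ribbon's outer margin. The construction is deterministic; `seed` controls
#' optional jitter of the hole centres.
#'
#' @inheritParams twisted_ribbon
#' @param holes data.frame or matrix with columns `length_fraction`,
#'   `width_fraction`, `radius` (mm), one row per hole. Holes must lie inside
#'   the surface and must not overlap.
#' @param jitter_mm standard deviation of optional centre jitter (default 0:
#'   none).
#' @param seed integer seed for the jitter; ignored when `jitter_mm = 0`.
#' @return An open [trimesh()] with `1 + nrow(holes)` boundary loops.
#' @export
perforated_ribbon <- function(length = 180, width = 30, twist = 0,
                              n_length = 181L, n_width = 31L,
                              holes = NULL, jitter_mm = 0, seed = 1L) {
  m <- twisted_ribbon(length, width, twist, n_length, n_width)
  if (is.null(holes) || nrow(holes) == 0L) return(m)
  holes <- as.data.frame(holes)
  stopifnot(all(c("length_fraction", "width_fraction", "radius") %in%
                  names(holes)))
  cx <- holes$length_fraction * length
  cy <- holes$width_fraction * width
  r <- holes$radius
  if (jitter_mm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    cx <- cx + stats::rnorm(length(cx), 0, jitter_mm)
    cy <- cy + stats::rnorm(length(cy), 0, jitter_mm)
  }
  if (any(cx - r < 0 | cx + r > length | cy - r < 0 | cy + r > width))
    stop("hole disc extends beyond the ribbon surface", call. = FALSE)
  if (nrow(holes) > 1L) {
    dd <- as.matrix(stats::dist(cbind(cx, cy)))
    rs <- outer(r, r, `+`)
    diag(dd) <- Inf
    if (any(dd <= rs)) stop("overlapping holes", call. = FALSE)
  }
  par <- attr(m, "parameters")
  px <- par$length_fraction * length
  py <- par$width_fraction * width
  inside <- rep(FALSE, nrow(m$vertices))
  for (h in seq_along(cx))
    inside <- inside |
      ((px - cx[h])^2 + (py - cy[h])^2 <= r[h]^2 + 1e-9)
  f <- m$faces
  drop <- inside[f[, 1L]] & inside[f[, 2L]] & inside[f[, 3L]]
  if (!any(drop)) return(m)
  f <- f[!drop, , drop = FALSE]
  # drop unreferenced vertices, remap
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  out <- trimesh(m$vertices[used, , drop = FALSE],
                 matrix(remap[f], ncol = 3L))
  attr(out, "parameters") <- par[used, , drop = FALSE]
  attr(out, "midline_length") <- attr(m, "midline_length")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Exact primitive solids
#'
#' Canonical closed triangle meshes with closed-form area and volume, used
#' as oracles: the axis-aligned cube (12 triangles) and the regular
#' tetrahedron (4 triangles).
#'
#' @param name `"cube"` or `"tetrahedron"`.
#' @param size edge length in mm.
#' @return A closed, outward-oriented [trimesh()].
#' @export
primitive_mesh <- function(name = c("cube", "tetrahedron"), size = 1) {
  name <- match.arg(name)
  if (size <= 0) stop("size must be positive", call. = FALSE)
  if (name == "cube") {
    v <- size * as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
    dimnames(v) <- NULL
    # vertices: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
    #           5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
    f <- rbind(
      c(1, 3, 2), c(2, 3, 4),   # bottom (z = 0), outward = -z
      c(5, 6, 7), c(6, 8, 7),   # top
      c(1, 2, 5), c(2, 6, 5),   # front (y = 0)
      c(3, 7, 4), c(4, 7, 8),   # back
      c(1, 5, 3), c(3, 5, 7),   # left (x = 0)
      c(2, 4, 6), c(4, 8, 6))   # right
  } else {
    # regular tetrahedron with edge `size`
    v <- size / (2 * sqrt(2)) * rbind(c(1, 1, 1), c(1, -1, -1),
                                      c(-1, 1, -1), c(-1, -1, 1))
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  }
  m <- trimesh(v, f)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Wrinkled sphere ("scan-like blob")
#'
#' A closed genus-0 blob: a UV sphere whose radius is modulated by a smooth
#' low-amplitude angular ripple, emulating the fine surface relief that
#' structured-light scans of plant organs carry. Unlike the ideal sphere its
#' area at coarse resolution is lost both to chord shortening and to
#' smoothing-out of the ripple, the regime in which scanned-leaf resolution
#' ladders operate.
#'
#' @param radius base radius mm.
#' @param amplitude ripple amplitude mm.
#' @param lobes angular frequency of the ripple (integer).
#' @param resolution_deg angular step, divisor of 180.
#' @return A closed [trimesh()].
#' @export
wrinkled_blob <- function(radius = 50, amplitude = 1, lobes = 12,
                          resolution_deg = 2) {
  m <- uv_sphere(radius = 1, resolution_deg = resolution_deg)
  v <- m$vertices
  r1 <- sqrt(rowSums(v^2))
  theta <- acos(pmin(1, pmax(-1, v[, 3L] / r1)))
  phi <- atan2(v[, 2L], v[, 1L])
  rr <- radius + amplitude * sin(lobes * theta) * cos(lobes * phi)
  m$vertices <- v * rr
  m
}
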