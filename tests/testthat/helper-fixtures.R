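# Shared fixtures and small analytic oracles, built in code.

unit_cube <- function() primitive_mesh("cube", 1)

single_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# strip in the xy-plane: length L along x, width W along y
flat_strip <- function(L = 180, W = 30, h = 1) {
  twisted_ribbon(L, W, 0, as.integer(round(L / h)) + 1L,
                 as.integer(round(W / h)) + 1L)
}

# random rigid motion (rotation + translation), deterministic under seed
rigid_motion <- function(mesh, seed) {
  set.seed(seed)
  a <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  tr <- stats::runif(3, -500, 500)
  out <- mesh
  out$vertices <- sweep(mesh$vertices %*% t(Rz %*% Ry %*% Rx), 2, -tr)
  out
}

# great-circle distance from the north pole for every vertex of a sphere mesh
sphere_arc_from_pole <- function(mesh, radius) {
  r1 <- sqrt(rowSums(mesh$vertices^2))
  radius * acos(pmin(1, pmax(-1, mesh$vertices[, 3] / r1)))
}

five_holes <- function() {
  data.frame(length_fraction = c(0.2, 0.35, 0.5, 0.65, 0.8),
             width_fraction = c(0.5, 0.3, 0.7, 0.4, 0.6),
             radius = 1)
}
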