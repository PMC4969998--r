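test_that("trimesh rejects invalid construction", {
  expect_error(trimesh(matrix(0, 2, 2), NULL), "3 columns")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 3))),
               "face indices")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 2))),
               "degenerate")
})

test_that("surface area matches closed forms", {
  expect_equal(surface_area(single_triangle()), 0.5)
  expect_equal(surface_area(unit_cube()), 6)
  tet <- primitive_mesh("tetrahedron", 2)
  expect_equal(surface_area(tet), sqrt(3) * 2^2)
})

test_that("enclosed volume matches closed forms and is translation invariant", {
  cu <- unit_cube()
  expect_equal(enclosed_volume(cu), 1)
  expect_equal(sv_ratio(cu), 6)
  moved <- cu
  moved$vertices <- sweep(cu$vertices, 2, c(-1000, 500, -3))
  expect_equal(enclosed_volume(moved), 1, tolerance = 1e-12)
  tet <- primitive_mesh("tetrahedron", 2)
  expect_equal(enclosed_volume(tet), 2^3 / (6 * sqrt(2)), tolerance = 1e-12)
})

test_that("volume errors on open surfaces name the boundary loops", {
  open_cube <- trimesh(unit_cube()$vertices, unit_cube()$faces[-1, ])
  expect_error(enclosed_volume(open_cube), "open surface.*1 boundary loop")
  expect_error(sv_ratio(open_cube), "open surface")
})

test_that("flipping all windings leaves |volume| unchanged, negates signed sum", {
  cu <- unit_cube()
  flipped <- trimesh(cu$vertices, cu$faces[, c(1, 3, 2)])
  expect_equal(phenomesh:::signed_volume(flipped),
               -phenomesh:::signed_volume(cu))
  expect_equal(enclosed_volume(flipped), enclosed_volume(cu))
})

test_that("orientation repair recovers volume from scrambled windings", {
  cu <- unit_cube()
  set.seed(7)
  scr <- cu
  flip <- sample(c(TRUE, FALSE), nrow(cu$faces), replace = TRUE)
  scr$faces[flip, ] <- scr$faces[flip, c(1, 3, 2)]
  expect_equal(enclosed_volume(scr), 1, tolerance = 1e-12)
})

test_that("mean edge length enumerates unique undirected edges", {
  eq <- trimesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                rbind(c(1, 2, 3)))
  expect_equal(mean_edge_length(eq), 2)
  # cube: 18 unique edges, 12 of length 1 and 6 face diagonals of sqrt(2)
  e <- mesh_edges(unit_cube())
  expect_equal(nrow(e), 18)
  expect_equal(sort(table(round(e$length, 6))), sort(c(`1` = 12L, `1.414214` = 6L)),
               ignore_attr = TRUE)
  expect_equal(mean_edge_length(unit_cube()), (12 + 6 * sqrt(2)) / 18)
})

test_that("validation report is self-consistent on closed and cut meshes", {
  v <- validate_mesh(unit_cube())
  expect_true(v$is_closed && v$is_manifold && v$is_consistently_oriented)
  expect_equal(v$euler_characteristic, 2)
  expect_equal(v$face_count, 2 * v$vertex_count - 4)
  expect_equal(v$connected_component_count, 1)

  cut <- trimesh(unit_cube()$vertices, unit_cube()$faces[-1, ])
  vc <- validate_mesh(cut)
  expect_false(vc$is_closed)
  expect_equal(vc$boundary_edge_count, 3)
})

test_that("boundary loops: closed mesh none, strip one, perforations add loops", {
  expect_length(boundary_loops(uv_sphere(50, 30)), 0)
  strip <- flat_strip(40, 10, 1)
  bl <- boundary_loops(strip)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$perimeter, 2 * (40 + 10), tolerance = 1e-9)
  holes <- five_holes()[1:3, ]
  p <- perforated_ribbon(180, 30, 0, 361L, 61L, holes = holes)
  expect_length(boundary_loops(p), 4)
})

test_that("morphometric report rows carry counts, area, volume, S/V", {
  r <- morphometric_report(unit_cube())
  expect_equal(r$vertices, 8)
  expect_equal(r$faces, 12)
  expect_equal(r$area, 6)
  expect_equal(r$volume, 1)
  expect_equal(r$sv_ratio, 6)
  strip <- flat_strip(10, 5, 1)
  expect_warning(ro <- morphometric_report(strip), "volume")
  expect_true(is.na(ro$volume) && is.na(ro$sv_ratio))
  expect_equal(ro$area, 50)
})

test_that("morphometrics are rigid-motion invariant", {
  meshes <- list(unit_cube(), uv_sphere(50, 30), primitive_mesh("tetrahedron", 3))
  for (seed in 1:3) {
    for (m in meshes) {
      mm <- rigid_motion(m, seed)
      expect_equal(surface_area(mm), surface_area(m), tolerance = 1e-9)
      expect_equal(enclosed_volume(mm), enclosed_volume(m), tolerance = 1e-9)
      expect_equal(mean_edge_length(mm), mean_edge_length(m), tolerance = 1e-9)
    }
  }
})

test_that("closed genus-0 synthetic meshes satisfy F = 2V - 4", {
  for (res in c(90, 30, 6, 4, 2)) {
    s <- uv_sphere(50, res)
    expect_equal(nrow(s$faces), 2 * nrow(s$vertices) - 4)
    v <- validate_mesh(s)
    expect_true(v$is_closed && v$is_manifold && v$is_consistently_oriented)
  }
})

test_that("inscribed sphere meshes under-measure and converge monotonically", {
  a_true <- 4 * pi * 50^2
  v_true <- 4 / 3 * pi * 50^3
  areas <- vols <- numeric(0)
  for (res in c(6, 4, 2)) {
    s <- uv_sphere(50, res)
    areas <- c(areas, surface_area(s))
    vols <- c(vols, enclosed_volume(s))
  }
  expect_true(all(areas < a_true) && all(vols < v_true))
  expect_true(all(diff(areas) > 0) && all(diff(vols) > 0))
})

test_that("snap_to_vertex returns the nearest vertex", {
  cu <- unit_cube()
  expect_equal(snap_to_vertex(cu, c(0.1, -0.2, 0.05)), 1L)
  expect_equal(snap_to_vertex(cu, c(1.4, 1.1, 0.9)), 8L)
})
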