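test_that("uv sphere counts follow the lat-long construction", {
  # (180/res - 1) rings of 360/res vertices plus two poles; F = 2V - 4
  for (res in c(90, 30, 6, 2)) {
    s <- uv_sphere(50, res)
    nring <- 180 / res - 1
    expect_equal(nrow(s$vertices), nring * 360 / res + 2)
    expect_equal(nrow(s$faces), 2 * nrow(s$vertices) - 4)
  }
  expect_error(uv_sphere(50, 7), "divisor of 180")
  expect_error(uv_sphere(-1, 2), "positive")
})

test_that("the 90-degree sphere is the octahedron", {
  o <- uv_sphere(1, 90)
  expect_equal(nrow(o$vertices), 6)
  expect_equal(nrow(o$faces), 8)
  expect_equal(enclosed_volume(o), 4 / 3, tolerance = 1e-12)
  expect_equal(surface_area(o), 2 * sqrt(3) * sqrt(2)^2, tolerance = 1e-12)
})

test_that("equatorial neighbour spacing at 2 degrees is 1.7 mm to 1 d.p.", {
  s <- uv_sphere(50, 2)
  eq <- which(abs(s$vertices[, 3]) < 1e-9)
  p1 <- s$vertices[eq[1], ]
  d <- sqrt(rowSums(sweep(s$vertices[eq[-1], , drop = FALSE], 2, p1)^2))
  spacing <- min(d)
  expect_equal(spacing, 2 * 50 * sin(pi / 180), tolerance = 1e-12)
  expect_equal(round(spacing, 1), 1.7)
})

test_that("sphere vertices lie exactly on the sphere", {
  s <- uv_sphere(50, 6)
  expect_equal(sqrt(rowSums(s$vertices^2)), rep(50, nrow(s$vertices)),
               tolerance = 1e-12)
})

test_that("ribbon construction: flat when untwisted, midline on the axis", {
  flat <- twisted_ribbon(100, 20, 0, 51L, 11L)
  expect_true(all(flat$vertices[, 3] == 0))
  tw <- twisted_ribbon(100, 20, 1.5, 101L, 21L)
  par <- attr(tw, "parameters")
  mid <- which(par$width_fraction == 0.5)
  expect_true(all(abs(tw$vertices[mid, 2]) < 1e-9))
  expect_true(all(abs(tw$vertices[mid, 3]) < 1e-9))
  # midline polyline length is exactly the axis length
  mid <- mid[order(tw$vertices[mid, 1])]
  seg <- diff(tw$vertices[mid, 1])
  expect_equal(sum(seg), 100)
  expect_length(boundary_loops(tw), 1)
})

test_that("ribbon margins elongate with twist as helices", {
  L <- 180; W <- 30; turns <- 2
  tw <- twisted_ribbon(L, W, turns, 361L, 31L)
  helix <- L * sqrt(1 + (2 * pi * turns * (W / 2) / L)^2)  # closed form
  par <- attr(tw, "parameters")
  edge_row <- which(par$width_fraction == 1)
  edge_row <- edge_row[order(tw$vertices[edge_row, 1])]
  chord_len <- sum(sqrt(rowSums(diff(tw$vertices[edge_row, ])^2)))
  expect_equal(chord_len, helix, tolerance = 0.001)  # chords from below
  expect_lte(chord_len, helix)
  expect_gt(boundary_loops(tw)[[1]]$perimeter, 2 * (L + W))
})

test_that("perforation is deterministic and validated", {
  plain <- perforated_ribbon(90, 30, 0, 91L, 31L, holes = NULL)
  expect_identical(plain$faces, twisted_ribbon(90, 30, 0, 91L, 31L)$faces)
  p1 <- perforated_ribbon(180, 30, 0, 361L, 61L, holes = five_holes(),
                          jitter_mm = 0.2, seed = 11L)
  p2 <- perforated_ribbon(180, 30, 0, 361L, 61L, holes = five_holes(),
                          jitter_mm = 0.2, seed = 11L)
  f1 <- withr::local_tempfile(fileext = ".ply")
  f2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(p1, f1); write_mesh(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  bad <- data.frame(length_fraction = c(0.5, 0.505), width_fraction = 0.5,
                    radius = 1)
  expect_error(perforated_ribbon(180, 30, 0, 181L, 31L, holes = bad),
               "overlapping")
  outside <- data.frame(length_fraction = 0.001, width_fraction = 0.5,
                        radius = 2)
  expect_error(perforated_ribbon(180, 30, 0, 181L, 31L, holes = outside),
               "beyond the ribbon")
})

test_that("primitives are exact", {
  cu <- primitive_mesh("cube", 2)
  expect_equal(surface_area(cu), 24)
  expect_equal(enclosed_volume(cu), 8)
  expect_equal(validate_mesh(cu)$euler_characteristic, 2)
  te <- primitive_mesh("tetrahedron", 1)
  expect_equal(mesh_edges(te)$length, rep(1, 6), tolerance = 1e-12)
})

test_that("the wrinkled blob is closed with more area than its base sphere", {
  b <- wrinkled_blob(50, 1, 12, 6)
  v <- validate_mesh(b)
  expect_true(v$is_closed && v$is_manifold)
  expect_equal(v$euler_characteristic, 2)
  expect_gt(surface_area(b), surface_area(uv_sphere(50, 6)))
})
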