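test_that("leaf edge set collects the margin and honours the exclusion radius", {
  strip <- flat_strip(180, 30, 2)
  start <- snap_to_vertex(strip, c(0, 0, 0))
  end <- snap_to_vertex(strip, c(180, 0, 0))
  edges0 <- leaf_edge_set(strip, start, end, 0)
  bl <- boundary_loops(strip)[[1]]$vertices
  expect_setequal(edges0, bl)
  # excluding 20 mm around the short-edge midpoints keeps only far margin
  edges20 <- leaf_edge_set(strip, start, end, 20)
  d <- dijkstra_field(strip, c(start, end))
  expect_true(all(d[edges20] > 20))
  expect_true(length(edges20) < length(edges0))
  expect_error(leaf_edge_set(uv_sphere(10, 30), 1, 2), "no outer edges")
  expect_error(leaf_edge_set(strip, start, end, 1e6), "smaller radius")
})

test_that("edge distance field peaks near the midline at about half width", {
  strip <- flat_strip(60, 20, 1)
  edges <- leaf_edge_set(strip, 1, nrow(strip$vertices), 0)
  f <- edge_distance_field(strip, edges)
  expect_equal(f$provenance, "edge map")
  expect_true(all(f$values[edges] == 0))
  interior <- max(f$values)
  expect_equal(interior, 10, tolerance = 0.05)
  # on a twisted ribbon the ridge still follows the midline
  tw <- twisted_ribbon(90, 30, 1.5, 91L, 31L)
  par <- attr(tw, "parameters")
  bdry <- unlist(lapply(boundary_loops(tw), `[[`, "vertices"))
  ftw <- edge_distance_field(tw, sort(unique(bdry)))
  core <- which(par$length_fraction > 0.2 & par$length_fraction < 0.8)
  top <- core[order(ftw$values[core], decreasing = TRUE)][1:20]
  expect_true(all(abs(par$width_fraction[top] - 0.5) <= 0.1))
})

test_that("band partition slices geodesic distance into k equal bands", {
  strip <- flat_strip(180, 30, 1)
  start <- snap_to_vertex(strip, c(0, 0, 0))
  end <- snap_to_vertex(strip, c(180, 0, 0))
  sf <- fmm_distance(strip, start)
  bands <- band_partition(sf, end, 3)
  # on the flat strip the source distance is essentially the planar distance
  # from the start corner; band boundaries sit at 60 and 120 mm
  d <- sqrt((strip$vertices[, 1])^2 + (strip$vertices[, 2])^2)
  expect_true(all(bands[sf$values < 59] == 0))
  expect_true(all(bands[sf$values > 61 & sf$values < 119] == 1))
  expect_true(all(bands[sf$values > 121] == 2))
  expect_error(band_partition(sf, end, 2), "at least 3")
  expect_error(band_partition(sf, end, 500), "k too large")
})

test_that("waypoints sit on the midline and ties go to the lowest index", {
  strip <- flat_strip(180, 30, 1)
  start <- snap_to_vertex(strip, c(0, 0, 0))
  end <- snap_to_vertex(strip, c(180, 0, 0))
  edges <- leaf_edge_set(strip, start, end, 0)
  ef <- edge_distance_field(strip, edges)
  sf <- fmm_distance(strip, start)
  bands <- band_partition(sf, end, 3)
  wp <- band_waypoints(ef, bands, start, end)
  expect_length(wp, 1)  # k = 3: bands 0 and 2 are excluded
  par <- attr(strip, "parameters")
  expect_true(abs(par$width_fraction[wp] - 0.5) <= 0.1)
  bands10 <- band_partition(sf, end, 10)
  wp10 <- band_waypoints(ef, bands10, start, end)
  expect_length(wp10, 8)
  expect_true(all(abs(par$width_fraction[wp10] - 0.5) <= 0.1))
  # explicit tie on a symmetric two-triangle sheet: lowest index wins
  sheet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                   rbind(c(1, 2, 3), c(2, 4, 3)))
  fake_field <- structure(list(values = c(0, 5, 5, 0), sources = integer(0),
                               provenance = "edge map"),
                          class = "scalar_field")
  expect_equal(band_waypoints(fake_field, c(0L, 1L, 1L, 2L), 1, 4), 2L)
})

test_that("centerline length recovers the strip midline within 2%", {
  strip <- flat_strip(180, 30, 1)
  start <- snap_to_vertex(strip, c(0, 0, 0))
  end <- snap_to_vertex(strip, c(180, 0, 0))
  cl <- centerline_length(strip, start, end, k = 10)
  expect_gte(cl$length, 180 - 1e-9)
  expect_lte(cl$length, 183.6)
  expect_gte(cl$length, cl$shortest_path_length - 1e-9)
  cl3 <- centerline_length(strip, start, end, k = 3)
  expect_equal(cl3$length, cl$length, tolerance = 0.01)
})

test_that("twisted-ribbon centerline tracks the axis, not the shortest path", {
  # even transverse count: the axis is not a lattice line, as on real leaves
  tw <- twisted_ribbon(180, 30, 2, 181L, 30L)
  start <- snap_to_vertex(tw, c(0, 0, 0))
  end <- snap_to_vertex(tw, c(180, 0, 0))
  cl <- centerline_length(tw, start, end, k = 10)
  expect_equal(cl$length, 180, tolerance = 0.03)
  expect_gt(cl$length, cl$shortest_path_length)
  # waypoint centrality against generator ground truth
  par <- attr(tw, "parameters")
  expect_true(all(par$width_fraction[cl$waypoints] >= 0.4 &
                    par$width_fraction[cl$waypoints] <= 0.6))
  # direction symmetry within 1%
  clr <- centerline_length(tw, end, start, k = 10)
  expect_equal(clr$length, cl$length, tolerance = 0.01)
})

test_that("centerline overestimate shrinks as the strip mesh is refined", {
  lens <- vapply(c(2, 1, 0.5), function(h) {
    strip <- flat_strip(120, 24, h)
    start <- snap_to_vertex(strip, c(0, 0, 0))
    end <- snap_to_vertex(strip, c(120, 0, 0))
    centerline_length(strip, start, end, k = 10)$length
  }, numeric(1))
  expect_true(all(lens >= 120 - 1e-9))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("centerline result is internally consistent", {
  tw <- twisted_ribbon(90, 20, 1, 91L, 16L)
  start <- snap_to_vertex(tw, c(0, 0, 0))
  end <- snap_to_vertex(tw, c(90, 0, 0))
  cl <- centerline_length(tw, start, end, k = 5)
  expect_equal(cl$length, sum(cl$segment_lengths), tolerance = 1e-12)
  expect_equal(cl$path[1], start)
  expect_equal(cl$path[length(cl$path)], end)
  expect_true(all(cl$waypoints %in% cl$path))
})
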