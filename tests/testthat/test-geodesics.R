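test_that("edge graph enumerates unique weighted edges", {
  g <- build_edge_graph(single_triangle())
  expect_equal(nrow(g$edges), 3)
  g2 <- build_edge_graph(unit_cube())
  expect_equal(nrow(g2$edges), 18)
  expect_true(all(abs(g2$edges$length - 1) < 1e-12 |
                    abs(g2$edges$length - sqrt(2)) < 1e-12))
  # two disconnected triangles
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(5, 0, 0), c(6, 0, 0), c(5, 1, 0)),
                 rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(dijkstra_path(two, 1, 4), "no path")
})

test_that("zero-length edges are rejected as unwelded duplicates", {
  dup <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 rbind(c(1, 2, 4), c(2, 3, 4)))
  expect_error(build_edge_graph(dup), "zero-length edge.*2 and 3")
})

test_that("dijkstra finds minimal edge paths deterministically", {
  p0 <- dijkstra_path(unit_cube(), 3, 3)
  expect_equal(p0$length, 0)
  expect_equal(p0$vertices, 3L)
  # unit square split along the diagonal: corner-to-corner uses the diagonal
  sq <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(dijkstra_path(sq, 1, 3)$length, sqrt(2))
  expect_equal(dijkstra_path(sq, 1, 3)$vertices, c(1L, 3L))
})

test_that("dijkstra distances are symmetric and respect the triangle inequality", {
  s <- uv_sphere(50, 30)
  set.seed(42)
  n <- nrow(s$vertices)
  for (i in 1:5) {
    trio <- sample(n, 3)
    dab <- dijkstra_path(s, trio[1], trio[2])$length
    dba <- dijkstra_path(s, trio[2], trio[1])$length
    dbc <- dijkstra_path(s, trio[2], trio[3])$length
    dac <- dijkstra_path(s, trio[1], trio[3])$length
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-9)
    # never shorter than the straight chord
    chord <- sqrt(sum((s$vertices[trio[1], ] - s$vertices[trio[2], ])^2))
    expect_gte(dab, chord - 1e-9)
  }
})

test_that("dijkstra agrees with an independent graph library", {
  m <- twisted_ribbon(60, 20, 1, 31L, 11L)
  g <- build_edge_graph(m)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$v1, to = g$edges$v2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_vertices)))
  set.seed(3)
  pairs <- matrix(sample(g$n_vertices, 12), ncol = 2)
  for (i in seq_len(nrow(pairs))) {
    ours <- dijkstra_path(m, pairs[i, 1], pairs[i, 2])$length
    ref <- igraph::distances(ig, v = pairs[i, 1], to = pairs[i, 2],
                             weights = g$edges$length)[1, 1]
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("geodesic path structure is consistent", {
  s <- uv_sphere(50, 15)
  p <- dijkstra_path(s, 1, 200)
  e <- mesh_edges(s)
  key <- phenomesh:::edge_key(p$vertices[-length(p$vertices)],
                              p$vertices[-1], nrow(s$vertices))
  allkeys <- phenomesh:::edge_key(e$v1, e$v2, nrow(s$vertices))
  expect_true(all(key %in% allkeys))  # consecutive vertices are adjacent
  seg <- sqrt(rowSums((s$vertices[p$vertices[-1], , drop = FALSE] -
                         s$vertices[p$vertices[-length(p$vertices)], ,
                                    drop = FALSE])^2))
  expect_equal(sum(seg), p$length, tolerance = 1e-12)
})

test_that("fmm with all vertices as sources is identically zero", {
  m <- uv_sphere(20, 30)
  f <- fmm_distance(m, seq_len(nrow(m$vertices)))
  expect_true(all(f$values == 0))
})

test_that("fmm on a flat strip reproduces planar distance to the source edge", {
  strip <- flat_strip(60, 20, 1)
  src <- which(abs(strip$vertices[, 1]) < 1e-9)  # short edge at x = 0
  f <- fmm_distance(strip, src)
  expect_true(all(f$values[src] == 0))
  err <- abs(f$values - strip$vertices[, 1])
  expect_lt(max(err), 0.01 * 60)
  # 1-Lipschitz along edges (small slack for the obtuse fallback)
  e <- mesh_edges(strip)
  expect_true(all(abs(f$values[e$v1] - f$values[e$v2]) <=
                    e$length * (1 + 1e-9)))
})

test_that("fmm distance from the pole matches great-circle arcs within 1%", {
  s <- uv_sphere(50, 2)
  f <- fmm_distance(s, 1L)
  arc <- sphere_arc_from_pole(s, 50)
  equator <- which(abs(s$vertices[, 3]) < 1e-9)
  expect_equal(f$values[equator[1]], pi / 2 * 50, tolerance = 0.01)
  antipode <- which.min(s$vertices[, 3])
  expect_equal(f$values[antipode], pi * 50, tolerance = 0.01)
  d <- dijkstra_field(s, 1L)
  expect_true(all(d - f$values >= -1e-9 * pmax(1, d)))
})

test_that("fmm error shrinks under refinement and dijkstra bounds hold", {
  maxerr <- numeric(0)
  for (res in c(6, 4, 2)) {
    s <- uv_sphere(50, res)
    f <- fmm_distance(s, 1L)
    arc <- sphere_arc_from_pole(s, 50)
    rel <- abs(f$values[-1] - arc[-1]) / arc[-1]
    maxerr <- c(maxerr, max(rel))
    # ordering chain: analytic <= fmm * (1 + eps), fmm <= dijkstra
    expect_true(all(f$values[-1] * 1.02 >= arc[-1]))
    d <- dijkstra_field(s, 1L)
    expect_true(all(d - f$values >= -1e-9 * pmax(1, d)))
  }
  expect_true(all(diff(maxerr) < 0))
})

test_that("fmm flags unreachable vertices", {
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(5, 0, 0), c(6, 0, 0), c(5, 1, 0)),
                 rbind(c(1, 2, 3), c(4, 5, 6)))
  f <- fmm_distance(two, 1L)
  expect_true(all(is.infinite(f$values[4:6])))
  expect_match(f$provenance, "unreachable")
})
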