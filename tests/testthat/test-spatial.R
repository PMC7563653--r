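# spatial-architecture features: analytic lattices, brute-force oracles,
# duality, rigid-motion invariance, unit handling

test_that("square lattice gives exact interior cells and unit-length MST", {
  pts <- as.matrix(expand.grid(x = seq(0, 50, 10), y = seq(0, 50, 10)))
  g <- build_graphs(pts, mpp = 1)
  # interior cells of a square lattice are exact squares of area s^2
  areas <- unname(g$voronoi$area[g$voronoi$interior])
  expect_gte(length(areas), 2)
  expect_equal(areas, rep(100, length(areas)), tolerance = 1e-9)
  # MST of an n-point connected set has n-1 edges, all of length s here
  expect_equal(nrow(g$mst$edges), 35)
  expect_equal(g$mst$edge_len, rep(10, 35), tolerance = 1e-9)
  f <- graph_features(g)
  expect_length(f, 51)
  expect_equal(unname(f["voronoi_area_sd"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["voronoi_perimeter_minmax"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["voronoi_area_disorder"]), 0, tolerance = 1e-7)
  expect_equal(unname(f["mst_edge_disorder"]), 0, tolerance = 1e-7)
})

test_that("MST length matches brute-force enumeration for small N", {
  set.seed(31)
  for (n in c(5, 6, 7)) {
    pts <- matrix(runif(2 * n, 0, 100), n, 2)
    g <- build_graphs(pts, mpp = 1)
    expect_equal(sum(g$mst$edge_len), brute_force_mst_length(pts),
                 tolerance = 1e-9)
    expect_equal(nrow(g$mst$edges), n - 1)
  }
})

test_that("3-4-5 right triangle yields MST edges {3, 4}", {
  # embed the triangle with a distant fourth point so the spatial
  # structures are defined; the triangle's MST edges must still be 3 and 4
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(50, 50))
  g <- build_graphs(pts, mpp = 1)
  tri_edges <- g$mst$edge_len[g$mst$edge_len < 10]
  expect_equal(sort(tri_edges), c(3, 4), tolerance = 1e-9)
})

test_that("every MST edge is a Delaunay edge and cells are mutual duals", {
  set.seed(17)
  pts <- matrix(runif(160, 0, 200), 80, 2)
  g <- build_graphs(pts, mpp = 1)
  del_keys <- paste(pmin(g$delaunay$edges[, 1], g$delaunay$edges[, 2]),
                    pmax(g$delaunay$edges[, 1], g$delaunay$edges[, 2]))
  mst_keys <- paste(pmin(g$mst$edges[, 1], g$mst$edges[, 2]),
                    pmax(g$mst$edges[, 1], g$mst$edges[, 2]))
  expect_true(all(mst_keys %in% del_keys))
  # duality: the cells of two Delaunay-adjacent interior sites share a
  # Voronoi boundary (at least two common polygon vertices)
  shared <- 0L; checked <- 0L
  for (r in seq_len(nrow(g$delaunay$edges))) {
    i <- g$delaunay$edges[r, 1]; j <- g$delaunay$edges[r, 2]
    if (!(g$voronoi$interior[i] && g$voronoi$interior[j])) next
    pi_ <- g$voronoi$polygons[[i]]; pj <- g$voronoi$polygons[[j]]
    d <- outer(seq_len(nrow(pi_)), seq_len(nrow(pj)), function(a, b)
      sqrt((pi_[a, 1] - pj[b, 1])^2 + (pi_[a, 2] - pj[b, 2])^2))
    checked <- checked + 1L
    if (sum(d < 1e-6) >= 2) shared <- shared + 1L
  }
  expect_gt(checked, 5)
  expect_equal(shared, checked)
})

test_that("graph features are invariant under translation and 90-degree rotation", {
  f <- cached_field(80, 23)
  cen <- f$gt$centroids
  g0 <- graph_features(build_graphs(cen, 0.25))
  gt_ <- graph_features(build_graphs(sweep(cen, 2, c(37, -12), "+"), 0.25))
  rot90 <- cbind(-cen[, 2], cen[, 1]) + 600
  gr <- graph_features(build_graphs(rot90, 0.25))
  expect_equal(gt_, g0, tolerance = 1e-6)
  expect_equal(gr, g0, tolerance = 1e-6)
})

test_that("radius-based neighborhood features track physical units", {
  f <- cached_field(80, 23)
  g1 <- build_graphs(f$gt$centroids, 0.25)
  g2 <- build_graphs(f$gt$centroids, 0.5)  # same pixels, coarser mpp
  # doubling the pixel size doubles every physical distance: a 20 um
  # radius at mpp 0.5 spans the same pixels as a 10 um radius at mpp 0.25
  expect_equal(g2$knn$radius_counts[, 2], g1$knn$radius_counts[, 1])
  expect_equal(g2$knn$dist[, 3], 2 * g1$knn$dist[, 3])
})

test_that("degenerate centroid sets are rejected", {
  expect_error(build_graphs(matrix(runif(6), 3, 2), 1), "at least 4")
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(build_graphs(line, 1), "collinear")
})

test_that("cluster graph matches closed forms on K3 and P3", {
  tri <- matrix(c(0, 0, 10, 0, 5, 8), 3, 2, byrow = TRUE)
  fc <- cluster_graph_features(build_cluster_graph(tri, 1, eps = 2))
  expect_length(fc, 26)
  expect_equal(unname(fc["ccg_node_count"]), 3)
  expect_equal(unname(fc["ccg_transitivity"]), 1)
  expect_equal(unname(fc["ccg_clustering_coef"]), 1)
  expect_equal(unname(fc["ccg_n_components"]), 1)
  expect_equal(unname(fc["ccg_diameter"]), 1)
  expect_equal(unname(fc["ccg_spectral_radius"]), 2, tolerance = 1e-9)
  expect_equal(unname(fc["ccg_eigen2"]), -1, tolerance = 1e-9)

  path3 <- matrix(c(0, 0, 14, 0, 28, 0.01), 3, 2, byrow = TRUE)
  fp <- cluster_graph_features(build_cluster_graph(path3, 1, eps = 2))
  expect_equal(unname(fp["ccg_edge_count"]), 2)
  expect_equal(unname(fp["ccg_clustering_coef"]), 0)
  expect_equal(unname(fp["ccg_endpoint_frac"]), 2 / 3)
  expect_equal(unname(fp["ccg_diameter"]), 2)
})

test_that("chained nuclei merge into one node; edges match the decay rule", {
  # chain of nuclei each within eps of the next -> single node, no edges
  chain <- cbind(seq(0, 30, 5), rep(0, 7))
  cg <- build_cluster_graph(chain, 1, eps = 6)
  expect_equal(igraph::vcount(cg$graph), 1)
  expect_equal(igraph::ecount(cg$graph), 0)

  # random instance: edge set equals brute-force decay-rule evaluation
  set.seed(101)
  pts <- matrix(runif(40, 0, 60), 20, 2)
  cg <- build_cluster_graph(pts, 1, eps = 3, alpha = 0.5,
                            threshold = 15^-0.5)
  nodes <- cg$nodes
  want <- matrix(0L, nrow(nodes), nrow(nodes))
  for (i in seq_len(nrow(nodes))) for (j in seq_len(nrow(nodes))) {
    if (i == j) next
    d <- sqrt(sum((nodes[i, ] - nodes[j, ])^2))
    if (d^(-0.5) >= 15^-0.5) want[i, j] <- 1L
  }
  got <- as.matrix(igraph::as_adjacency_matrix(cg$graph, sparse = FALSE))
  expect_equal(unname(got), unname(want))
})

test_that("empty cluster graphs degrade gracefully", {
  cg <- build_cluster_graph(matrix(c(5, 5), 1, 2), 1)
  f <- cluster_graph_features(cg)
  expect_equal(unname(f["ccg_node_count"]), 1)
  expect_equal(unname(f["ccg_edge_count"]), 0)
})
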