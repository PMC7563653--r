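# Spatial-architecture features from nuclear centroids: Voronoi tessellation,
# Delaunay triangulation, Euclidean minimum spanning tree, nearest-neighbor
# statistics (51 features), and the cell cluster graph (26 features).

#' Build the spatial graphs over nuclear centroids
#'
#' Constructs the Voronoi tessellation, its dual Delaunay triangulation, the
#' Euclidean minimum spanning tree (computed on the Delaunay edge set, of
#' which it is always a subset), and k-nearest-neighbor / radius-count
#' statistics. All geometry is in microns. Voronoi cells clipped by the
#' enclosing window are flagged non-interior and excluded from Voronoi
#' statistics.
#'
#' @param centroids n x 2 matrix of pixel coordinates (n >= 4,
#'   non-collinear).
#' @param mpp microns per pixel.
#' @return object of class `spatial_graphs`: Voronoi cell table and
#'   polygons, Delaunay triangles and edge list, MST edge list, kNN
#'   distances and radius counts.
#' @export
build_graphs <- function(centroids, mpp) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2)
  n <- nrow(centroids)
  if (n < 4) stop("at least 4 centroids are required")
  pts <- centroids * mpp
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("centroids are collinear; spatial graphs undefined")

  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  # interior cells: not clipped by the window AND not Delaunay-adjacent to
  # a clipped cell (a one-ring guard band, so boundary-distorted cells
  # never enter the Voronoi statistics)
  unclipped <- vapply(tiles, function(tl) !any(tl$bp), logical(1))
  interior <- unclipped
  for (r in seq_len(nrow(dd$delsgs))) {
    i <- dd$delsgs$ind1[r]; j <- dd$delsgs$ind2[r]
    if (!unclipped[i]) interior[j] <- FALSE
    if (!unclipped[j]) interior[i] <- FALSE
  }
  vor <- lapply(tiles, function(tl) cbind(tl$x, tl$y))
  vor_area <- vapply(vor, polygon_area, numeric(1))
  vor_perim <- vapply(vor, polygon_perimeter, numeric(1))
  vor_chords <- lapply(vor, function(p) {
    ctr <- polygon_centroid(p)
    sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  })

  tri <- deldir::triang.list(dd)
  tri_sides <- unlist(lapply(tri, function(tt) {
    v <- cbind(tt$x, tt$y)
    c(sqrt(sum((v[1, ] - v[2, ])^2)), sqrt(sum((v[2, ] - v[3, ])^2)),
      sqrt(sum((v[1, ] - v[3, ])^2)))
  }))
  tri_area <- vapply(tri, function(tt) polygon_area(cbind(tt$x, tt$y)),
                     numeric(1))

  del_edges <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  # edge lengths from the point coordinates (delsgs stores rounded copies)
  del_len <- sqrt(rowSums((pts[del_edges[, 1], , drop = FALSE] -
                             pts[del_edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(del_edges, directed = FALSE)
  igraph::E(g)$weight <- del_len
  mst <- igraph::mst(g)
  me <- igraph::as_edgelist(mst)
  mst_len <- igraph::E(mst)$weight

  k_max <- min(max(KNN_K), n - 1L)
  kn <- FNN::get.knn(pts, k = k_max)$nn.dist
  dmat <- as.matrix(stats::dist(pts))
  radius_counts <- sapply(NN_RADII, function(r) rowSums(dmat <= r) - 1L)
  local_density <- radius_counts[, length(NN_RADII)] /
    (pi * max(NN_RADII)^2)

  structure(list(
    points = pts, n = n,
    voronoi = list(polygons = vor, area = vor_area, perimeter = vor_perim,
                   chords = vor_chords, interior = interior),
    delaunay = list(edges = del_edges, edge_len = del_len,
                    tri_sides = tri_sides, tri_area = tri_area),
    mst = list(edges = me, edge_len = mst_len),
    knn = list(dist = kn, radius_counts = radius_counts,
               local_density = local_density)
  ), class = "spatial_graphs")
}

#' Spatial-graph feature block (51 features)
#'
#' Summarizes the structures from [build_graphs()] into the 51-feature
#' graph block: Voronoi cell area / perimeter / centroid-to-vertex chord
#' length and Delaunay triangle side / area and MST edge length, each by
#' \{mean, SD, min/max ratio, disorder\}; distance to the 3/5/7th nearest
#' neighbor and neighbor counts within 10-50 micron radii and local density,
#' each by \{mean, SD, disorder\}. Disorder is `1 - 1/(1 + SD/mean)`.
#'
#' @param graphs a `spatial_graphs` object.
#' @return named numeric vector of length 51 in manifest order.
#' @export
graph_features <- function(graphs) {
  stopifnot(inherits(graphs, "spatial_graphs"))
  keep <- graphs$voronoi$interior
  if (sum(keep) < 2)
    stop("fewer than 2 interior Voronoi cells; enlarge the field")
  chord_all <- unlist(graphs$voronoi$chords[keep])
  out <- c(
    stat4(graphs$voronoi$area[keep]),
    stat4(graphs$voronoi$perimeter[keep]),
    stat4(chord_all),
    stat4(graphs$delaunay$tri_sides),
    stat4(graphs$delaunay$tri_area),
    stat4(graphs$mst$edge_len)
  )
  stat3 <- function(x) c(mean(x), stats::sd(x), disorder_stat(x))
  for (k in KNN_K) {
    kk <- min(k, ncol(graphs$knn$dist))
    out <- c(out, stat3(graphs$knn$dist[, kk]))
  }
  for (i in seq_along(NN_RADII))
    out <- c(out, stat3(graphs$knn$radius_counts[, i]))
  out <- c(out, stat3(graphs$knn$local_density))
  out[!is.finite(out)] <- 0
  names(out) <- manifest_names("graph")
  out
}

#' Build the cell cluster graph
#'
#' Nuclei are agglomeratively grouped by single-linkage clustering at
#' distance `eps`; each cluster becomes a node at the member-centroid mean.
#' Nodes u, v are connected iff `d(u,v)^(-alpha) >= threshold`, a
#' deterministic distance-decay rule (equivalently `d <= threshold^(-1/alpha)`).
#'
#' @param centroids n x 2 pixel-coordinate matrix (n >= 1).
#' @param mpp microns per pixel.
#' @param eps single-linkage merge distance, microns (default 8, below the
#'   typical nearest-neighbor spacing so only genuinely abutting nuclei
#'   merge into one node).
#' @param alpha decay exponent (default 0.5).
#' @param threshold decay threshold; the default corresponds to a 15 micron
#'   connection cutoff at `alpha = 0.5`, chosen so the expected node degree
#'   is about 5 on the default synthetic field.
#' @return object of class `cluster_graph` with the igraph object, node
#'   coordinates, cluster sizes and edge lengths.
#' @export
build_cluster_graph <- function(centroids, mpp, eps = 8, alpha = 0.5,
                                threshold = 15^-0.5) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2, nrow(centroids) >= 1)
  pts <- centroids * mpp
  n <- nrow(pts)
  memb <- if (n == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = eps)
  k <- max(memb)
  nodes <- t(vapply(seq_len(k), function(i)
    colMeans(pts[memb == i, , drop = FALSE]), numeric(2)))
  sizes <- tabulate(memb, k)
  cutoff <- threshold^(-1 / alpha)
  edges <- NULL; elen <- numeric(0)
  if (k >= 2) {
    dmat <- as.matrix(stats::dist(nodes))
    idx <- which(upper.tri(dmat) & dmat <= cutoff & dmat > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      edges <- idx
      elen <- dmat[idx]
    }
  }
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- elen
  }
  structure(list(graph = g, nodes = nodes, sizes = sizes,
                 edge_len = elen, eps = eps, alpha = alpha,
                 threshold = threshold, cutoff = cutoff),
            class = "cluster_graph")
}

#' Cell-cluster-graph feature block (26 features)
#'
#' Topological and metric summaries of the cluster graph: node/edge counts,
#' degree and edge-length statistics, eccentricity / diameter / radius /
#' average path length on the giant component, clustering coefficients,
#' component structure, cluster-size statistics, and the two leading
#' adjacency eigenvalues.
#'
#' @param cg a `cluster_graph` object.
#' @return named numeric vector of length 26 in manifest order.
#' @export
cluster_graph_features <- function(cg) {
  stopifnot(inherits(cg, "cluster_graph"))
  g <- cg$graph
  k <- igraph::vcount(g)
  nm <- manifest_names("cluster")
  if (k == 0) {
    warning("empty cluster graph; returning all-zero block")
    out <- rep(0, 26); names(out) <- nm
    return(out)
  }
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  giant_id <- which.max(comps$csize)
  giant <- igraph::induced_subgraph(g, which(comps$membership == giant_id))
  gsize <- igraph::vcount(giant)
  # topological (hop-count) distances; metric structure is captured by the
  # edge-length statistics instead
  ecc <- if (gsize >= 1) igraph::eccentricity(giant, weights = NA) else 0
  rad <- min(ecc)
  loc_cc <- igraph::transitivity(g, type = "localundirected",
                                 isolates = "zero")
  trans <- igraph::transitivity(g, type = "global")
  adj_eig <- if (k >= 1)
    sort(eigen(igraph::as_adjacency_matrix(g, sparse = FALSE),
               symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE) else 0
  el <- cg$edge_len
  el_stats <- if (length(el) >= 1)
    c(mean(el), if (length(el) >= 2) stats::sd(el) else 0,
      minmax_ratio(el), disorder_stat(el)) else rep(0, 4)
  out <- c(
    k, length(el),
    mean(deg), if (k >= 2) stats::sd(deg) else 0,
    el_stats,
    mean(ecc), if (gsize >= 2) stats::sd(ecc) else 0,
    stats::quantile(ecc, 0.9, names = FALSE, type = 7),
    max(ecc),                                   # diameter (giant component)
    rad,
    if (gsize >= 2) igraph::mean_distance(giant, weights = NA) else 0,
    mean(loc_cc),
    if (is.nan(trans)) 0 else trans,
    comps$no,
    gsize / k,
    mean(deg == 0),
    mean(deg == 1),
    sum(ecc == rad),
    mean(cg$sizes), if (k >= 2) stats::sd(cg$sizes) else 0,
    minmax_ratio(cg$sizes),
    adj_eig[1],
    if (k >= 2) adj_eig[2] else 0
  )
  out[!is.finite(out)] <- 0
  names(out) <- nm
  out
}
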