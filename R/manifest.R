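# Canonical feature manifest. Every feature block resolves its order and
# names from here; downstream code addresses features by name, never by
# position, except when reading/writing the cohort CSV boundary.

MANIFEST_VERSION <- "1.0"

# the 25 per-nucleus shape measures, in canonical order
SHAPE_MEASURES <- c(
  "area", "perimeter", "radial_max", "radial_mean", "radial_sd",
  "radius_ratio", "smoothness", "fractal_dim",
  paste0("hu", 1:7), paste0("fd", 1:10)
)

# the 13 second-order co-occurrence measures for orientation disorder
DISORDER_MEASURES <- c(
  "contrast_energy", "contrast_inverse_moment", "contrast_average",
  "contrast_variance", "contrast_entropy",
  "intensity_average", "intensity_variance", "intensity_entropy",
  "entropy", "energy", "correlation", "imc1", "imc2"
)

# the 26 cell-cluster-graph measures, in canonical order
CLUSTER_MEASURES <- c(
  "node_count", "edge_count", "degree_mean", "degree_sd",
  "edge_len_mean", "edge_len_sd", "edge_len_minmax", "edge_len_disorder",
  "ecc_mean", "ecc_sd", "ecc_p90", "diameter", "radius", "avg_path_len",
  "clustering_coef", "transitivity", "n_components", "giant_ratio",
  "isolated_frac", "endpoint_frac", "central_count",
  "size_mean", "size_sd", "size_minmax", "spectral_radius", "eigen2"
)

KNN_K <- c(3L, 5L, 7L)
NN_RADII <- c(10, 20, 30, 40, 50)  # microns

#' Canonical 216-feature manifest
#'
#' Returns the frozen, versioned manifest of the 216 nuclear morphometry
#' features in their canonical order: 51 spatial-graph features
#' (Voronoi / Delaunay / minimum spanning tree / nearest-neighbor
#' statistics), 100 nuclear shape features (25 contour measures, each
#' aggregated by mean, median, SD and min/max ratio over nuclei), 39
#' orientation-disorder features (13 co-occurrence statistics aggregated by
#' mean, SD and range over local subgraphs), and 26 cell-cluster-graph
#' features.
#'
#' @return data.frame with columns `name`, `family`
#'   (`graph`/`shape`/`disorder`/`cluster`), `units` and `version`
#'   attribute; exactly 216 rows.
#' @examples
#' m <- feature_manifest()
#' table(m$family)
#' @export
feature_manifest <- function() {
  graph_names <- c(
    paste0("voronoi_area_", c("mean", "sd", "minmax", "disorder")),
    paste0("voronoi_perimeter_", c("mean", "sd", "minmax", "disorder")),
    paste0("voronoi_chord_", c("mean", "sd", "minmax", "disorder")),
    paste0("delaunay_side_", c("mean", "sd", "minmax", "disorder")),
    paste0("delaunay_area_", c("mean", "sd", "minmax", "disorder")),
    paste0("mst_edge_", c("mean", "sd", "minmax", "disorder")),
    as.vector(t(outer(paste0("knn_dist", KNN_K, "_"),
                      c("mean", "sd", "disorder"), paste0))),
    as.vector(t(outer(paste0("nn_count_r", NN_RADII, "_"),
                      c("mean", "sd", "disorder"), paste0))),
    paste0("local_density_", c("mean", "sd", "disorder"))
  )
  shape_names <- as.vector(t(outer(paste0("shape_", SHAPE_MEASURES, "_"),
                                   c("mean", "median", "sd", "minmax"),
                                   paste0)))
  disorder_names <- as.vector(t(outer(paste0("orient_", DISORDER_MEASURES, "_"),
                                      c("mean", "sd", "range"), paste0)))
  cluster_names <- paste0("ccg_", CLUSTER_MEASURES)

  units_graph <- rep("mixed", length(graph_names))
  m <- data.frame(
    name = c(graph_names, shape_names, disorder_names, cluster_names),
    family = rep(c("graph", "shape", "disorder", "cluster"),
                 times = c(length(graph_names), length(shape_names),
                           length(disorder_names), length(cluster_names))),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(m) == 216L, !anyDuplicated(m$name))
  attr(m, "version") <- MANIFEST_VERSION
  m
}

manifest_names <- function(family = NULL) {
  m <- feature_manifest()
  if (is.null(family)) m$name else m$name[m$family == family]
}
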