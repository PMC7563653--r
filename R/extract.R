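# Full-panel feature extraction: concatenates the four family blocks in
# manifest order (graph 51, shape 100, disorder 39, cluster 26 = 216), and
# the cohort CSV boundary.

#' Construct a nucleus set
#'
#' Bundles segmented (or ground-truth) nucleus contours with centroids and
#' the pixel size. Centroids are recomputed from the polygons when not
#' supplied.
#'
#' @param contours list of closed polygons (n x 2 pixel-coordinate
#'   matrices).
#' @param centroids optional n x 2 matrix; defaults to polygon centroids.
#' @param mpp microns per pixel.
#' @return object of class `nucleus_set`.
#' @export
nucleus_set <- function(contours, centroids = NULL, mpp) {
  stopifnot(is.list(contours), mpp > 0)
  if (is.null(centroids))
    centroids <- t(vapply(contours, polygon_centroid, numeric(2)))
  stopifnot(nrow(centroids) == length(contours))
  structure(list(contours = contours, centroids = centroids, mpp = mpp),
            class = "nucleus_set")
}

as_nucleus_set <- function(x) {
  if (inherits(x, "nucleus_set")) return(x)
  # ground-truth lists from the synthetic generator carry the same fields
  nucleus_set(x$contours, x$centroids, x$mpp)
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei, %.3g microns/pixel\n",
              length(x$contours), x$mpp))
  invisible(x)
}

#' Extract the full 216-feature morphometry panel
#'
#' Runs the four family extractors on one nucleus set and concatenates
#' their blocks in manifest order: spatial-graph (51), shape (100),
#' orientation disorder (39), cell cluster graph (26).
#'
#' @param nuclei a [nucleus_set()] (or a ground-truth list from
#'   [generate_nucleus_field()]).
#' @param min_nuclei minimum nuclei required (default 10).
#' @param subgraph_alpha,subgraph_threshold distance-decay parameters shared
#'   by the disorder subgraphs (see [build_subgraphs()]).
#' @param ccg_eps,ccg_alpha,ccg_threshold cell-cluster-graph parameters
#'   (see [build_cluster_graph()]).
#' @param bins orientation bins for the disorder block.
#' @return named numeric vector of length 216 in manifest order.
#' @examples
#' f <- generate_nucleus_field(synthetic_config(n_nuclei = 60, seed = 2))
#' v <- extract_all(f$gt)
#' length(v)
#' @export
extract_all <- function(nuclei, min_nuclei = 10L,
                        subgraph_alpha = 0.5, subgraph_threshold = 50^-0.5,
                        ccg_eps = 8, ccg_alpha = 0.5,
                        ccg_threshold = 15^-0.5, bins = 18L) {
  ns <- as_nucleus_set(nuclei)
  n <- length(ns$contours)
  if (n < min_nuclei)
    stop(sprintf(paste0(
      "%d nuclei < minimum %d: the spatial-graph features require enough ",
      "interior Voronoi cells and the shape/disorder aggregates require ",
      ">= 2 nuclei"), n, min_nuclei))
  g <- build_graphs(ns$centroids, ns$mpp)
  graph_block <- graph_features(g)
  shp <- t(vapply(ns$contours, measure_nucleus,
                  numeric(length(SHAPE_MEASURES)), mpp = ns$mpp))
  shape_block <- aggregate_shape(shp)
  ors <- vapply(ns$contours, function(p) as.numeric(nucleus_orientation(p)),
                numeric(1))
  sg <- build_subgraphs(ns$centroids, ns$mpp, subgraph_alpha,
                        subgraph_threshold)
  disorder_block <- disorder_features(ors, sg, bins)
  cg <- build_cluster_graph(ns$centroids, ns$mpp, ccg_eps, ccg_alpha,
                            ccg_threshold)
  cluster_block <- cluster_graph_features(cg)
  out <- c(graph_block, shape_block, disorder_block, cluster_block)
  stopifnot(identical(names(out), manifest_names()))
  out
}

#' Extract features for a whole synthetic cohort
#'
#' @param cohort list of patients from [generate_cohort()].
#' @param ... passed to [extract_all()].
#' @return `cohort_table` data.frame: `patient_id`, `label`, 216 feature
#'   columns in manifest order.
#' @export
extract_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(p) {
    v <- extract_all(p$gt, ...)
    cbind(data.frame(patient_id = p$patient_id, label = p$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

VALID_LABELS <- c("non-progressor", "progressor")

validate_cohort <- function(df) {
  nm <- manifest_names()
  feat_cols <- setdiff(colnames(df), c("patient_id", "label"))
  if (length(feat_cols) != length(nm))
    stop(sprintf("feature count mismatch: expected %d, found %d",
                 length(nm), length(feat_cols)))
  if (!identical(feat_cols, nm)) {
    if (all(sort(feat_cols) == sort(nm))) {
      warning("feature columns out of manifest order; remapping by name")
      df <- df[, c("patient_id", "label", nm)]
    } else {
      stop("feature names do not match the manifest")
    }
  }
  bad <- which(!df$label %in% VALID_LABELS)
  if (length(bad))
    stop(sprintf("unknown label %s in row %d", dQuote(df$label[bad[1]]),
                 bad[1]))
  if (anyNA(df[, nm]))
    stop("missing feature values in cohort table")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read a cohort feature table
#'
#' CSV with header `patient_id, label`, then the 216 manifest-ordered
#' feature columns. Round-trips losslessly to at least 12 significant
#' digits; labels and the column contract are validated on read.
#'
#' @param cohort a `cohort_table` data.frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- validate_cohort(as.data.frame(cohort, check.names = FALSE))
  nm <- manifest_names()
  df[nm] <- lapply(df[nm], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% colnames(df)[1:2]))
    stop("cohort CSV must start with columns patient_id, label")
  validate_cohort(df)
}

cohort_matrix <- function(cohort) {
  m <- as.matrix(cohort[, manifest_names()])
  rownames(m) <- cohort$patient_id
  m
}

cohort_labels <- function(cohort) cohort$label == "progressor"
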