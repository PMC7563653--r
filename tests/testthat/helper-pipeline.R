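# shared end-to-end pipeline fixtures for the heavier tests

.pipeline_cache <- new.env(parent = emptyenv())

# 190-patient two-class cohort (95 per class) under the default study
# conditions, extracted once per master seed and cached for the session
pipeline_cohort <- function(master_seed, n_per_class = 95,
                            n_nuclei = 100) {
  key <- paste0("seed", master_seed, "_", n_per_class, "_", n_nuclei)
  if (is.null(.pipeline_cache[[key]])) {
    cfgs <- progression_configs(n_nuclei = n_nuclei)
    co <- generate_cohort(n_per_class, cfgs, seed = master_seed)
    .pipeline_cache[[key]] <- extract_cohort(co)
  }
  .pipeline_cache[[key]]
}

# features expected a priori to respond to the three planted generator
# knobs: packing variance (jitter_sigma), orientation disorder (kappa),
# and shape heterogeneity (eccentricity_sd)
planted_effect_features <- function() {
  nm <- nucleoqh::feature_manifest()$name
  c(
    # packing variance: dispersion of all tessellation/graph statistics
    # plus the density sub-block (clumping shifts neighbor counts and
    # nearest-neighbor distances) and the cluster-graph structure
    grep("^(voronoi|delaunay|mst)_.*_(sd|disorder)$", nm, value = TRUE),
    grep("^(knn_dist|nn_count|local_density)", nm, value = TRUE),
    c("ccg_degree_mean", "ccg_degree_sd", "ccg_edge_count",
      "ccg_edge_len_sd", "ccg_edge_len_disorder",
      "ccg_size_mean", "ccg_size_sd"),
    # orientation disorder: the whole co-occurrence family
    grep("^orient_", nm, value = TRUE),
    # shape heterogeneity: eccentricity-linked measures and dispersions
    c("shape_radius_ratio_sd", "shape_radius_ratio_minmax",
      "shape_radial_sd_mean", "shape_radial_sd_sd",
      "shape_fd2_mean", "shape_fd2_sd",
      "shape_hu1_sd", "shape_hu2_mean", "shape_hu2_sd")
  )
}

# stratified train/test split: 30 + 30 training, remainder held out
split_training <- function(tab, seed, n_train_per_class = 30) {
  set.seed(seed)
  pos <- which(tab$label == "progressor")
  neg <- which(tab$label == "non-progressor")
  tr <- c(sample(pos, n_train_per_class), sample(neg, n_train_per_class))
  list(train = tab[tr, , drop = FALSE], test = tab[-tr, , drop = FALSE])
}
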