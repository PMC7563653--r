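# cohort fixtures built in code

# feature-level synthetic cohort: 216 standard-normal features in manifest
# order, with an optional standardized mean shift planted on chosen
# features in the progressor class
make_feature_cohort <- function(n_per_class, shift = 0,
                                signal_features = character(0),
                                seed = 1) {
  set.seed(seed)
  nm <- nucleoqh::feature_manifest()$name
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * length(nm)), n, length(nm),
              dimnames = list(NULL, nm))
  label <- rep(c("non-progressor", "progressor"), each = n_per_class)
  X[label == "progressor", signal_features] <-
    X[label == "progressor", signal_features] + shift
  out <- cbind(data.frame(patient_id = sprintf("S%03d", seq_len(n)),
                          label = label, stringsAsFactors = FALSE),
               as.data.frame(X, check.names = FALSE))
  class(out) <- c("cohort_table", "data.frame")
  out
}

# memoized small nucleus fields so several test files can share them
.field_cache <- new.env(parent = emptyenv())

cached_field <- function(n_nuclei, seed, render = FALSE, ...) {
  key <- paste(n_nuclei, seed, render, ..., sep = "_")
  if (is.null(.field_cache[[key]]))
    .field_cache[[key]] <- generate_nucleus_field(
      synthetic_config(n_nuclei = n_nuclei, seed = seed, render = render,
                       ...))
  .field_cache[[key]]
}
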