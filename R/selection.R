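# Repeated-split feature identification: univariate ranking (Wilcoxon
# rank-sum or Welch t-test) on one half-split, LDA/QDA validation on the
# other, AUC-based retention, and recurrence tallying of the selected
# features; plus the clustergram of the final features.

# Column-wise two-sided p-values; constant features get p = 1 so they are
# never selected. TT is Welch's unequal-variance t-test; WLCX is the
# Wilcoxon rank-sum normal approximation with tie correction and
# continuity correction (matching stats::t.test / stats::wilcox.test with
# exact = FALSE, which the tests use as oracles).
feature_pvalues <- function(X, y, selector) {
  n1 <- sum(y); n0 <- sum(!y); n <- n1 + n0
  if (selector == "TT") {
    m1 <- colMeans(X[y, , drop = FALSE])
    m0 <- colMeans(X[!y, , drop = FALSE])
    v1 <- apply(X[y, , drop = FALSE], 2, stats::var)
    v0 <- apply(X[!y, , drop = FALSE], 2, stats::var)
    se2 <- v1 / n1 + v0 / n0
    tt <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  } else {
    p <- apply(X, 2, function(x) {
      r <- rank(x)
      u <- sum(r[y]) - n1 * (n1 + 1) / 2
      ties <- table(x)
      sig2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sig2 <= 0) return(NA_real_)
      z <- u - n1 * n0 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sig2)   # continuity correction
      2 * stats::pnorm(-abs(z))
    })
  }
  p[!is.finite(p)] <- 1
  pmin(p, 1)
}

standardized_effect <- function(x, y) {
  sp <- sqrt((stats::var(x[y]) + stats::var(x[!y])) / 2)
  if (!is.finite(sp) || sp == 0) return(0)
  abs(mean(x[y]) - mean(x[!y])) / sp
}

#' Rank features by univariate class separation
#'
#' Orders features by ascending two-sided p-value of the chosen test
#' (Wilcoxon rank-sum `WLCX` or Welch t-test `TT`) comparing progressors
#' against non-progressors; ties are broken by descending absolute
#' standardized effect size, then by manifest order. Constant features are
#' assigned p = 1 and are never selected.
#'
#' @param train `cohort_table` with both classes present.
#' @param selector `"WLCX"` or `"TT"`.
#' @param k number of features to return (default 6).
#' @return character vector of `k` feature names.
#' @export
rank_features <- function(train, selector = c("WLCX", "TT"), k = 6L) {
  selector <- match.arg(selector)
  y <- cohort_labels(train)
  if (!any(y) || all(y)) stop("both classes must be present")
  X <- cohort_matrix(train)
  pv <- feature_pvalues(X, y, selector)
  eff <- apply(X, 2, standardized_effect, y = y)
  ord <- order(pv, -eff, seq_along(pv))
  colnames(X)[ord[seq_len(k)]]
}

# one half-split: select features on half A only, train LDA/QDA on half A,
# score on half B; half-B labels enter only the recorded validation AUC
one_split_records <- function(half_a, half_b, k = 6L) {
  records <- list()
  Xa <- cohort_matrix(half_a); ya <- cohort_labels(half_a)
  Xb <- cohort_matrix(half_b); yb <- cohort_labels(half_b)
  for (sel in c("TT", "WLCX")) {
    feats <- rank_features(half_a, sel, k)
    for (clf in c("LDA", "QDA")) {
      fit <- fit_discriminant(Xa[, feats, drop = FALSE], ya, type = clf)
      sc <- predict_discriminant(fit, Xb[, feats, drop = FALSE])
      records[[length(records) + 1L]] <-
        list(iteration = NA_integer_, selector = sel, classifier = clf,
             features = feats, auc = auc_rank(sc, yb))
    }
  }
  records
}

#' Repeated-split feature identification
#'
#' Runs `n_iter` iterations; in each, the training cohort is split into two
#' class-stratified halves. On half A, six features are selected by each of
#' the two univariate selectors (WLCX, TT); each set then trains an LDA and
#' a QDA classifier on half A, and the model's AUC is recorded on half B,
#' giving four records per iteration (TT+LDA, TT+QDA, WLCX+LDA, WLCX+QDA).
#' Records with validation AUC >= `retention_auc` are retained; feature
#' occurrences in retained records are tallied and the six most recurrent
#' features returned. Recurrence ties are broken by total occurrences
#' across all (retained or not) records, then by mean selection rank, then
#' by manifest order.
#'
#' @param d1 balanced `cohort_table` (equal progressors and
#'   non-progressors).
#' @param n_iter number of random half-split iterations (default 30).
#' @param retention_auc minimum validation AUC for a record to be retained
#'   (default 0.65).
#' @param seed master seed driving all splits.
#' @param k features selected per record (default 6).
#' @return object of class `qh_selection`: `records` (one row per
#'   iteration x selector x classifier with the selected features and
#'   validation AUC), `tally`, and `features` (the final `k` names).
#' @export
identify_features <- function(d1, n_iter = 30L, retention_auc = 0.65,
                              seed = 1L, k = 6L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  y <- cohort_labels(d1)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos != n_neg)
    stop("d1 must be balanced (equal progressors and non-progressors)")
  if (n_pos < 2) stop("need at least 2 patients per class")
  set.seed(seed)
  X <- cohort_matrix(d1)
  nm <- manifest_names()

  records <- list()
  for (it in seq_len(n_iter)) {
    # class-stratified half-split, sampling without replacement
    ia <- c(sample(which(y), n_pos %/% 2), sample(which(!y), n_neg %/% 2))
    recs <- one_split_records(d1[ia, , drop = FALSE],
                              d1[-ia, , drop = FALSE], k)
    for (r in recs) {
      r$iteration <- it
      records[[length(records) + 1L]] <- r
    }
  }
  aucs <- vapply(records, `[[`, numeric(1), "auc")
  retained <- aucs >= retention_auc
  if (!any(retained))
    stop("no combinations retained: no record reached the retention AUC")
  all_feats <- lapply(records, `[[`, "features")
  tally_in <- function(idx) {
    t0 <- table(factor(unlist(all_feats[idx]), levels = nm))
    as.vector(t0)
  }
  tally_ret <- tally_in(which(retained))
  tally_all <- tally_in(seq_along(records))
  # mean selection rank (1..k) across all records where a feature appears
  rank_sum <- numeric(length(nm)); rank_n <- numeric(length(nm))
  for (fs in all_feats) {
    ii <- match(fs, nm)
    rank_sum[ii] <- rank_sum[ii] + seq_along(fs)
    rank_n[ii] <- rank_n[ii] + 1
  }
  mean_rank <- ifelse(rank_n > 0, rank_sum / rank_n, Inf)
  ord <- order(-tally_ret, -tally_all, mean_rank, seq_along(nm))
  final <- nm[ord[seq_len(k)]]

  rec_df <- data.frame(
    iteration = vapply(records, `[[`, numeric(1), "iteration"),
    selector = vapply(records, `[[`, character(1), "selector"),
    classifier = vapply(records, `[[`, character(1), "classifier"),
    features = vapply(all_feats, paste, character(1), collapse = ";"),
    auc = aucs, retained = retained, stringsAsFactors = FALSE)
  structure(list(records = rec_df,
                 tally = stats::setNames(tally_ret, nm),
                 features = final, retention_auc = retention_auc,
                 n_iter = n_iter, seed = seed),
            class = "qh_selection")
}

#' @export
print.qh_selection <- function(x, ...) {
  cat(sprintf(
    "<qh_selection> %d iterations x 4 records = %d records, %d retained (AUC >= %.2f)\n",
    x$n_iter, nrow(x$records), sum(x$records$retained), x$retention_auc))
  cat("final features:\n")
  for (f in x$features)
    cat(sprintf("  %-40s (retained-record recurrence %d)\n", f, x$tally[f]))
  invisible(x)
}

#' Clustergram of selected features
#'
#' Hierarchically clusters both patients and features using Spearman
#' distance (1 - Spearman correlation) with average linkage, and z-scores
#' the matrix per feature for heatmap display. Constant features have
#' undefined correlations and are dropped with a warning.
#'
#' @param d1 `cohort_table`.
#' @param features feature names to include (typically the final six).
#' @return list with `row_linkage` (patients), `col_linkage` (features),
#'   `matrix` (z-scored patients x features), `labels`.
#' @export
clustergram <- function(d1, features) {
  X <- cohort_matrix(d1)[, features, drop = FALSE]
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(features[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need at least 2 non-constant features")
  spearman_dist <- function(m) {
    rho <- stats::cor(m, method = "spearman")
    stats::as.dist(1 - rho)
  }
  col_link <- stats::hclust(spearman_dist(X), method = "average")
  row_link <- stats::hclust(spearman_dist(t(X)), method = "average")
  Z <- scale(X)
  list(row_linkage = row_link, col_linkage = col_link, matrix = Z,
       labels = d1$label)
}

#' Plot a clustergram as a heatmap with dendrogram ordering
#'
#' @param cg result of [clustergram()].
#' @param ... passed to [graphics::image()].
#' @export
plot_clustergram <- function(cg, ...) {
  Z <- cg$matrix[cg$row_linkage$order, cg$col_linkage$order, drop = FALSE]
  graphics::image(t(Z), axes = FALSE,
                  col = grDevices::hcl.colors(64, "BrBG"), ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(Z)),
                 labels = colnames(Z), las = 2, cex.axis = 0.6)
  invisible(cg)
}
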