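# Nuclear orientation-disorder features: per-nucleus orientation from the
# principal axis of the boundary, local subgraphs from a deterministic
# distance-decay rule, and second-order co-occurrence statistics of
# quantized orientations within each subgraph (39 features).

#' Principal-axis orientation of a nucleus
#'
#' The orientation is the angle of the dominant eigenvector of the
#' covariance of the contour points (resampled to equal arc length so
#' vertex density does not bias the axis), folded to the axial range
#' [0, 180) degrees. Near-circular contours have no meaningful axis: if the
#' eigenvalue ratio is below 1.05 the angle is reported as 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param contour closed polygon, n x 2 matrix (>= 8 vertices). Units
#'   cancel; pixel coordinates are fine.
#' @return angle in degrees in [0, 180), with attribute `degenerate`.
#' @export
nucleus_orientation <- function(contour) {
  stopifnot(is.matrix(contour), ncol(contour) == 2)
  if (nrow(contour) < 8) stop("contour must have at least 8 vertices")
  p <- resample_contour(contour, 128L)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  degenerate <- ev$values[2] <= 0 || ev$values[1] / ev$values[2] < 1.05
  ang <- if (degenerate) 0 else
    fold_axial(atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi)
  structure(ang, degenerate = degenerate)
}

#' Local subgraphs by deterministic distance decay
#'
#' Nucleus j belongs to the subgraph of nucleus i iff
#' `d(i,j)^(-alpha) >= threshold` (equivalently `d <= threshold^(-1/alpha)`),
#' the deterministic form of a probabilistic distance-decay neighborhood
#' rule; the subgraph of i is i together with its neighbors.
#'
#' @param centroids n x 2 pixel-coordinate matrix (n >= 2).
#' @param mpp microns per pixel.
#' @param alpha decay exponent (default 0.5).
#' @param threshold decay threshold; the default gives a 50 micron cutoff
#'   at `alpha = 0.5`.
#' @return list of integer neighbor vectors (each includes the nucleus
#'   itself as first element); isolated nuclei yield singletons.
#' @export
build_subgraphs <- function(centroids, mpp, alpha = 0.5,
                            threshold = 50^-0.5) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2, nrow(centroids) >= 2)
  cutoff <- threshold^(-1 / alpha)
  dmat <- as.matrix(stats::dist(centroids * mpp))
  lapply(seq_len(nrow(centroids)), function(i) {
    nb <- which(dmat[i, ] <= cutoff & seq_len(ncol(dmat)) != i)
    c(i, unname(nb))
  })
}

# second-order statistics of a normalized symmetric co-occurrence matrix
# over B axial orientation bins; "contrast" distances use the cyclic axial
# bin distance min(|i-j|, B-|i-j|)
cooccurrence_stats <- function(P) {
  B <- nrow(P)
  idx <- seq_len(B)
  I <- matrix(idx, B, B)
  J <- t(I)
  dm <- pmin(abs(I - J), B - abs(I - J))
  plog <- function(x) ifelse(x > 0, log2(x), 0)

  pd <- vapply(0:max(dm), function(k) sum(P[dm == k]), numeric(1))
  kd <- 0:max(dm)
  ca <- sum(kd * pd)
  s <- I + J
  ps <- vapply(2:(2 * B), function(k) sum(P[s == k]), numeric(1))
  ks <- 2:(2 * B)
  ia <- sum(ks * ps)

  px <- rowSums(P)
  mu_x <- sum(idx * px)
  sd_x <- sqrt(sum((idx - mu_x)^2 * px))
  corr <- if (sd_x > 0)
    (sum(I * J * P) - mu_x^2) / sd_x^2 else 0

  hxy <- -sum(P * plog(P))
  hx <- -sum(px * plog(px))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  c(contrast_energy = sum(P * dm^2),
    contrast_inverse_moment = sum(P / (1 + dm^2)),
    contrast_average = ca,
    contrast_variance = sum((kd - ca)^2 * pd),
    contrast_entropy = -sum(pd * plog(pd)),
    intensity_average = ia,
    intensity_variance = sum((ks - ia)^2 * ps),
    intensity_entropy = -sum(ps * plog(ps)),
    entropy = hxy,
    energy = sum(P^2),
    correlation = corr,
    imc1 = imc1,
    imc2 = imc2)
}

#' Orientation-disorder feature block (39 features)
#'
#' Within each local subgraph, each member's orientation is taken relative
#' to the subgraph's center nucleus (`(theta_j - theta_center) mod 180`,
#' an axial quantity, so the block is exactly invariant under global
#' rotations of the field) and quantized into `bins` equal bins over
#' [0, 180); a symmetric co-occurrence matrix is accumulated over all
#' within-subgraph nucleus pairs and normalized to a joint distribution.
#' Thirteen second-order statistics (contrast energy / inverse moment /
#' average / variance / entropy, intensity average / variance / entropy,
#' entropy, energy, correlation, and the two information measures of
#' correlation) are computed per subgraph and aggregated across subgraphs
#' by \{mean, SD, range\}, giving 13 x 3 = 39 features in manifest order.
#'
#' @param orientations numeric vector of axial angles, degrees in [0, 180).
#' @param subgraphs neighbor lists from [build_subgraphs()] (first element
#'   of each is the subgraph's center nucleus).
#' @param bins number of orientation bins (default 18, i.e. 10 degrees).
#' @return named numeric vector of length 39.
#' @export
disorder_features <- function(orientations, subgraphs, bins = 18L) {
  stopifnot(length(orientations) >= 2, bins >= 2)
  mats <- list()
  for (sg in subgraphs) {
    if (length(sg) < 2) next
    rel <- fold_axial(orientations[sg] - orientations[sg[1]])
    bin_of <- pmin(floor(rel / (180 / bins)) + 1L, bins)
    # each unordered pair contributes symmetrically at (b_i, b_j) and
    # (b_j, b_i): with per-bin member counts c this is c c' - diag(c)
    cc <- tabulate(bin_of, bins)
    M <- tcrossprod(cc)
    diag(M) <- cc * (cc - 1)
    mats[[length(mats) + 1L]] <- M / sum(M)
  }
  if (length(mats) == 0)
    stop("no co-occurring pairs: all subgraphs are singletons")
  stats_mat <- t(vapply(mats, cooccurrence_stats,
                        numeric(length(DISORDER_MEASURES))))
  agg <- function(x) c(mean = mean(x),
                       sd = if (length(x) >= 2) stats::sd(x) else 0,
                       range = diff(range(x)))
  out <- as.vector(apply(stats_mat, 2, agg))
  out[!is.finite(out)] <- 0
  names(out) <- manifest_names("disorder")
  out
}
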