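# Shared numeric helpers: rank statistics, summary statistics over nuclei,
# polygon geometry, axial angles, von Mises sampling.

#' Rank-based AUC of a score against a binary label
#'
#' Computes the area under the ROC curve as the Mann-Whitney U statistic
#' divided by the number of positive-negative pairs; tied scores receive
#' average ranks, so each tied pair contributes 1/2.
#'
#' @param scores numeric vector of continuous scores (higher = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @return AUC as a fraction in [0, 1].
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# disorder statistic used throughout the architecture features:
# 1 - 1/(1 + sd/mean); 0 for a zero-variance set, -> 1 as cv -> Inf
disorder_stat <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(m) || m == 0) return(0)
  1 - 1 / (1 + s / abs(m))
}

minmax_ratio <- function(x) {
  mx <- max(x)
  if (mx == 0) return(1)  # all zero -> treat as perfectly homogeneous
  min(x) / mx
}

# {mean, sd, minmax, disorder} block used by the spatial-graph features
stat4 <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), minmax = minmax_ratio(x),
    disorder = disorder_stat(x))
}

# {mean, median, sd, minmax} block used by the shape features
stat_shape <- function(x) {
  c(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
    minmax = minmax_ratio(x))
}

# ---- polygon geometry (closed polygons as n x 2 matrices, not repeated) ----

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i <- seq_len(nrow(p)); j <- c(2:nrow(p), 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

polygon_perimeter <- function(p) {
  d <- p[c(2:nrow(p), 1L), , drop = FALSE] - p
  sum(sqrt(rowSums(d^2)))
}

# area-weighted centroid (shoelace); falls back to vertex mean for
# degenerate (near-zero-area) polygons
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i <- seq_len(nrow(p)); j <- c(2:nrow(p), 1L)
  cr <- x[i] * y[j] - x[j] * y[i]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(p))
  c(sum((x[i] + x[j]) * cr), sum((y[i] + y[j]) * cr)) / (6 * a)
}

# resample a closed polygon to n points equally spaced in arc length
resample_contour <- function(p, n = 128L) {
  q <- rbind(p, p[1L, , drop = FALSE])
  seg <- sqrt(rowSums((q[-1L, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  t_new <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(stats::approx(s, q[, 1], xout = t_new)$y,
        stats::approx(s, q[, 2], xout = t_new)$y)
}

point_in_polygon <- function(pt, poly) {
  # even-odd ray casting
  x <- pt[1]; y <- pt[2]
  px <- poly[, 1]; py <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1L))
  crosses <- ((py > y) != (py[j] > y)) &
    (x < (px[j] - px) * (y - py) / (py[j] - py) + px)
  sum(crosses) %% 2L == 1L
}

segments_intersect <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygons_overlap <- function(p, q) {
  # boundary crossing or full containment
  np <- nrow(p); nq <- nrow(q)
  ip <- c(2:np, 1L); iq <- c(2:nq, 1L)
  for (i in seq_len(np)) {
    for (j in seq_len(nq)) {
      if (segments_intersect(p[i, ], p[ip[i], ], q[j, ], q[iq[j], ]))
        return(TRUE)
    }
  }
  point_in_polygon(p[1L, ], q) || point_in_polygon(q[1L, ], p)
}

# ---- axial (orientation) angles, degrees on [0, 180) ----

fold_axial <- function(theta_deg) {
  a <- theta_deg %% 180
  # angles within numerical noise of 180 are axially 0
  a[a > 180 - 1e-9] <- 0
  a
}

# smallest axial difference between two orientations, in [0, 90]
axial_diff <- function(a, b) {
  d <- abs(fold_axial(a) - fold_axial(b))
  pmin(d, 180 - d)
}

# ---- von Mises sampling (Best & Fisher 1979 rejection scheme) ----

rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}
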