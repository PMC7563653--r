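# Per-nucleus contour shape measures and their cohort aggregation into the
# 100-feature shape block (25 measures x {mean, median, sd, min/max ratio}).

# Exact raw geometric moment m_pq of a simple polygon (Steger's closed
# form via Green's theorem); vertices as n x 2 matrix, not repeated.
polygon_moment <- function(p, pp, qq) {
  x1 <- p[, 1]; y1 <- p[, 2]
  nx <- c(2:nrow(p), 1L)
  x2 <- p[nx, 1]; y2 <- p[nx, 2]
  cross <- x1 * y2 - x2 * y1
  acc <- 0
  for (k in 0:pp) for (l in 0:qq) {
    acc <- acc + choose(k + l, l) * choose(pp + qq - k - l, qq - l) *
      sum(cross * x1^k * x2^(pp - k) * y1^l * y2^(qq - l))
  }
  acc / ((pp + qq + 2) * (pp + qq + 1) * choose(pp + qq, pp))
}

# the seven Hu rotation/translation/scale-invariant moments of a polygon;
# central moments up to order 3 by closed-form per-edge sums (equivalent to
# polygon_moment(), which the tests use as the independent oracle)
hu_moments <- function(p) {
  x1 <- p[, 1]; y1 <- p[, 2]
  nx <- c(2:nrow(p), 1L)
  x2 <- p[nx, 1]; y2 <- p[nx, 2]
  cross <- x1 * y2 - x2 * y1
  m00 <- sum(cross) / 2
  if (m00 < 0) { cross <- -cross; m00 <- -m00 }
  cx <- sum(cross * (x1 + x2)) / (6 * m00)
  cy <- sum(cross * (y1 + y2)) / (6 * m00)
  x1 <- x1 - cx; x2 <- x2 - cx; y1 <- y1 - cy; y2 <- y2 - cy
  cross <- x1 * y2 - x2 * y1        # cross products of centred coordinates
  if (sum(cross) < 0) cross <- -cross
  mu20 <- sum(cross * (x1^2 + x1 * x2 + x2^2)) / 12
  mu02 <- sum(cross * (y1^2 + y1 * y2 + y2^2)) / 12
  mu11 <- sum(cross * (2 * x1 * y1 + x1 * y2 + x2 * y1 + 2 * x2 * y2)) / 24
  mu30 <- sum(cross * (x1^3 + x1^2 * x2 + x1 * x2^2 + x2^3)) / 20
  mu03 <- sum(cross * (y1^3 + y1^2 * y2 + y1 * y2^2 + y2^3)) / 20
  mu21 <- sum(cross * (x1^2 * (3 * y1 + y2) + 2 * x1 * x2 * (y1 + y2) +
                         x2^2 * (y1 + 3 * y2))) / 60
  mu12 <- sum(cross * (y1^2 * (3 * x1 + x2) + 2 * y1 * y2 * (x1 + x2) +
                         y2^2 * (x1 + 3 * x2))) / 60
  n20 <- mu20 / m00^2; n02 <- mu02 / m00^2; n11 <- mu11 / m00^2
  s3 <- m00^2.5
  n30 <- mu30 / s3; n03 <- mu03 / s3; n21 <- mu21 / s3; n12 <- mu12 / s3
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# divider (Richardson compass) fractal dimension of the contour curve:
# walk the densified closed contour with rulers of decreasing length and
# regress log measured length on log ruler; D = 1 - slope. Depends only on
# inter-point distances, so it is exactly invariant under rigid motions
# (a grid-based box count is not) and scales out with the ruler choice.
fractal_dimension <- function(p, n_dense = 256L) {
  q <- resample_contour(p, n_dense)
  per <- polygon_perimeter(q)
  if (per <= 0) return(1)
  rulers <- per / c(8, 16, 32, 64)
  xs <- c(q[, 1], q[1L, 1]); ys <- c(q[, 2], q[1L, 2])
  n <- length(xs)
  lens <- vapply(rulers, function(eps) {
    eps2 <- eps * eps
    n_steps <- 0
    ax <- xs[1L]; ay <- ys[1L]
    i <- 2L
    repeat {
      # advance to the first vertex at Euclidean distance >= eps
      while (i <= n) {
        dx <- xs[i] - ax; dy <- ys[i] - ay
        if (dx * dx + dy * dy >= eps2) break
        i <- i + 1L
      }
      if (i > n) {
        # close the walk back to the start
        dx <- xs[1L] - ax; dy <- ys[1L] - ay
        n_steps <- n_steps + sqrt(dx * dx + dy * dy) / eps
        break
      }
      # interpolate on the segment crossing the eps sphere:
      # solve |a + t d - anchor| = eps for t in (0, 1]
      px <- xs[i - 1L]; py <- ys[i - 1L]
      dx <- xs[i] - px; dy <- ys[i] - py
      fx <- px - ax; fy <- py - ay
      aa <- dx * dx + dy * dy
      bb <- 2 * (fx * dx + fy * dy)
      cc <- fx * fx + fy * fy - eps2
      t_ <- (-bb + sqrt(max(0, bb * bb - 4 * aa * cc))) / (2 * aa)
      t_ <- min(1, max(0, t_))
      ax <- px + t_ * dx; ay <- py + t_ * dy
      n_steps <- n_steps + 1
    }
    n_steps * eps
  }, numeric(1))
  lx <- log(rulers)
  ly <- log(lens)
  1 - sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Shape measures of one nucleus contour
#'
#' Computes the 25 canonical per-nucleus shape measures on the contour
#' resampled to 128 equal-arc-length points: area and perimeter (microns),
#' max / mean / SD of the radial distance from the polygon centroid to the
#' contour, min/max radius ratio, local-roughness smoothness, box-counting
#' fractal dimension, the seven Hu invariant moments (computed exactly from
#' polygon moments), and ten normalized Fourier descriptors (harmonic
#' magnitudes scaled by the first harmonic, making them
#' similarity-invariant; descriptor 1 is identically 1).
#'
#' @param contour simple closed polygon, n x 2 matrix of pixel coordinates
#'   (>= 8 vertices).
#' @param mpp microns per pixel.
#' @return named numeric vector of length 25 (names from the manifest's
#'   shape-measure list).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- cbind(20 * cos(th), 20 * sin(th))  # radius 5 um at 0.25 mpp
#' measure_nucleus(circ, mpp = 0.25)[c("area", "perimeter")]
#' @export
measure_nucleus <- function(contour, mpp) {
  stopifnot(is.matrix(contour), ncol(contour) == 2)
  if (nrow(contour) < 8) stop("contour must have at least 8 vertices")
  p_um <- contour * mpp
  area <- polygon_area(p_um)
  if (area <= .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  rs <- resample_contour(p_um, 128L)
  ctr <- polygon_centroid(rs)
  r <- sqrt((rs[, 1] - ctr[1])^2 + (rs[, 2] - ctr[2])^2)
  n <- length(r)
  neigh_mean <- (r[c(n, 1:(n - 1))] + r[c(2:n, 1)]) / 2
  z <- complex(real = rs[, 1], imaginary = rs[, 2])
  fc <- stats::fft(z)
  denom <- Mod(fc[2])
  fd <- if (denom > 0) Mod(fc[2:11]) / denom else rep(0, 10)
  out <- c(
    polygon_area(rs), polygon_perimeter(rs),
    max(r), mean(r), stats::sd(r),
    min(r) / max(r),
    mean(abs(r - neigh_mean)),
    fractal_dimension(rs),
    hu_moments(rs),
    fd
  )
  names(out) <- SHAPE_MEASURES
  out
}

#' Aggregate per-nucleus shape measures into the 100-feature shape block
#'
#' For each of the 25 shape measures, emits the mean, median, sample SD and
#' min/max ratio over the nuclei of a region, in manifest order.
#'
#' @param measures matrix (nuclei x 25) from [measure_nucleus()], or a list
#'   of such vectors.
#' @return named numeric vector of length 100.
#' @export
aggregate_shape <- function(measures) {
  if (is.list(measures)) measures <- do.call(rbind, measures)
  stopifnot(is.matrix(measures), ncol(measures) == length(SHAPE_MEASURES))
  if (nrow(measures) < 2)
    stop("at least 2 nuclei are required (SD undefined otherwise)")
  out <- as.vector(apply(measures, 2, stat_shape))
  names(out) <- manifest_names("shape")
  out
}
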