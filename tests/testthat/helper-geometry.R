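# geometry helpers shared across test files

make_circle <- function(r_px, n = 128, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r_px * cos(th), center[2] + r_px * sin(th))
}

make_ellipse <- function(a_px, b_px, angle_rad = 0, n = 128,
                         center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a_px * cos(th); y <- b_px * sin(th)
  cbind(center[1] + x * cos(angle_rad) - y * sin(angle_rad),
        center[2] + x * sin(angle_rad) + y * cos(angle_rad))
}

rotate_points <- function(p, angle_rad, center = c(0, 0)) {
  q <- sweep(p, 2, center)
  R <- matrix(c(cos(angle_rad), sin(angle_rad),
                -sin(angle_rad), cos(angle_rad)), 2, 2)
  sweep(q %*% R, 2, center, "+")
}

# binary mask of a polygon over a W x H pixel grid (pixel centres).
# inclusive = TRUE also includes pixels whose centre lies on the polygon
# boundary, which makes the mask exactly symmetric under 90-degree
# rotations (even-odd tests break on-edge ties directionally)
rasterize_contour <- function(poly, W, H, inclusive = FALSE) {
  m <- matrix(FALSE, W, H)
  xr <- max(1, floor(min(poly[, 1]))):min(W, ceiling(max(poly[, 1])) + 1)
  yr <- max(1, floor(min(poly[, 2]))):min(H, ceiling(max(poly[, 2])) + 1)
  gx <- rep(xr - 0.5, times = length(yr))
  gy <- rep(yr - 0.5, each = length(xr))
  ins <- nucleoqh:::in_polygon_vec(gx, gy, poly)
  if (inclusive) {
    on_edge <- rep(FALSE, length(gx))
    nv <- nrow(poly)
    nxt <- c(2:nv, 1)
    for (e in seq_len(nv)) {
      a <- poly[e, ]; b <- poly[nxt[e], ]
      ab <- b - a
      len2 <- sum(ab^2)
      if (len2 == 0) next
      t_ <- pmin(1, pmax(0, ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2))
      d2 <- (a[1] + t_ * ab[1] - gx)^2 + (a[2] + t_ * ab[2] - gy)^2
      on_edge <- on_edge | d2 < 1e-18
    }
    ins <- ins | on_edge
  }
  m[cbind(gx[ins] + 0.5, gy[ins] + 0.5)] <- TRUE
  m
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# greedy one-to-one matching of detected points to truth within a radius
match_detections <- function(detected, truth, radius) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  pairs <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected[, 1] - truth[i, 1])^2 +
                (detected[, 2] - truth[i, 2])^2)
    j <- which(!used & d < radius)
    if (length(j)) {
      jj <- j[which.min(d[j])]
      used[jj] <- TRUE
      tp <- tp + 1L
      pairs <- rbind(pairs, c(i, jj))
    }
  }
  prec <- tp / nrow(detected)
  rec <- tp / nrow(truth)
  list(tp = tp, precision = prec, recall = rec,
       f1 = 2 * prec * rec / (prec + rec), pairs = pairs)
}

# brute-force Euclidean MST total length by enumerating all spanning trees
# (edge subsets of size n-1 that connect all vertices); n <= 7
brute_force_mst_length <- function(pts) {
  n <- nrow(pts)
  dmat <- as.matrix(dist(pts))
  edges <- t(combn(n, 2))
  wts <- dmat[edges]
  best <- Inf
  for (sel in combn(nrow(edges), n - 1, simplify = FALSE)) {
    # union-find connectivity check
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (acyclic && length(unique(vapply(1:n, find, integer(1)))) == 1)
      best <- min(best, sum(wts[sel]))
  }
  best
}

# brute-force pairwise-win AUC
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
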