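# Nucleus detection with a directional Gaussian filter bank and
# marker-controlled watershed segmentation on the hematoxylin channel.

# zero-mean anisotropic Gaussian kernel, elongated along angle theta
directional_gaussian_kernel <- function(sigma_major, sigma_minor, theta) {
  half <- ceiling(2.5 * sigma_major)
  g <- expand.grid(x = -half:half, y = -half:half)
  u <- g$x * cos(theta) + g$y * sin(theta)
  v <- -g$x * sin(theta) + g$y * cos(theta)
  k <- exp(-(u^2 / (2 * sigma_major^2) + v^2 / (2 * sigma_minor^2)))
  k <- matrix(k, 2 * half + 1, 2 * half + 1)
  k / sum(k) - 1 / length(k)
}

#' Detect nucleus seed points with a directional Gaussian filter bank
#'
#' Convolves the hematoxylin concentration map with a bank of zero-mean
#' anisotropic Gaussian kernels (`length(scales)` scales x
#' `n_orientations` orientations); the response map is the pixelwise
#' maximum over the bank. Seeds are local maxima of the response
#' (non-maximum suppression over a disc with radius equal to the smallest
#' scale) above an Otsu threshold computed within the ROI; seeds outside
#' the ROI are discarded.
#'
#' @param img normalized W x H x 3 array in [0, 1].
#' @param roi_mask logical or 0/1 W x H matrix; `NULL` = whole field.
#' @param mpp microns per pixel.
#' @param scales equivalent nuclear radii, microns (default 2.5/4/5.5,
#'   covering 2-6 micron nuclei).
#' @param n_orientations kernel orientations (default 6).
#' @param aspect minor/major sigma ratio of the kernels (default 0.6).
#' @return m x 2 matrix of seed pixel coordinates (0-based, x/y).
#' @export
detect_nuclei <- function(img, roi_mask = NULL, mpp,
                          scales = c(2.5, 4, 5.5), n_orientations = 6L,
                          aspect = 0.6) {
  W <- dim(img)[1]; H <- dim(img)[2]
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, W, H)
  roi_mask <- roi_mask > 0
  if (!any(roi_mask)) return(matrix(numeric(0), 0, 2))
  hmap <- hematoxylin_map(img)
  response <- matrix(-Inf, W, H)
  thetas <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  for (s_um in scales) {
    s_px <- s_um / mpp / 2   # sigma ~ radius / 2
    for (th in thetas) {
      k <- directional_gaussian_kernel(s_px, s_px * aspect, th)
      r <- as.matrix(EBImage::filter2(EBImage::Image(hmap), k))
      response <- pmax(response, r)
    }
  }
  response[!roi_mask] <- -Inf
  thr <- otsu_threshold(response[roi_mask & is.finite(response)])
  # candidates: strict 3x3 local maxima above the Otsu threshold
  nb_max <- matrix(-Inf, W, H)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(W, W + dx)
    xt <- max(1, 1 - dx):min(W, W - dx)
    ys <- max(1, 1 + dy):min(H, H + dy)
    yt <- max(1, 1 - dy):min(H, H - dy)
    nb_max[xt, yt] <- pmax(nb_max[xt, yt], response[xs, ys])
  }
  cand <- which(response > thr & response >= nb_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2))
  # greedy non-maximum suppression at the smallest filter scale
  nms_r <- min(scales) / mpp
  ord <- order(response[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) > nms_r^2)
      kept <- rbind(kept, p)
  }
  cbind(x = kept[, 1] - 0.5, y = kept[, 2] - 0.5)
}

otsu_threshold <- function(x, n_breaks = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * n_breaks) + 1L,
                     n_breaks), n_breaks)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_breaks))
  mu_t <- mu[n_breaks]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / n_breaks * diff(r)
}

#' Segment nuclei by marker-controlled watershed
#'
#' Uses the detected seeds as internal markers on the gradient of the
#' (smoothed) hematoxylin channel, constrained to an Otsu foreground mask
#' within the ROI; flooding assigns each foreground pixel to a marker
#' (seeded watershed region growing). Regions smaller than `min_area_um2`
#' or touching the image border are dropped. One contour per surviving
#' region; centroids are polygon centroids.
#'
#' @param img normalized W x H x 3 array in [0, 1].
#' @param seeds m x 2 seed matrix from [detect_nuclei()].
#' @param roi_mask logical W x H matrix or `NULL`.
#' @param mpp microns per pixel.
#' @param min_area_um2 minimum nucleus area, square microns (default 8).
#' @return a [nucleus_set()] (possibly empty).
#' @export
segment_nuclei <- function(img, seeds, roi_mask = NULL, mpp,
                           min_area_um2 = 8) {
  W <- dim(img)[1]; H <- dim(img)[2]
  empty <- nucleus_set(list(), matrix(numeric(0), 0, 2), mpp)
  if (is.null(seeds) || nrow(seeds) == 0) return(empty)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, W, H)
  roi_mask <- roi_mask > 0
  hmap <- as.matrix(EBImage::gblur(EBImage::Image(hematoxylin_map(img)),
                                   sigma = 1))
  fg <- hmap > otsu_threshold(hmap[roi_mask]) & roi_mask
  # gradient-magnitude relief (Sobel)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(hmap), sx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(hmap), t(sx)))
  relief <- sqrt(gx^2 + gy^2)
  marker <- matrix(0L, W, H)
  sx_i <- pmin(pmax(round(seeds[, 1] + 0.5), 1L), W)
  sy_i <- pmin(pmax(round(seeds[, 2] + 0.5), 1L), H)
  for (i in seq_len(nrow(seeds))) marker[sx_i[i], sy_i[i]] <- i
  lab <- EBImage::propagate(EBImage::Image(relief),
                            EBImage::Image(marker), mask = fg)
  lab <- as.matrix(lab)
  min_px <- min_area_um2 / mpp^2
  contours <- list(); centroids <- NULL
  oc <- EBImage::ocontour(EBImage::Image(lab))
  for (i in seq_along(oc)) {
    reg <- oc[[i]]
    if (is.null(reg) || nrow(reg) < 8) next
    npx <- sum(lab == i)
    if (npx < min_px) next
    pix <- which(lab == i, arr.ind = TRUE)
    if (any(pix[, 1] %in% c(1L, W)) || any(pix[, 2] %in% c(1L, H))) next
    # ocontour returns 0-based pixel indices; shift to pixel centres so
    # contour coordinates share the centroid/feature convention
    contours[[length(contours) + 1L]] <- reg + 0.5
  }
  if (length(contours) == 0) return(empty)
  nucleus_set(contours, mpp = mpp)
}

#' Run detection and segmentation on one image
#'
#' @param img RGB array in [0, 1].
#' @param roi_mask logical mask or `NULL`.
#' @param mpp microns per pixel.
#' @param normalize normalize stains to the default template first.
#' @param ... passed to [detect_nuclei()].
#' @return a [nucleus_set()].
#' @export
segment_image <- function(img, roi_mask = NULL, mpp, normalize = TRUE, ...) {
  if (normalize) img <- normalize_stain(img)
  seeds <- detect_nuclei(img, roi_mask, mpp, ...)
  segment_nuclei(img, seeds, roi_mask, mpp)
}
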