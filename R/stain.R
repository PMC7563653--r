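# H&E stain estimation and normalization in optical density space.
# Stain vectors are estimated by SVD (plane of the two stains, robust
# angular extremes), concentrations by least squares, and images are
# re-rendered with template vectors after scaling each stain's
# 99th-percentile ("maximum") optical density to the template's.

OD_EPS <- 1 / 255

rgb_to_od <- function(img) {
  # img: W x H x 3 in [0,1]
  -log(pmax(img, OD_EPS))
}

od_to_rgb <- function(od) pmin(1, pmax(0, exp(-od)))

#' Reference H&E stain template
#'
#' Unit-norm optical-density direction vectors for hematoxylin and eosin
#' (standard published values) plus per-stain maximum (99th percentile)
#' optical-density scales.
#'
#' @param max_od length-2 positive vector of per-stain OD scales.
#' @return object of class `stain_template` with `stain_matrix` (3 x 2,
#'   columns hematoxylin, eosin, unit norm) and `max_od`.
#' @export
stain_template <- function(max_od = c(1.2, 0.6)) {
  stopifnot(length(max_od) == 2, all(max_od > 0))
  V <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  structure(list(stain_matrix = V, max_od = max_od),
            class = "stain_template")
}

#' Estimate the stain matrix of an H&E image
#'
#' SVD-based estimation: tissue pixels (OD magnitude above `beta`) are
#' projected onto the plane of the two leading right singular vectors of
#' their OD cloud; the stain directions are the robust angular extremes
#' (percentiles `alpha` and `100 - alpha`) of the projections. The vector
#' with the larger blue-channel OD share is labeled hematoxylin.
#'
#' @param img W x H x 3 array in [0, 1].
#' @param beta tissue OD threshold (default 0.15).
#' @param alpha robust angle percentile (default 1).
#' @return `stain_template` estimated from the image, or `NULL` when the
#'   estimate is degenerate (blank or effectively single-stain image).
#' @export
estimate_stains <- function(img, beta = 0.15, alpha = 1) {
  od <- rgb_to_od(img)
  M <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
             as.vector(od[, , 3]))
  keep <- sqrt(rowSums(M^2)) > beta
  if (sum(keep) < 100) return(NULL)
  M <- M[keep, , drop = FALSE]
  sv <- svd(M, nu = 0, nv = 3)
  if (sv$d[2] < 1e-3 * sv$d[1]) return(NULL)  # single-stain image
  V2 <- sv$v[, 1:2]
  # orient the plane so projections have positive first coordinate
  if (mean(M %*% V2[, 1]) < 0) V2[, 1] <- -V2[, 1]
  if (stats::median(M %*% V2[, 2]) < 0) V2[, 2] <- -V2[, 2]
  proj <- M %*% V2
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  dirs <- vapply(qs, function(a) V2 %*% c(cos(a), sin(a)), numeric(3))
  dirs <- apply(dirs, 2, function(v) { v <- v * sign(sum(v)); v / sqrt(sum(v^2)) })
  # hematoxylin absorbs red strongly: larger red OD share
  h_first <- dirs[1, 1] / sum(abs(dirs[, 1])) >=
    dirs[1, 2] / sum(abs(dirs[, 2]))
  V <- if (h_first) dirs else dirs[, 2:1]
  colnames(V) <- c("h", "e")
  conc <- stain_concentrations(od, V)
  max_od <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE)
  if (any(max_od <= 0)) return(NULL)
  structure(list(stain_matrix = V, max_od = max_od),
            class = "stain_template")
}

# per-pixel stain concentrations by least squares in OD space, clamped >= 0
stain_concentrations <- function(od, V) {
  M <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
             as.vector(od[, , 3]))
  C <- solve(crossprod(V), crossprod(V, M))
  C[C < 0] <- 0
  t(C)
}

#' Normalize an H&E image to a stain template
#'
#' Estimates the image's stain vectors, maps each pixel to stain
#' concentrations, rescales each stain so its 99th-percentile OD matches
#' the template, and re-renders with the template's stain vectors.
#' Near-white background pixels carry ~zero concentration and remain
#' near-white. Blank or single-stain images signal a degenerate stain
#' estimate: the input is returned unchanged with a warning.
#'
#' @param img W x H x 3 array in [0, 1].
#' @param template target [stain_template()].
#' @return normalized image, same shape and range.
#' @export
normalize_stain <- function(img, template = stain_template()) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  est <- estimate_stains(img)
  if (is.null(est)) {
    warning("degenerate stain estimate (blank or single-stain image); ",
            "returning input unchanged")
    return(img)
  }
  od <- rgb_to_od(img)
  conc <- stain_concentrations(od, est$stain_matrix)
  conc <- sweep(conc, 2, template$max_od / est$max_od, "*")
  od_new <- conc %*% t(template$stain_matrix)
  out <- img
  for (ch in 1:3)
    out[, , ch] <- matrix(od_to_rgb(od_new[, ch]), dim(img)[1], dim(img)[2])
  out
}

# hematoxylin concentration map of an image (template-direction projection)
hematoxylin_map <- function(img, template = stain_template()) {
  od <- rgb_to_od(img)
  conc <- stain_concentrations(od, template$stain_matrix)
  matrix(conc[, 1], dim(img)[1], dim(img)[2])
}
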