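# synthetic nuclei-field generator: determinism, geometry contracts,
# degenerate regimes, and the tunable-disorder monotonicity trends

test_that("generator is deterministic and respects geometric contracts", {
  cfg <- synthetic_config(n_nuclei = 40, seed = 7)
  f1 <- generate_nucleus_field(cfg)
  f2 <- generate_nucleus_field(cfg)
  expect_identical(f1, f2)

  gt <- f1$gt
  expect_length(gt$contours, 40)
  expect_equal(nrow(gt$centroids), 40)
  expect_true(all(gt$orientations >= 0 & gt$orientations < 180))
  # every centroid lies inside its contour
  for (i in seq_along(gt$contours))
    expect_true(nucleoqh:::point_in_polygon(gt$centroids[i, ],
                                            gt$contours[[i]]))
  # no two contours intersect (check all close pairs)
  for (i in 1:39) for (j in (i + 1):40) {
    d <- sqrt(sum((gt$centroids[i, ] - gt$centroids[j, ])^2))
    if (d < 80)
      expect_false(nucleoqh:::polygons_overlap(gt$contours[[i]],
                                               gt$contours[[j]]))
  }
  # recovered orientation matches the generating angle within 2 degrees
  # (exact ellipses; boundary perturbation adds its own axis noise)
  fe <- generate_nucleus_field(synthetic_config(n_nuclei = 30, seed = 8,
                                                boundary_irregularity = 0))
  est <- vapply(fe$gt$contours,
                function(p) as.numeric(nucleus_orientation(p)), numeric(1))
  expect_true(all(nucleoqh:::axial_diff(est, fe$gt$orientations) < 2))
})

test_that("single-nucleus render places one dark blob at the field centre", {
  f <- generate_nucleus_field(synthetic_config(n_nuclei = 1, seed = 3,
                                               field_size = c(128, 128),
                                               jitter_sigma = 0,
                                               render = TRUE))
  expect_length(f$gt$contours, 1)
  expect_equal(dim(f$image), c(128, 128, 3))
  ctr <- nucleoqh:::polygon_centroid(f$gt$contours[[1]])
  expect_lt(sqrt(sum((ctr - c(64, 64))^2)), 2)
  # nucleus interior darker than background in every channel
  inside <- rasterize_contour(f$gt$contours[[1]], 128, 128)
  for (ch in 1:3)
    expect_lt(mean(f$image[, , ch][inside]), mean(f$image[, , ch][!inside]))
})

test_that("zero-variance config yields a perfectly regular field", {
  cfg <- synthetic_config(n_nuclei = 60, seed = 5, jitter_sigma = 0,
                          axis_sd = 0, eccentricity_sd = 0, kappa = Inf,
                          boundary_irregularity = 0)
  f <- generate_nucleus_field(cfg)
  g <- build_graphs(f$gt$centroids, cfg$mpp)
  areas <- g$voronoi$area[g$voronoi$interior]
  expect_gt(length(areas), 5)
  expect_lt(sd(areas) / mean(areas), 1e-6)  # tessellation vertex round-off
  # identical aligned ellipses -> orientation disorder contrast 0
  ors <- vapply(f$gt$contours, function(p) as.numeric(nucleus_orientation(p)),
                numeric(1))
  sg <- build_subgraphs(f$gt$centroids, cfg$mpp)
  d <- disorder_features(ors, sg)
  expect_equal(unname(d["orient_contrast_energy_mean"]), 0)
  expect_equal(unname(d["orient_entropy_mean"]), 0)
  expect_equal(unname(d["orient_energy_mean"]), 1)
})

test_that("over-dense requests fail with a clear error", {
  expect_error(
    generate_nucleus_field(synthetic_config(n_nuclei = 500,
                                            field_size = c(128, 128),
                                            seed = 1)),
    "over-dense|too small")
})

test_that("disorder knobs are monotone in expectation (Monte Carlo)", {
  seeds <- 1:10
  stat_for <- function(cfg, fun) {
    vapply(seeds, function(s) {
      cfg$seed <- s
      fun(generate_nucleus_field(cfg)$gt)
    }, numeric(1))
  }
  vor_sd <- function(gt) {
    g <- build_graphs(gt$centroids, gt$mpp)
    sd(g$voronoi$area[g$voronoi$interior])
  }
  base <- synthetic_config(n_nuclei = 60)
  hi <- base; hi$jitter_sigma <- 2 * base$jitter_sigma
  expect_gt(mean(stat_for(hi, vor_sd)), mean(stat_for(base, vor_sd)))

  ent <- function(gt) {
    ors <- gt$orientations
    sg <- build_subgraphs(gt$centroids, gt$mpp)
    disorder_features(ors, sg)["orient_entropy_mean"]
  }
  lo_kappa <- base; lo_kappa$kappa <- 0.3
  hi_kappa <- base; hi_kappa$kappa <- 6
  expect_gt(mean(stat_for(lo_kappa, ent)), mean(stat_for(hi_kappa, ent)))

  rr_sd <- function(gt) {
    m <- vapply(gt$contours, function(p)
      measure_nucleus(p, gt$mpp)["radius_ratio"], numeric(1))
    sd(m)
  }
  hi_ecc <- base; hi_ecc$eccentricity_sd <- 0.16
  expect_gt(mean(stat_for(hi_ecc, rr_sd)), mean(stat_for(base, rr_sd)))
})

test_that("cohort generation is balanced, deterministic, and class effects show", {
  cfgs <- progression_configs(n_nuclei = 60)
  co <- generate_cohort(5, cfgs, seed = 11)
  expect_length(co, 10)
  expect_equal(sum(vapply(co, `[[`, character(1), "label") == "progressor"),
               5)
  co2 <- generate_cohort(5, cfgs, seed = 11)
  expect_identical(co, co2)

  # doubled jitter strictly raises per-patient Voronoi-area SD
  # (one-sided Wilcoxon across the cohort)
  base <- synthetic_config(n_nuclei = 60)
  hij <- base; hij$jitter_sigma <- 2 * base$jitter_sigma
  co3 <- generate_cohort(30, list(base, hij), seed = 21)
  vsd <- vapply(co3, function(p) {
    g <- build_graphs(p$gt$centroids, p$gt$mpp)
    sd(g$voronoi$area[g$voronoi$interior])
  }, numeric(1))
  lab <- vapply(co3, `[[`, character(1), "label") == "progressor"
  expect_lt(wilcox.test(vsd[lab], vsd[!lab], alternative = "greater")$p.value,
            0.01)
})

test_that("ground-truth JSON round-trips", {
  f <- cached_field(20, 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(f$gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$contours, lapply(f$gt$contours, unname))
  expect_equal(back$centroids, unname(f$gt$centroids))
  expect_equal(back$orientations, f$gt$orientations)
  expect_equal(back$mpp, f$gt$mpp)
})
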