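# classifier construction, cross-validation, operating point, evaluation

test_that("AUC equals brute-force pairwise wins and the pROC oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)  # ties likely
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(auc_rank(scores, labels), brute_force_auc(scores, labels))
  }
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2)
  labels <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("regularized discriminants agree with MASS on well-conditioned data", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, 0.5) == 1
  X[y, ] <- X[y, ] + 1
  fit_l <- nucleoqh:::fit_discriminant(X, y, "LDA", ridge = 1e-8)
  fit_q <- nucleoqh:::fit_discriminant(X, y, "QDA", ridge = 1e-8)
  sc_l <- nucleoqh:::predict_discriminant(fit_l, X)
  sc_q <- nucleoqh:::predict_discriminant(fit_q, X)
  ml <- MASS::lda(X, grouping = y)
  mq <- MASS::qda(X, grouping = y)
  expect_equal(sc_l, unname(predict(ml, X)$posterior[, "TRUE"]),
               tolerance = 1e-6)
  expect_equal(sc_q, unname(predict(mq, X)$posterior[, "TRUE"]),
               tolerance = 1e-6)
})

test_that("cross-validation is exact on a perfect separator and chance on noise", {
  co <- make_feature_cohort(15, seed = 2)
  nm <- feature_manifest()$name
  co[[nm[1]]] <- as.numeric(co$label == "progressor")
  cv <- cross_validate(co, nm[1:3], c("LDA", "RF"), folds = 3,
                       iterations = 10, seed = 4)
  expect_s3_class(cv, "qh_cv")
  expect_equal(cv$summary$auc_mean, c(1, 1))
  expect_equal(cv$summary$auc_sd, c(0, 0))

  # pure-noise features: chance-level AUC; averaging over several fresh
  # null cohorts (iterations on one cohort share its sampling noise)
  null_auc <- vapply(1:5, function(s) {
    co2 <- make_feature_cohort(15, seed = 300 + s)
    cross_validate(co2, nm[1:6], "LDA", folds = 3, iterations = 20,
                   seed = s)$summary$auc_mean
  }, numeric(1))
  expect_gt(mean(null_auc), 0.4)
  expect_lt(mean(null_auc), 0.6)
})

test_that("stratified folds require divisible class counts", {
  co <- make_feature_cohort(10, seed = 6)
  expect_error(cross_validate(co, feature_manifest()$name[1:3], "LDA",
                              folds = 3, iterations = 2, seed = 1),
               "stratify")
})

test_that("operating point maximizes Youden's J with deterministic ties", {
  thr <- choose_operating_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(thr, 0.5)
  # completely overlapping scores: first (lowest) candidate wins
  s <- c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(choose_operating_point(s, y), 0.4)
  expect_error(choose_operating_point(c(0.2, 0.4), c(1, 1)), "both classes")
  # brute-force midpoint search oracle
  set.seed(12)
  sc <- runif(20); yy <- rbinom(20, 1, 0.5)
  if (any(yy == 1) && any(yy == 0)) {
    u <- sort(unique(sc))
    cand <- (u[-1] + u[-length(u)]) / 2
    jfun <- function(t) {
      pred <- sc >= t
      sum(pred & yy == 1) / sum(yy) + sum(!pred & yy == 0) / sum(!yy) - 1
    }
    best <- cand[which.max(vapply(cand, jfun, numeric(1)))]
    expect_equal(choose_operating_point(sc, yy), best)
  }
})

test_that("confusion metric identities hold for random matrices", {
  set.seed(9)
  for (rep in 1:50) {
    cts <- sample(1:100, 4)
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])$fractions
    tn <- cts[1]; fp <- cts[2]; fn <- cts[3]; tp <- cts[4]
    expect_equal(unname(m["sensitivity"]), tp / (tp + fn))
    expect_equal(unname(m["specificity"]), tn / (tn + fp))
    expect_equal(unname(m["ppv"]), tp / (tp + fp))
    expect_equal(unname(m["npv"]), tn / (tn + fn))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("evaluation reports AUC antisymmetry and perfect prediction", {
  co <- make_feature_cohort(10, shift = 3,
                            signal_features = feature_manifest()$name[1:6],
                            seed = 13)
  mod <- fit_model(co, feature_manifest()$name[1:6], "RF", seed = 1)
  ev <- evaluate(mod, co, threshold = 0.5)
  expect_s3_class(ev, "qh_eval")
  y <- co$label == "progressor"
  expect_equal(unname(ev$counts["tn"] + ev$counts["fp"]), sum(!y))
  expect_equal(unname(ev$counts["fn"] + ev$counts["tp"]), sum(y))
  # flipping scores flips the AUC
  expect_equal(auc_rank(1 - ev$scores, y), 1 - ev$auc)
  # resubstitution on a huge effect: all correct -> all metrics 100%
  expect_equal(unname(ev$percent[c("sensitivity", "specificity",
                                   "ppv", "npv")]),
               c(100, 100, 100, 100))
})

test_that("feature mismatch on prediction is an error", {
  co <- make_feature_cohort(5, seed = 14)
  mod <- fit_model(co, feature_manifest()$name[1:3], "LDA")
  bad <- nucleoqh:::cohort_matrix(co)[, 10:12]
  expect_error(predict(mod, bad), "feature mismatch")
})

test_that("univariate AUC matches pair enumeration on the worked set", {
  # pos {3, 5}, neg {1, 4}: pairs (3>1), (3<4), (5>1), (5>4) -> 3/4
  v <- c(3, 5, 1, 4)
  y <- c(1, 1, 0, 0)
  expect_equal(univariate_auc(v, y), 0.75)
  expect_equal(univariate_auc(v, y), brute_force_auc(v, y))
  expect_equal(univariate_auc(c(1, 1, 0, 0), y), 1)
  expect_equal(univariate_auc(c(0, 0, 1, 1), y), 0)
  expect_warning(a <- univariate_auc(c(2, 2, 2, 2), y), "degenerate")
  expect_equal(a, 0.5)
})

test_that("random forest fits are reproducible under a fixed seed", {
  co <- make_feature_cohort(15, shift = 1,
                            signal_features = feature_manifest()$name[1:6],
                            seed = 15)
  m1 <- fit_model(co, feature_manifest()$name[1:6], "RF", seed = 42)
  m2 <- fit_model(co, feature_manifest()$name[1:6], "RF", seed = 42)
  expect_equal(predict(m1, co), predict(m2, co))
})
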