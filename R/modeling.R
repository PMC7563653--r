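# Classifier construction and evaluation: ridge-regularized Gaussian
# discriminants (LDA/QDA), random forest, stratified k-fold cross-validation
# repeated over iterations, Youden operating-point selection, and
# confusion-matrix reporting. The progressor class is positive throughout
# and scores are the progressor posterior probability.

# ---- ridge-regularized Gaussian discriminant analysis -----------------
# Class covariances on 15-patient halves are near-singular for 6 features;
# a small ridge (epsilon on the diagonal) keeps both LDA and QDA defined.

fit_discriminant <- function(X, y, type = c("LDA", "QDA"), ridge = 1e-4) {
  type <- match.arg(type)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y), any(y), any(!y))
  p <- ncol(X)
  classes <- list(pos = X[y, , drop = FALSE], neg = X[!y, , drop = FALSE])
  mu <- lapply(classes, colMeans)
  prior <- c(pos = mean(y), neg = mean(!y))
  covs <- lapply(classes, function(m) {
    S <- if (nrow(m) > 1) stats::cov(m) else matrix(0, p, p)
    S + diag(ridge, p)
  })
  if (type == "LDA") {
    n1 <- sum(y); n0 <- sum(!y)
    Sp <- ((n1 - 1) * (covs$pos - diag(ridge, p)) +
             (n0 - 1) * (covs$neg - diag(ridge, p))) / (n1 + n0 - 2) +
      diag(ridge, p)
    covs <- list(pos = Sp, neg = Sp)
  }
  structure(list(type = type, mu = mu, covs = covs, prior = prior,
                 ridge = ridge, features = colnames(X)),
            class = "qh_discriminant")
}

predict_discriminant <- function(fit, X) {
  stopifnot(inherits(fit, "qh_discriminant"))
  if (!is.null(fit$features) && !is.null(colnames(X)))
    X <- X[, fit$features, drop = FALSE]
  logd <- function(cl) {
    S <- fit$covs[[cl]]
    ch <- chol(S)
    d <- sweep(X, 2, fit$mu[[cl]])
    z <- backsolve(ch, t(d), transpose = TRUE)
    -sum(log(diag(ch))) - 0.5 * colSums(z^2) + log(fit$prior[[cl]])
  }
  lp <- logd("pos"); ln <- logd("neg")
  m <- pmax(lp, ln)
  exp(lp - m) / (exp(lp - m) + exp(ln - m))
}

#' Fit a progression classifier on selected features
#'
#' @param cohort `cohort_table` training data.
#' @param features character vector of feature names (typically the six
#'   from [identify_features()]).
#' @param classifier `"LDA"`, `"QDA"` (ridge-regularized Gaussian
#'   discriminants) or `"RF"` (random forest, 100 trees, square-root
#'   feature subsampling).
#' @param seed seed for the stochastic RF fit (ignored by LDA/QDA).
#' @param ridge diagonal regularization for LDA/QDA covariances.
#' @return object of class `qh_model`.
#' @export
fit_model <- function(cohort, features, classifier = c("RF", "LDA", "QDA"),
                      seed = 1L, ridge = 1e-4) {
  classifier <- match.arg(classifier)
  X <- cohort_matrix(cohort)[, features, drop = FALSE]
  y <- cohort_labels(cohort)
  fit <- if (classifier == "RF") {
    set.seed(seed)
    randomForest::randomForest(
      x = X, y = factor(y, levels = c(FALSE, TRUE),
                        labels = c("non-progressor", "progressor")),
      ntree = 100, mtry = max(1L, floor(sqrt(ncol(X)))))
  } else {
    fit_discriminant(X, y, classifier, ridge)
  }
  structure(list(classifier = classifier, fit = fit, features = features,
                 seed = seed),
            class = "qh_model")
}

#' Progressor scores from a fitted model
#'
#' @param object a `qh_model`.
#' @param newdata `cohort_table` (or feature matrix with named columns).
#' @param ... unused.
#' @return numeric vector of progressor-class scores in [0, 1].
#' @export
predict.qh_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "data.frame"))
    cohort_matrix(newdata) else as.matrix(newdata)
  missing <- setdiff(object$features, colnames(X))
  if (length(missing))
    stop("feature mismatch: model features absent from new data: ",
         paste(missing, collapse = ", "))
  X <- X[, object$features, drop = FALSE]
  if (object$classifier == "RF")
    unname(stats::predict(object$fit, X, type = "prob")[, "progressor"])
  else
    unname(predict_discriminant(object$fit, X))
}

#' @export
print.qh_model <- function(x, ...) {
  cat(sprintf("<qh_model> %s on %d features: %s\n", x$classifier,
              length(x$features), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each requested classifier, runs `iterations` independent stratified
#' `folds`-fold partitions of the cohort; per iteration the out-of-fold
#' scores are pooled to compute one AUC (and accuracy / sensitivity /
#' specificity at a 0.5 score threshold). Means and SDs over iterations are
#' reported and the model with the highest mean AUC is flagged best.
#'
#' @param d1 balanced `cohort_table`.
#' @param features feature names used by every model.
#' @param classifiers character vector among `"LDA"`, `"QDA"`, `"RF"`.
#' @param folds number of folds (default 3); every fold must contain the
#'   same number of patients of each class, so the per-class count must be
#'   divisible by `folds`.
#' @param iterations repetitions (default 100).
#' @param seed master seed.
#' @return object of class `qh_cv`: `summary` data.frame (mean/SD of AUC,
#'   ACC, SENS, SPEC per model), `best` (classifier name), and the pooled
#'   out-of-fold scores of the best model's last iteration.
#' @export
cross_validate <- function(d1, features, classifiers = c("LDA", "QDA", "RF"),
                           folds = 3L, iterations = 100L, seed = 1L) {
  y <- cohort_labels(d1)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos %% folds != 0 || n_neg %% folds != 0)
    stop(sprintf(
      "cannot stratify %d progressors / %d non-progressors into %d equal folds",
      n_pos, n_neg, folds))
  X <- cohort_matrix(d1)[, features, drop = FALSE]
  res <- list()
  oof_best <- NULL
  for (clf in classifiers) {
    set.seed(seed)
    m <- matrix(NA_real_, iterations, 4,
                dimnames = list(NULL, c("AUC", "ACC", "SENS", "SPEC")))
    for (it in seq_len(iterations)) {
      fold <- integer(length(y))
      fold[y] <- sample(rep(seq_len(folds), n_pos / folds))
      fold[!y] <- sample(rep(seq_len(folds), n_neg / folds))
      scores <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- if (clf == "RF") {
          randomForest::randomForest(
            x = X[tr, , drop = FALSE],
            y = factor(y[tr], levels = c(FALSE, TRUE)), ntree = 100,
            mtry = max(1L, floor(sqrt(ncol(X)))))
        } else {
          fit_discriminant(X[tr, , drop = FALSE], y[tr], clf)
        }
        scores[!tr] <- if (clf == "RF")
          stats::predict(fit, X[!tr, , drop = FALSE],
                         type = "prob")[, "TRUE"]
        else predict_discriminant(fit, X[!tr, , drop = FALSE])
      }
      pred <- scores >= 0.5
      m[it, ] <- c(auc_rank(scores, y),
                   mean(pred == y),
                   sum(pred & y) / n_pos,
                   sum(!pred & !y) / n_neg)
      if (it == iterations) last_oof <- scores
    }
    res[[clf]] <- list(stats = m, oof = last_oof)
  }
  summ <- do.call(rbind, lapply(names(res), function(clf) {
    m <- res[[clf]]$stats
    data.frame(model = clf,
               auc_mean = mean(m[, "AUC"]), auc_sd = stats::sd(m[, "AUC"]),
               acc_mean = mean(m[, "ACC"]), acc_sd = stats::sd(m[, "ACC"]),
               sens_mean = mean(m[, "SENS"]), sens_sd = stats::sd(m[, "SENS"]),
               spec_mean = mean(m[, "SPEC"]), spec_sd = stats::sd(m[, "SPEC"]),
               stringsAsFactors = FALSE)
  }))
  best <- summ$model[which.max(summ$auc_mean)]
  structure(list(summary = summ, best = best,
                 best_oof_scores = res[[best]]$oof, labels = y,
                 features = features, folds = folds,
                 iterations = iterations),
            class = "qh_cv")
}

#' @export
print.qh_cv <- function(x, ...) {
  cat(sprintf("<qh_cv> %d-fold x %d iterations on %d features\n",
              x$folds, x$iterations, length(x$features)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s AUC %.2f +/- %.2f  ACC %.2f +/- %.2f%s\n",
                s$model[i], s$auc_mean[i], s$auc_sd[i], s$acc_mean[i],
                s$acc_sd[i], if (s$model[i] == x$best) "  <- best" else ""))
  invisible(x)
}

#' Youden operating point
#'
#' Chooses the score threshold maximizing Youden's J statistic
#' (sensitivity + specificity - 1) with the decision rule
#' `score >= threshold`. Candidate thresholds are the midpoints between
#' consecutive distinct scores; ties take the lowest threshold.
#'
#' @param scores continuous scores.
#' @param labels binary labels (positive = progressor).
#' @return threshold value.
#' @export
choose_operating_point <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes are required to choose an operating point")
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels) / sum(labels) + sum(!pred & !labels) / sum(!labels) - 1
  }, numeric(1))
  cand[which.max(j)]  # which.max returns the first (lowest) maximizer
}

#' Confusion-matrix metrics
#'
#' @param tn,fp,fn,tp confusion counts (positive = progressor).
#' @return list with raw fractions (`sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`) and `percent`, the same values as
#'   nearest-integer percentages.
#' @examples
#' confusion_metrics(tn = 22, fp = 14, fn = 28, tp = 67)$percent
#' @export
confusion_metrics <- function(tn, fp, fn, tp) {
  fr <- c(sensitivity = tp / (tp + fn),
          specificity = tn / (tn + fp),
          ppv = tp / (tp + fp),
          npv = tn / (tn + fn),
          accuracy = (tp + tn) / (tn + fp + fn + tp))
  list(fractions = fr, percent = round(100 * fr),
       counts = c(tn = tn, fp = fp, fn = fn, tp = tp))
}

#' Evaluate a fitted model on a held-out cohort
#'
#' Computes the rank-based AUC of the model's continuous scores and the
#' confusion matrix and derived metrics at a fixed operating point chosen
#' beforehand on training data.
#'
#' @param model a `qh_model` trained on disjoint patients.
#' @param test held-out `cohort_table`.
#' @param threshold operating point; predicted progressor iff
#'   `score >= threshold`.
#' @return object of class `qh_eval` with `auc`, `threshold`, `counts`,
#'   `metrics` (fractions), `percent` (nearest-integer percentages) and the
#'   per-patient `scores`.
#' @export
evaluate <- function(model, test, threshold) {
  scores <- predict(model, test)
  y <- cohort_labels(test)
  pred <- scores >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  cm <- confusion_metrics(tn, fp, fn, tp)
  structure(list(auc = auc_rank(scores, y), threshold = threshold,
                 counts = cm$counts, metrics = cm$fractions,
                 percent = cm$percent, scores = scores, labels = y),
            class = "qh_eval")
}

#' @export
print.qh_eval <- function(x, ...) {
  cat(sprintf("<qh_eval> AUC %.3f at operating point %.3f\n", x$auc,
              x$threshold))
  cat(sprintf("  TN %d  FP %d  FN %d  TP %d\n", x$counts["tn"],
              x$counts["fp"], x$counts["fn"], x$counts["tp"]))
  cat(sprintf("  sens %d%%  spec %d%%  PPV %d%%  NPV %d%%  acc %d%%\n",
              x$percent["sensitivity"], x$percent["specificity"],
              x$percent["ppv"], x$percent["npv"], x$percent["accuracy"]))
  invisible(x)
}

#' Univariate AUC of a raw measurement
#'
#' Rank-based AUC using the measurement itself as the score (ties receive
#' average ranks). Used for clinical comparator markers such as pro-PSA or
#' Gleason sum.
#'
#' @param values numeric measurements.
#' @param labels binary labels (positive = progressor).
#' @return AUC fraction; a constant measurement returns 0.5 with a warning.
#' @export
univariate_auc <- function(values, labels) {
  if (length(unique(values)) == 1) {
    warning("degenerate measurement: all values identical; AUC = 0.5")
    return(0.5)
  }
  auc_rank(values, labels)
}
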