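# binary AUROC with fixed orientation (higher score -> positive class)
.binary_auc <- function(y_bin, score) {
  if (length(unique(y_bin)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y_bin, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

# average precision (step-wise interpolation of the PR curve)
.average_precision <- function(y_bin, score) {
  npos <- sum(y_bin)
  if (npos == 0L || npos == length(y_bin)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  rel <- y_bin[ord]
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec * rel) / npos
}

#' Class-support-weighted one-vs-rest AUCROC
#'
#' @param y Integer labels 1--4.
#' @param prob n x 4 probability matrix.
#' @return Weighted mean of per-class one-vs-rest AUCs.
#' @export
weighted_ovr_auc <- function(y, prob) {
  w <- tabulate(y, 4) / length(y)
  aucs <- vapply(1:4, function(cc) {
    if (w[cc] == 0) return(NA_real_)
    .binary_auc(y == cc, prob[, cc])
  }, 1)
  sum(w * aucs, na.rm = TRUE) / sum(w[!is.na(aucs)])
}

# 2x2 / KxK Cohen kappa from a square confusion table
.kappa <- function(tab) {
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  if (pe == 1) return(0)
  e1071::classAgreement(tab)$kappa
}

#' Seven-metric multiclass performance report
#'
#' Computes the class-support-weighted one-vs-rest metric panel: AUCROC,
#' AUPRC (average precision), accuracy (equals weighted recall), balanced
#' accuracy, precision, F1 and Cohen's kappa, plus a per-class one-vs-rest
#' breakdown (binary accuracy, balanced accuracy, PPV, F1, kappa, FPR, FNR).
#' AUC metrics require probabilities and are `NA` without them; classes
#' absent from the truth get `NA` AUCs rather than zeros.
#'
#' @param truth Integer labels 1--4.
#' @param pred Predicted labels 1--4.
#' @param prob Optional n x 4 probability matrix.
#' @param ba_method Balanced accuracy as macro recall (default) or as the
#'   per-class mean of sensitivity and specificity averaged over classes.
#' @return Object of class `metric_report`: list with `overall` (named
#'   vector) and `per_class` (data frame).
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
compute_metrics <- function(truth, pred, prob = NULL,
                            ba_method = c("macro_recall", "mean_sens_spec")) {
  ba_method <- match.arg(ba_method)
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(unique(truth)) < 2L)
    stop("need at least two classes in the truth labels")
  tab <- table(factor(truth, 1:4), factor(pred, 1:4))
  n <- length(truth)
  support <- tabulate(truth, 4)
  w <- support / n

  per <- lapply(1:4, function(cc) {
    tp <- tab[cc, cc]; fn <- support[cc] - tp
    fp <- sum(tab[, cc]) - tp; tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (is.na(sens) || sens + ppv == 0) 0 else 2 * ppv * sens / (ppv + sens)
    bt <- matrix(c(tn, fn, fp, tp), 2)
    data.frame(
      class = cc, support = support[cc],
      accuracy = (tp + tn) / n,
      balanced_accuracy = mean(c(sens, spec)),
      ppv = ppv, f1 = f1, kappa = .kappa(bt),
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
      recall = sens,
      aucroc = if (is.null(prob)) NA_real_ else .binary_auc(truth == cc, prob[, cc]),
      auprc = if (is.null(prob)) NA_real_ else .average_precision(truth == cc, prob[, cc])
    )
  })
  per <- do.call(rbind, per)

  present <- support > 0
  wnorm <- function(x) sum((w * x)[present & !is.na(x)]) / sum(w[present & !is.na(x)])
  ba <- if (ba_method == "macro_recall") mean(per$recall[present])
        else mean(per$balanced_accuracy[present])
  overall <- c(
    aucroc = if (is.null(prob)) NA_real_ else wnorm(per$aucroc),
    auprc = if (is.null(prob)) NA_real_ else wnorm(per$auprc),
    accuracy = mean(truth == pred),
    balanced_accuracy = ba,
    precision = wnorm(per$ppv),
    f1 = wnorm(per$f1),
    kappa = .kappa(tab)
  )
  structure(list(overall = overall, per_class = per), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (weighted one-vs-rest):\n")
  print(round(x$overall, 4))
  invisible(x)
}

#' Landis--Koch agreement band for a kappa value
#'
#' @param kappa Value in `[-1, 1]`.
#' @return One of `"no agreement"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost perfect"`.
#' @export
#' @examples
#' kappa_band(0.629)
kappa_band <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa < 0) "no agreement"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Repeated multi-fold cross-validation plan
#'
#' The default pairs 2/3/4/5/10-fold CV with 30/20/15/12/6 repetitions: 60
#' repetitions, each contributing its fold count of validation sets, i.e.
#' 300 train/validation splits.
#'
#' @param folds Fold counts.
#' @param reps Matching repetition counts.
#' @param base_seed Base seed; repetition r (counted across the whole plan)
#'   uses seed `base_seed + r`.
#' @return Object of class `rmfcv_plan`.
#' @export
#' @examples
#' rmfcv_plan()$total
rmfcv_plan <- function(folds = c(2, 3, 4, 5, 10),
                       reps = c(30, 20, 15, 12, 6),
                       base_seed = 1701L) {
  stopifnot(length(folds) == length(reps), all(folds >= 2), all(reps >= 1))
  structure(list(folds = folds, reps = reps,
                 base_seed = as.integer(base_seed),
                 total = as.integer(sum(folds * reps))),
            class = "rmfcv_plan")
}

#' @export
print.rmfcv_plan <- function(x, ...) {
  cat("rmfcv_plan:", paste0(x$folds, "-fold x ", x$reps, collapse = ", "),
      "=> ", x$total, "splits\n")
  invisible(x)
}

#' Generate stratified repeated multi-fold CV splits
#'
#' Within every repetition the validation folds partition the samples
#' exactly, per-fold class counts are balanced to within one, and each
#' repetition uses its own derived seed.
#'
#' @param y Labels (any coding; stratification is on distinct values).
#' @param plan An [rmfcv_plan()].
#' @return List of splits, each a list with `train`, `val`, `folds`, `rep`,
#'   `fold`, `seed`; length equals `plan$total`.
#' @export
rmfcv_splits <- function(y, plan = rmfcv_plan()) {
  stopifnot(inherits(plan, "rmfcv_plan"))
  counts <- table(y)
  if (any(counts < max(plan$folds)))
    stop("class too small for ", max(plan$folds), "-fold CV: ",
         paste(names(counts)[counts < max(plan$folds)], collapse = ", "))
  out <- list(); rep_id <- 0L
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[i]
    for (r in seq_len(plan$reps[i])) {
      rep_id <- rep_id + 1L
      seed <- plan$base_seed + rep_id
      set.seed(seed)
      fold_of <- integer(length(y))
      for (lv in names(counts)) {
        idx <- sample(which(y == lv))
        fold_of[idx] <- rep_len(seq_len(f), length(idx))
      }
      for (k in seq_len(f)) {
        val <- which(fold_of == k)
        out[[length(out) + 1L]] <- list(train = which(fold_of != k),
                                        val = val, folds = f, rep = rep_id,
                                        fold = k, seed = seed)
      }
    }
  }
  out
}

#' Metric report within age-sex strata
#'
#' Evaluates predictions within the eight age-sex strata (female/male/any
#' crossed with age >= 65 / < 65 / any, excluding the trivial any-any cell).
#' Empty strata yield `NA` metrics.
#'
#' @param age,sex Per-sample age (years) and sex (`"female"`/`"male"`).
#' @param truth,pred,prob As in [compute_metrics()].
#' @return Data frame with one row per stratum (`stratum`, `n`, the seven
#'   overall metrics); full [compute_metrics()] reports in the
#'   `reports` attribute.
#' @export
strata_report <- function(age, sex, truth, pred, prob = NULL) {
  strata <- list(
    "female" = sex == "female", "male" = sex == "male",
    "age>=65" = age >= 65, "age<65" = age < 65,
    "female,age>=65" = sex == "female" & age >= 65,
    "female,age<65" = sex == "female" & age < 65,
    "male,age>=65" = sex == "male" & age >= 65,
    "male,age<65" = sex == "male" & age < 65
  )
  reports <- lapply(strata, function(keep) {
    keep <- keep & !is.na(keep)
    if (sum(keep) < 2L || length(unique(truth[keep])) < 2L) return(NULL)
    compute_metrics(truth[keep], pred[keep],
                    if (is.null(prob)) NULL else prob[keep, , drop = FALSE])
  })
  metric_names <- c("aucroc", "auprc", "accuracy", "balanced_accuracy",
                    "precision", "f1", "kappa")
  rows <- mapply(function(rep, keep) {
    ov <- if (is.null(rep))
      stats::setNames(rep(NA_real_, 7), metric_names) else rep$overall
    c(n = sum(keep & !is.na(keep)), ov)
  }, reports, strata)
  out <- data.frame(stratum = names(strata), t(rows), check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Most frequent features among misclassified samples
#'
#' For each true class, ranks binary/discretized features by presence
#' frequency among the samples of that class that were misclassified, and
#' reports the top `top` with counts; frequency ties break lexicographically
#' by feature name.
#'
#' @param truth,pred Labels 1--4.
#' @param features Data frame of binary (0/1) or discretized features; a
#'   discretized level counts as "present" when it is not `"normal"`.
#' @param top Number of features to keep per class.
#' @return Data frame with `class`, `feature`, `count`, `rank`; empty when
#'   nothing is misclassified.
#' @export
misclassified_feature_table <- function(truth, pred, features, top = 10L) {
  features <- as.data.frame(features)
  stopifnot(length(truth) == length(pred), nrow(features) == length(truth))
  present <- vapply(features, function(v) {
    if (is.numeric(v)) as.numeric(v == 1)
    else as.numeric(!is.na(v) & v != "normal")
  }, numeric(nrow(features)))
  if (!is.matrix(present)) present <- matrix(present, nrow = nrow(features))
  colnames(present) <- names(features)
  rows <- lapply(sort(unique(truth)), function(cc) {
    mis <- truth == cc & pred != cc
    if (!any(mis)) return(NULL)
    cnt <- colSums(present[mis, , drop = FALSE], na.rm = TRUE)
    ord <- order(-cnt, names(cnt))[seq_len(min(top, length(cnt)))]
    data.frame(class = cc, feature = names(cnt)[ord], count = cnt[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = integer(0), feature = character(0),
                      count = numeric(0), rank = integer(0))
  rownames(out) <- NULL
  out
}

#' Univariate one-vs-rest feature importance
#'
#' Classifier-agnostic importance: for every (feature, class) pair, two-sided
#' Student's t and Kolmogorov--Smirnov tests of the feature in class `c`
#' versus the rest.
#'
#' @param x Numeric feature matrix or data frame.
#' @param y Labels 1--4.
#' @return Data frame with `feature`, `class`, `t_stat`, `t_p`, `ks_stat`,
#'   `ks_p` (NA for degenerate comparisons, e.g. constant features).
#' @export
univariate_importance <- function(x, y) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  rows <- list()
  for (f in names(x)) {
    v <- as.numeric(x[[f]])
    for (cc in sort(unique(as.integer(y)))) {
      a <- v[y == cc]; b <- v[y != cc]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      ks <- tryCatch(suppressWarnings(stats::ks.test(a, b)),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, class = cc,
        t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        t_p = if (is.null(tt)) NA_real_ else tt$p.value,
        ks_stat = if (is.null(ks)) NA_real_ else unname(ks$statistic),
        ks_p = if (is.null(ks)) NA_real_ else ks$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapley-value feature attribution for a trained member
#'
#' Permutation-sampling estimator of Shapley values against a k-means
#' background: for each explained instance and sampled permutation, features
#' are switched one at a time from a background row to the instance's values
#' and the change in each class probability is credited to the switched
#' feature. Exact in expectation; a constant model gets zero attribution
#' everywhere. Results are deterministic under `seed`. With `nsim = 0` the
#' model-based estimator is skipped and univariate importance is returned
#' with a warning.
#'
#' @param model An `etio_member` (or anything [predict_proba()] accepts), or
#'   a plain function mapping a numeric matrix to an n x 4 probability
#'   matrix.
#' @param x Numeric matrix of instances to explain (row-sample large inputs).
#' @param y Labels, only used for the `nsim = 0` fallback.
#' @param background_k Number of k-means background centers (default 100,
#'   capped at the number of rows).
#' @param nsim Permutations sampled per instance.
#' @param seed Seed for background clustering and permutation sampling.
#' @return List with `mean_abs` (feature x class matrix of mean absolute
#'   attributions) and `ranking` (list of per-class feature orderings, best
#'   first).
#' @export
shap_adapter <- function(model, x, y = NULL, background_k = 100L, nsim = 20L,
                         seed = 1L) {
  x <- as.matrix(x)
  if (nsim == 0L) {
    warning("nsim = 0: falling back to univariate importance")
    return(univariate_importance(x, y))
  }
  pf <- if (is.function(model)) model else function(z) predict_proba(model, z)
  set.seed(seed)
  k <- min(background_k, nrow(x))
  bg <- if (k < nrow(x))
    stats::kmeans(x, centers = k, nstart = 1, iter.max = 30)$centers
  else x
  p <- ncol(x)
  phi <- array(0, dim = c(p, 4), dimnames = list(colnames(x), as.character(1:4)))
  for (i in seq_len(nrow(x))) {
    acc <- matrix(0, p, 4)
    for (m in seq_len(nsim)) {
      b <- bg[sample(nrow(bg), 1L), ]
      perm <- sample(p)
      z <- matrix(rep(b, p + 1L), nrow = p + 1L, byrow = TRUE,
                  dimnames = list(NULL, colnames(x)))
      for (t in seq_len(p)) z[(t + 1L):(p + 1L), perm[t]] <- x[i, perm[t]]
      pr <- pf(z)
      acc[perm, ] <- acc[perm, ] + (pr[-1L, , drop = FALSE] -
                                      pr[-(p + 1L), , drop = FALSE])
    }
    phi <- phi + abs(acc / nsim)
  }
  mean_abs <- phi / nrow(x)
  ranking <- lapply(1:4, function(cc)
    rownames(mean_abs)[order(-mean_abs[, cc])])
  names(ranking) <- as.character(1:4)
  list(mean_abs = mean_abs, ranking = ranking)
}
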