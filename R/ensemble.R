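#' Fit the nine-member ensemble consensus stroke-etiology classifier
#'
#' The central fitting function. Optionally runs grid-search hyperparameter
#' optimization per learner family (five stratified 80/20 shuffle splits,
#' best mean weighted one-vs-rest AUCROC), then trains the five probabilistic
#' base classifiers (LR, SVC, RF, XGB, SVC2). At prediction time the four
#' summary-statistic ensembles (MEAN, MEDIAN, MAX, MIN) are derived from the
#' base probabilities and the nine member labels are combined by consensus
#' (plurality) voting.
#'
#' @param x Numeric feature matrix (samples x encoded features, complete) or
#'   a complete [feature_matrix()] (encoded internally).
#' @param y Adjudicated etiology labels 1--4 (cryptogenic code 5 must be
#'   excluded from training).
#' @param params Optional named list of per-family parameter lists (`LR`,
#'   `SVC`, `RF`, `XGB`); when `NULL`, HPO is run with `grids`.
#' @param grids Per-family search grids for HPO; default [default_grids()].
#' @param hpo_seed Seed anchoring the HPO shuffle splits (default 1701).
#' @param fit_seed Seed for the final model fits.
#' @return An object of class `etio_ensemble` with components `members`
#'   (the five fitted base models), `params`, `hpo` (per-family
#'   `hpo_result`s or `NULL`), `template` (encoded column layout), `n`,
#'   `class_counts` and `call`.
#' @seealso [predict.etio_ensemble()], [rmfcv_evaluate()]
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(n = 300, seed = 42))
#' prep <- prepare_matrix(coh, impute_seed = 1)
#' tr <- prep$y %in% 1:4
#' fit <- etio_ensemble(prep$x[tr, ], prep$y[tr],
#'                      params = fast_params())
#' predict(fit, prep$x[!tr, ])
#' }
etio_ensemble <- function(x, y, params = NULL, grids = default_grids(),
                          hpo_seed = 1701L, fit_seed = 1L) {
  cl <- match.call()
  if (inherits(x, "feature_matrix")) x <- encode_features(x)
  x <- as.matrix(x)
  y <- .as_y(y)
  if (anyNA(x)) stop("feature matrix has missing values; impute() first")
  hpo_res <- NULL
  if (is.null(params)) {
    hpo_res <- lapply(.families, function(f)
      hpo(f, x, as.integer(y), grid = grids[[f]], seed = hpo_seed))
    names(hpo_res) <- .families
    params <- lapply(hpo_res, `[[`, "best_params")
  }
  members <- fit_five(x, as.integer(y), params, seed = fit_seed)
  structure(list(members = members, params = params, hpo = hpo_res,
                 template = colnames(x), n = nrow(x),
                 class_counts = table(y), call = cl),
            class = "etio_ensemble")
}

#' Reasonable fixed hyperparameters for quick fits
#'
#' A single sensible setting per family, for fitting without a grid search
#' (examples, smoke runs, reduced-budget evaluations).
#' @return Named list of per-family parameter lists.
#' @export
fast_params <- function() {
  list(LR = list(decay = 0.01),
       SVC = list(cost = 1, gamma = NA),
       RF = list(ntree = 200, maxnodes = NA, nodesize = 1),
       XGB = list(nrounds = 100, max_depth = 3, eta = 0.3))
}

.member_names <- c("LR", "SVC", "RF", "XGB", "SVC2",
                   "MEAN", "MEDIAN", "MAX", "MIN")

# base + ensemble probabilities and the 9 member label columns
.member_predictions <- function(members, x) {
  base <- lapply(members, predict_proba, x = x)
  n <- nrow(base[[1]])
  arr <- array(unlist(base), dim = c(n, 4, 5))
  stats <- list(
    MEAN = apply(arr, c(1, 2), mean),
    MEDIAN = apply(arr, c(1, 2), stats::median),
    MAX = apply(arr, c(1, 2), max),
    MIN = apply(arr, c(1, 2), min)
  )
  stats <- lapply(stats, function(m) {
    s <- rowSums(m)
    zero <- s == 0
    if (any(zero)) {
      warning("zero-sum ensemble statistic; returning uniform probabilities")
      m[zero, ] <- 0.25; s[zero] <- 1
    }
    m / s
  })
  all_probs <- c(base, stats)
  labels <- vapply(all_probs, function(m) max.col(m, ties.method = "first"),
                   integer(n))
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = n)
  colnames(labels) <- .member_names
  list(base = base, ensembles = stats, labels = labels)
}

#' Predict with the consensus meta-classifier
#'
#' Runs the five base models, derives the four renormalized ensemble
#' probability rows, takes each of the nine members' argmax label, and
#' returns the consensus (plurality) prediction with its support count
#' (votes for the winning label, 3--9 by pigeonhole). Vote ties break by the
#' higher MEAN-ensemble probability, then the lower class code.
#'
#' @param object An [etio_ensemble()] fit.
#' @param newdata Numeric matrix in the training encoding, or a complete
#'   [feature_matrix()].
#' @param type `"consensus"` (default): data frame of predictions;
#'   `"prob"`: the MEAN-ensemble probability matrix; `"members"`: the n x 9
#'   member label matrix.
#' @param ... Unused.
#' @return See `type`. The consensus data frame has columns `pred`,
#'   `support`, `votes.1`..`votes.4`, plus attributes `members` (label
#'   matrix) and `prob` (MEAN-ensemble probabilities).
#' @export
predict.etio_ensemble <- function(object, newdata,
                                  type = c("consensus", "prob", "members"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix"))
    newdata <- encode_features(newdata, template = object$template)
  newdata <- as.matrix(newdata)[, object$template, drop = FALSE]
  mp <- .member_predictions(object$members, newdata)
  if (type == "members") return(mp$labels)
  if (type == "prob") return(mp$ensembles$MEAN)
  n <- nrow(mp$labels)
  votes <- t(vapply(seq_len(n), function(i)
    tabulate(mp$labels[i, ], nbins = 4), integer(4)))
  pred <- integer(n); support <- integer(n)
  for (i in seq_len(n)) {
    cv <- consensus_vote(mp$labels[i, ], mp$ensembles$MEAN[i, ])
    pred[i] <- cv$label; support[i] <- cv$support
  }
  out <- data.frame(pred = pred, support = support,
                    votes.1 = votes[, 1], votes.2 = votes[, 2],
                    votes.3 = votes[, 3], votes.4 = votes[, 4])
  attr(out, "members") <- mp$labels
  attr(out, "prob") <- mp$ensembles$MEAN
  out
}

#' @export
print.etio_ensemble <- function(x, ...) {
  cat("etio_ensemble: 9-member consensus stroke-etiology classifier\n")
  cat("  base members: LR, SVC, RF, XGB, SVC2",
      "+ ensembles MEAN, MEDIAN, MAX, MIN\n")
  cat("  trained on", x$n, "samples,", length(x$template), "encoded features\n")
  cat("  class counts:", paste(names(x$class_counts), x$class_counts,
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.etio_ensemble <- function(object, ...) {
  print(object)
  cat("\nhyperparameters:\n")
  for (f in names(object$params))
    cat("  ", f, ": ", paste(names(object$params[[f]]),
                             unlist(object$params[[f]]), sep = "=",
                             collapse = " "), "\n", sep = "")
  if (!is.null(object$hpo)) {
    cat("\nHPO mean validation AUCROC at optimum:\n")
    for (f in names(object$hpo))
      cat("  ", f, ": ", round(max(object$hpo[[f]]$mean_auc), 4), "\n", sep = "")
  }
  invisible(object)
}

#' Repeated multi-fold cross-validated evaluation of the consensus model
#'
#' For every split of the plan, refits the five base models on the training
#' fold (at fixed hyperparameters, seeded by the split's derived seed) and
#' scores the consensus and the nine individual members on the validation
#' fold.
#'
#' @param x Numeric encoded feature matrix (complete).
#' @param y Labels 1--4.
#' @param params Per-family hyperparameters (see [fit_five()]).
#' @param plan An [rmfcv_plan()]; scale it to your compute budget.
#' @return Object of class `rmfcv_result`: `split_metrics` (per-split data
#'   frame with consensus accuracy/F1/kappa/AUCROC), `member_accuracy`
#'   (splits x 9), `predictions` (pooled validation predictions with
#'   `split`, `idx`, `truth`, `pred`, `support`), and `plan`.
#' @export
rmfcv_evaluate <- function(x, y, params, plan = rmfcv_plan()) {
  x <- as.matrix(x); y <- .as_y(y)
  splits <- rmfcv_splits(as.integer(y), plan)
  sm <- list(); macc <- list(); preds <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    members <- fit_five(x[sp$train, , drop = FALSE],
                        as.integer(y)[sp$train], params, seed = sp$seed)
    xv <- x[sp$val, , drop = FALSE]
    yv <- as.integer(y)[sp$val]
    mp <- .member_predictions(members, xv)
    cons <- vapply(seq_along(sp$val), function(i) {
      cv <- consensus_vote(mp$labels[i, ], mp$ensembles$MEAN[i, ])
      c(cv$label, cv$support)
    }, numeric(2))
    rep_i <- compute_metrics(yv, cons[1, ], mp$ensembles$MEAN)
    sm[[s]] <- data.frame(split = s, folds = sp$folds, rep = sp$rep,
                          fold = sp$fold,
                          accuracy = rep_i$overall[["accuracy"]],
                          f1 = rep_i$overall[["f1"]],
                          kappa = rep_i$overall[["kappa"]],
                          aucroc = rep_i$overall[["aucroc"]])
    macc[[s]] <- colMeans(mp$labels == yv)
    preds[[s]] <- data.frame(split = s, idx = sp$val, truth = yv,
                             pred = cons[1, ], support = cons[2, ])
  }
  structure(list(split_metrics = do.call(rbind, sm),
                 member_accuracy = do.call(rbind, macc),
                 predictions = do.call(rbind, preds),
                 plan = plan),
            class = "rmfcv_result")
}

#' @export
print.rmfcv_result <- function(x, ...) {
  cat("rmfcv_result:", nrow(x$split_metrics), "splits\n")
  cat("  consensus accuracy:", round(mean(x$split_metrics$accuracy), 4),
      "+/-", round(stats::sd(x$split_metrics$accuracy), 4), "\n")
  invisible(x)
}

#' Prepare a generated cohort for model fitting
#'
#' Convenience pipeline: assemble a named dataset configuration, impute
#' missing values, and encode to a numeric model matrix.
#'
#' @param cohort A [feature_matrix()], e.g. from [generate_cohort()].
#' @param config Registry configuration name (default the full discretized
#'   set `combn1d.age.sex.v1`).
#' @param impute_method `"pmm"` or `"rf"`.
#' @param impute_seed Imputation seed.
#' @return List with `x` (encoded matrix for all samples), `y` (adjudicated
#'   labels 1--5) and `meta`.
#' @export
prepare_matrix <- function(cohort, config = "combn1d.age.sex.v1",
                           impute_method = "pmm", impute_seed = 1L) {
  ds <- build_dataset(cohort, config)
  ds <- impute(ds, method = impute_method, seed = impute_seed)
  list(x = encode_features(ds), y = ds$meta$toast, meta = ds$meta)
}
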