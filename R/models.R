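#' Default hyperparameter grids for the four base learner families
#'
#' Modest, config-overridable grids: L2-regularized multinomial logistic
#' regression over four penalty strengths; RBF support-vector classifier over
#' cost and gamma (an `NA` gamma means the dimension-scaled heuristic
#' default); random forest over tree count, node size and a depth cap;
#' gradient boosting over rounds, depth and learning rate.
#'
#' @return Named list of data frames, one per family (`LR`, `SVC`, `RF`,
#'   `XGB`); rows are grid points in evaluation order.
#' @export
default_grids <- function() {
  list(
    LR = data.frame(decay = c(0.01, 0.1, 1, 10)),
    SVC = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01)),
    RF = expand.grid(ntree = c(200, 500), maxnodes = c(NA, 1024),
                     nodesize = c(1, 5)),
    XGB = expand.grid(nrounds = c(100, 300), max_depth = c(3, 6),
                      eta = c(0.1, 0.3))
  )
}

.families <- c("LR", "SVC", "RF", "XGB")

.as_y <- function(y) {
  y <- factor(as.integer(y), levels = 1:4)
  if (anyNA(y)) stop("labels must be codes 1-4 (cryptogenic code 5 is never trained on)")
  y
}

# fit one family with one parameter setting; x numeric matrix, y codes 1-4
.fit_family <- function(family, x, y, params, seed = 1L) {
  y <- .as_y(y)
  if (length(unique(y)) < 2L) stop("degenerate single-class training input")
  set.seed(seed)
  fit <- switch(family,
    LR = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, decay = params$decay, trace = FALSE,
                     MaxNWts = 1e5, maxit = 300)
    },
    SVC = {
      g <- if (is.null(params$gamma) || is.na(params$gamma))
        1 / ncol(x) else params$gamma
      e1071::svm(x, y, kernel = "radial", cost = params$cost, gamma = g,
                 probability = TRUE)
    },
    RF = {
      mx <- if (is.null(params$maxnodes) || is.na(params$maxnodes))
        NULL else params$maxnodes
      randomForest::randomForest(x, y, ntree = params$ntree,
                                 nodesize = params$nodesize %||% 1,
                                 maxnodes = mx)
    },
    XGB = {
      dm <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = 4,
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dm, nrounds = params$nrounds, verbose = 0)
    },
    SVC2 = {
      g <- if (is.null(params$gamma) || is.na(params$gamma))
        1 / ncol(x) else params$gamma
      lapply(1:4, function(cc) {
        yb <- factor(ifelse(y == cc, "pos", "neg"), levels = c("pos", "neg"))
        e1071::svm(x, yb, kernel = "radial", cost = params$cost, gamma = g)
      })
    },
    stop("unknown learner family: ", family)
  )
  structure(list(family = family, fit = fit, params = params,
                 template = colnames(x), classes = 1:4),
            class = "etio_member")
}

#' Per-model class probabilities
#'
#' Returns the n x 4 class-probability matrix of one trained member on new
#' data, with the fixed class order 1,2,3,4 and rows renormalized to sum to
#' one. For the `SVC2` variant, probabilities are the softmax of the four
#' one-vs-rest decision margins.
#'
#' @param model An `etio_member` from the fitting layer.
#' @param x Numeric matrix matching the training encoding.
#' @return Matrix of probabilities, rows summing to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "etio_member"))
  x <- as.matrix(x)
  if (!identical(colnames(x), model$template)) {
    if (!all(model$template %in% colnames(x)))
      stop("prediction data does not match training schema")
    x <- x[, model$template, drop = FALSE]
  }
  p <- switch(model$family,
    LR = {
      pr <- stats::predict(model$fit, newdata = as.data.frame(x, check.names = FALSE),
                           type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(x))
      pr
    },
    SVC = {
      pr <- attr(stats::predict(model$fit, x, probability = TRUE), "probabilities")
      pr[, order(as.integer(colnames(pr))), drop = FALSE]
    },
    RF = stats::predict(model$fit, x, type = "prob"),
    XGB = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = 4, byrow = TRUE)
      pr
    },
    SVC2 = {
      margins <- sapply(model$fit, function(f) {
        dv <- attr(stats::predict(f, x, decision.values = TRUE),
                   "decision.values")
        # e1071 orients the margin by training-data order, not factor levels
        if (identical(colnames(dv)[1], "neg/pos")) dv <- -dv
        as.numeric(dv)
      })
      if (!is.matrix(margins)) margins <- matrix(margins, nrow = nrow(x))
      ex <- exp(margins - apply(margins, 1, max))
      ex / rowSums(ex)
    }
  )
  p <- as.matrix(p)
  colnames(p) <- as.character(1:4)
  p[p < 0 | is.na(p)] <- 0
  p / rowSums(p)
}

# stratified 80/20 shuffle splits; error if a class misses either side
.shuffle_splits <- function(y, n_splits = 5L, val_frac = 0.2, seed = 1701L) {
  y <- .as_y(y)
  set.seed(seed)
  lapply(seq_len(n_splits), function(s) {
    val <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      nv <- round(length(idx) * val_frac)
      if (nv < 1L || nv >= length(idx))
        stop("stratification failure: class ", lv, " too small for a ",
             val_frac, " validation split")
      sample(idx, nv)
    }))
    list(train = setdiff(seq_along(y), val), val = sort(val))
  })
}

#' Grid-search hyperparameter optimization for one learner family
#'
#' Every grid point is evaluated on the same five stratified random 80/20
#' train/validation splits (seeded, default 1701); the selected point
#' maximizes the mean class-support-weighted one-vs-rest AUCROC over the
#' splits, ties broken by grid order.
#'
#' @param family One of `"LR"`, `"SVC"`, `"RF"`, `"XGB"`.
#' @param x Numeric feature matrix (complete).
#' @param y Labels 1--4.
#' @param grid Data frame of parameter settings (rows in evaluation order);
#'   default the family's entry in [default_grids()].
#' @param seed Split seed.
#' @param n_splits,val_frac Shuffle-split plan (five 80/20 splits by default).
#' @param dataset Optional dataset name carried into the result.
#' @return An object of class `hpo_result`: `family`, `dataset`, `grid`,
#'   `mean_auc` per grid row, `split_auc` matrix, `best` (row index) and
#'   `best_params`.
#' @export
hpo <- function(family, x, y, grid = default_grids()[[family]],
                seed = 1701L, n_splits = 5L, val_frac = 0.2,
                dataset = NA_character_) {
  stopifnot(family %in% .families, nrow(grid) >= 1L)
  y <- .as_y(y)
  if (any(table(y) < 5L)) stop("need at least 5 samples per class for HPO")
  splits <- .shuffle_splits(y, n_splits, val_frac, seed)
  split_auc <- matrix(NA_real_, nrow(grid), length(splits))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    for (s in seq_along(splits)) {
      tr <- splits[[s]]$train; va <- splits[[s]]$val
      m <- .fit_family(family, x[tr, , drop = FALSE], y[tr], params,
                       seed = seed + s)
      p <- predict_proba(m, x[va, , drop = FALSE])
      split_auc[g, s] <- weighted_ovr_auc(as.integer(y[va]), p)
    }
  }
  mean_auc <- rowMeans(split_auc)
  best <- which.max(mean_auc)
  structure(list(family = family, dataset = dataset, grid = grid,
                 mean_auc = mean_auc, split_auc = split_auc, best = best,
                 best_params = as.list(grid[best, , drop = FALSE]),
                 seed = seed),
            class = "hpo_result")
}

#' @export
print.hpo_result <- function(x, ...) {
  cat("hpo_result:", x$family,
      if (!is.na(x$dataset)) paste0("on ", x$dataset), "\n")
  cat("  grid points:", nrow(x$grid), " best mean AUCROC:",
      round(max(x$mean_auc), 4), "\n")
  cat("  best params:", paste(names(x$best_params),
                              unlist(x$best_params), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the hyperparameter-optimization sweep
#'
#' One HPO task per (learner family, registry dataset) pair; the default
#' four families by 24 registry configurations enumerate 96 tasks.
#'
#' @param datasets Dataset configuration names; default the full registry.
#' @param families Learner families; default all four.
#' @return Data frame with columns `family` and `dataset`, one row per task.
#' @export
hpo_tasks <- function(datasets = names(feature_group_registry()),
                      families = .families) {
  out <- expand.grid(family = families, dataset = datasets,
                     stringsAsFactors = FALSE)
  out[order(match(out$family, families)), c("family", "dataset")]
}

#' Fit the five probabilistic base classifiers
#'
#' Trains the four optimized families at their selected hyperparameters plus
#' the `SVC2` variant, which reuses the support-vector hyperparameters but
#' derives probabilities from softmaxed one-vs-rest decision margins.
#'
#' @param x Numeric feature matrix (complete).
#' @param y Labels 1--4 (every class present).
#' @param params Named list with one parameter list per family (`LR`, `SVC`,
#'   `RF`, `XGB`), e.g. the `best_params` of [hpo()] results.
#' @param seed Fit seed.
#' @return Named list of class `etio_base_models` with members `LR`, `SVC`,
#'   `RF`, `XGB`, `SVC2`.
#' @export
fit_five <- function(x, y, params, seed = 1L) {
  missing <- setdiff(.families, names(params))
  if (length(missing) > 0L)
    stop("missing hyperparameters for family: ", paste(missing, collapse = ", "))
  members <- lapply(.families, function(f)
    .fit_family(f, x, y, params[[f]], seed = seed))
  names(members) <- .families
  members$SVC2 <- .fit_family("SVC2", x, y, params$SVC, seed = seed)
  structure(members, class = "etio_base_models")
}
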