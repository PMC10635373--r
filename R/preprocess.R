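#' Impute missing feature values
#'
#' Two single-completion methods behind one surface. `pmm` is predictive mean
#' matching: each incomplete column is regressed on the remaining columns
#' (initially mean/mode-completed), and every missing cell receives the
#' observed value of a donor drawn from the `k` observed rows whose predicted
#' means are closest, so imputed values always come from the column's
#' observed support. `rf` fits a random forest per incomplete column and
#' predicts the missing cells, which tolerates larger missing fractions.
#' Observed cells are never changed; complete input is returned as-is; a
#' fully missing column is an error naming the column. Deterministic under
#' `seed`.
#'
#' @param x A [feature_matrix()] or a plain data frame (numeric and/or
#'   character/factor columns).
#' @param method `"pmm"` or `"rf"`.
#' @param seed Integer seed.
#' @param k Donor-pool size for `pmm`.
#' @return Completed object of the same class as `x`.
#' @export
#' @examples
#' df <- data.frame(a = c(1, 2, NA, 4), b = c(0, 1, 1, 0))
#' impute(df, "pmm", seed = 1)
impute <- function(x, method = c("pmm", "rf"), seed = 1L, k = 5L) {
  method <- match.arg(method)
  if (inherits(x, "feature_matrix")) {
    x$values <- impute(x$values, method = method, seed = seed, k = k)
    return(x)
  }
  stopifnot(is.data.frame(x))
  has_na <- vapply(x, anyNA, TRUE)
  if (!any(has_na)) return(x)
  fully <- vapply(x, function(col) all(is.na(col)), TRUE)
  if (any(fully))
    stop("cannot impute fully-missing column(s): ",
         paste(names(x)[fully], collapse = ", "))
  set.seed(seed)

  is_num <- vapply(x, is.numeric, TRUE)
  # initial mean/mode completion used as the predictor frame
  init <- x
  for (j in names(x)) {
    col <- init[[j]]
    if (!anyNA(col)) next
    if (is_num[[j]]) {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
    } else {
      tab <- table(col)
      col[is.na(col)] <- names(tab)[which.max(tab)]
    }
    init[[j]] <- col
  }
  # numeric-coded predictor matrix
  code <- function(df) {
    m <- lapply(df, function(col)
      if (is.numeric(col)) col else as.numeric(factor(col)))
    do.call(cbind, m)
  }
  out <- x
  for (j in names(x)[has_na]) {
    mis <- is.na(x[[j]])
    obs <- !mis
    pred <- code(init[setdiff(names(x), j)])
    if (method == "pmm") {
      y <- if (is_num[[j]]) x[[j]] else as.numeric(factor(x[[j]]))
      y[mis] <- NA
      fit <- stats::lm.fit(cbind(1, pred[obs, , drop = FALSE]), y[obs])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      yhat <- drop(cbind(1, pred) %*% beta)
      donors <- which(obs)
      for (i in which(mis)) {
        d <- abs(yhat[donors] - yhat[i])
        pool <- donors[order(d)][seq_len(min(k, length(donors)))]
        out[[j]][i] <- x[[j]][sample(pool, 1L)]
      }
    } else {
      ytr <- x[[j]][obs]
      fac <- !is_num[[j]] || length(unique(ytr)) <= 2L
      ytr <- if (fac) factor(ytr) else ytr
      rf <- randomForest::randomForest(pred[obs, , drop = FALSE], ytr,
                                       ntree = 100)
      ph <- stats::predict(rf, pred[mis, , drop = FALSE])
      out[[j]][mis] <- if (fac) {
        v <- as.character(ph)
        if (is_num[[j]]) as.numeric(v) else v
      } else as.numeric(ph)
    }
  }
  out
}

#' Default PCA variance thresholds
#'
#' The eleven cumulative total-variance thresholds the reduction is evaluated
#' at (0.10--0.90 by 0.10, then 0.95 and 0.99).
#' @return Numeric vector of fractions.
#' @export
default_pca_thresholds <- function()
  c(seq(0.1, 0.9, by = 0.1), 0.95, 0.99)

#' Fit a train-anchored PCA reduction
#'
#' Principal components are fit on the (optionally standardized) training
#' matrix only; validation/test data are later projected with the training
#' loadings, means and scales via [pca_apply()]. For each requested threshold
#' the selected component count is the smallest `k` whose cumulative
#' explained fraction of total variance reaches the threshold (capped at the
#' rank).
#'
#' @param x Numeric training matrix (samples x features), complete.
#' @param thresholds Fractions in `(0, 1]`.
#' @param standardize Scale columns to unit variance (zero-variance columns
#'   are dropped from the rotation).
#' @return An object of class `pca_model` with fields `prcomp`, `dropped`,
#'   `thresholds`, `k` (named component counts) and `explained` (variance
#'   fractions, descending).
#' @export
pca_fit <- function(x, thresholds = default_pca_thresholds(),
                    standardize = TRUE) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), !anyNA(x), all(thresholds > 0), all(thresholds <= 1))
  keep <- apply(x, 2, stats::sd) > 0
  fit <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                       scale. = standardize)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  cum <- cumsum(expl)
  kk <- vapply(thresholds, function(t) {
    w <- which(cum >= t - 1e-12)
    if (length(w) == 0L) length(cum) else min(w)
  }, 1L)
  names(kk) <- as.character(thresholds)
  structure(list(prcomp = fit, dropped = colnames(x)[!keep],
                 thresholds = thresholds, k = kk, explained = expl),
            class = "pca_model")
}

#' Project data with a fitted PCA model
#'
#' Uses only the training-fit centering, scaling and loadings.
#'
#' @param model A [pca_fit()] result.
#' @param x Numeric matrix with the training columns.
#' @param threshold One of the model's thresholds (selects the component
#'   count); default the largest.
#' @return Reduced numeric matrix (samples x k components).
#' @export
pca_apply <- function(model, x, threshold = NULL) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  x <- x[, rownames(model$prcomp$rotation), drop = FALSE]
  if (is.null(threshold)) threshold <- max(model$thresholds)
  key <- as.character(threshold)
  if (!key %in% names(model$k)) stop("threshold not fitted: ", threshold)
  k <- model$k[[key]]
  scores <- stats::predict(model$prcomp, newdata = x)
  scores[, seq_len(k), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-hot/numeric encoding of a feature matrix for model fitting
#'
#' Continuous and binary features pass through as numeric columns;
#' categorical (discretized) features are expanded to one indicator column
#' per level (`feature=high`, ...). A template from a previous encoding
#' enforces an identical column layout for new data, which is how train-time
#' schemas are applied at prediction time.
#'
#' @param fm A [feature_matrix()] (complete; impute first).
#' @param template Optional character vector of column names from a previous
#'   call; output is conformed to it (absent columns filled with 0).
#' @return Numeric matrix with a `template` attribute.
#' @export
encode_features <- function(fm, template = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- list()
  for (j in seq_len(nrow(fm$descriptors))) {
    nm <- fm$descriptors$name[j]
    v <- fm$values[[nm]]
    if (fm$descriptors$kind[j] == "categorical" || is.character(v)) {
      for (lev in c("high", "normal", "low")) {
        if (is.null(template) && !any(v == lev, na.rm = TRUE)) next
        cols[[paste0(nm, "=", lev)]] <- as.numeric(v == lev)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- fm$meta$id
  if (!is.null(template)) {
    out <- matrix(0, nrow(m), length(template),
                  dimnames = list(rownames(m), template))
    shared <- intersect(colnames(m), template)
    out[, shared] <- m[, shared]
    m <- out
  }
  attr(m, "template") <- colnames(m)
  m
}
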