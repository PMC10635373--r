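#' Summary-statistic ensemble of base-model probabilities
#'
#' Applies one of the four summary statistics (`MEAN`, `MEDIAN`, `MAX`,
#' `MIN`) per class across the base models' probability rows, then
#' renormalizes over the four classes so the result is again a probability
#' vector. A `MIN` over models with disjoint support can zero out; the result
#' is then uniform with a warning.
#'
#' @param rows Matrix of base-model probability rows (models x 4), each row
#'   summing to 1.
#' @param stat One of `"MEAN"`, `"MEDIAN"`, `"MAX"`, `"MIN"`.
#' @return Length-4 probability vector summing to 1.
#' @export
#' @examples
#' rows <- rbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.6, 0.1, 0.1))
#' ensemble_probs(rows, "MAX")
ensemble_probs <- function(rows, stat = c("MEAN", "MEDIAN", "MAX", "MIN")) {
  stat <- match.arg(stat)
  rows <- as.matrix(rows)
  stopifnot(ncol(rows) == 4, all(abs(rowSums(rows) - 1) < 1e-6))
  v <- switch(stat,
    MEAN = colMeans(rows),
    MEDIAN = apply(rows, 2, stats::median),
    MAX = apply(rows, 2, max),
    MIN = apply(rows, 2, min)
  )
  if (sum(v) == 0) {
    warning("zero-sum ensemble statistic; returning uniform probabilities")
    return(rep(0.25, 4))
  }
  v / sum(v)
}

#' Consensus vote over the nine member classifiers
#'
#' Tallies the nine member labels (five base + four ensemble classifiers),
#' returns the plurality label, its support count, and the per-class vote
#' counts. With nine votes over four classes the plurality support is always
#' at least 3. Ties are broken by the higher MEAN-ensemble probability, then
#' by the lower class code.
#'
#' @param labels Integer vector of 9 member labels in 1--4.
#' @param mean_probs Length-4 MEAN-ensemble probability vector (tie-breaks).
#' @return List with `label`, `support`, `votes` (named length-4 counts).
#' @export
#' @examples
#' consensus_vote(c(1, 1, 1, 2, 2, 3, 3, 3, 3), rep(0.25, 4))
consensus_vote <- function(labels, mean_probs = rep(0.25, 4)) {
  stopifnot(length(labels) == 9, all(labels %in% 1:4),
            length(mean_probs) == 4)
  votes <- tabulate(labels, nbins = 4)
  names(votes) <- as.character(1:4)
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    top <- top[order(-mean_probs[top], top)]
  }
  label <- unname(top[1L])
  list(label = label, support = votes[[label]], votes = votes)
}

#' Reference consensus-support thresholds
#'
#' The published first-quartile ("moderate confidence") support thresholds
#' derived from external validation: 7 supports for class 1, 9 for class 2,
#' 7.2 for class 3 and 7 for class 4. Shipped as a reference constant for use
#' when no validation cohort is at hand.
#'
#' @return Named numeric vector of per-class thresholds with a `quantile`
#'   attribute (`0.25`).
#' @export
reference_thresholds <- function() {
  structure(c(`1` = 7, `2` = 9, `3` = 7.2, `4` = 7), quantile = 0.25)
}

#' Per-class support thresholds from a validation cohort
#'
#' For each predicted class, the q-quantile (linear interpolation between
#' order statistics, so fractional thresholds arise) of the consensus support
#' counts among the samples predicted as that class.
#'
#' @param pred Predicted plurality labels (1--4) on the validation cohort.
#' @param support Matching consensus support counts (3--9).
#' @param q Quantile in (0, 1); 0.25 is the "moderate confidence" choice.
#' @return Named numeric vector of thresholds in `[3, 9]` with a `quantile`
#'   attribute.
#' @export
#' @examples
#' quartile_thresholds(rep(1, 5), c(7, 7, 8, 9, 9), q = 0.25)
quartile_thresholds <- function(pred, support, q = 0.25) {
  stopifnot(length(pred) == length(support), q > 0, q < 1)
  out <- vapply(1:4, function(cc) {
    s <- support[pred == cc]
    if (length(s) == 0L)
      stop("class ", cc, " never predicted; threshold undefined")
    stats::quantile(s, q, type = 7, names = FALSE)
  }, 1)
  names(out) <- as.character(1:4)
  structure(out, quantile = q)
}

#' Reclassify cryptogenic strokes with a certainty heuristic
#'
#' A cryptogenic sample whose consensus plurality label is `c` with support
#' `s` is assigned etiology `c` iff `s >= t_c` (boundary inclusive);
#' otherwise it stays unassigned as "persistently cryptogenic".
#'
#' @param pred Plurality labels (1--4).
#' @param support Matching consensus support counts.
#' @param thresholds Per-class thresholds, e.g. [reference_thresholds()] or
#'   [quartile_thresholds()].
#' @return Factor over levels `"1"`..`"4"` and `"persistently cryptogenic"`.
#' @export
#' @examples
#' reclassify_cryptogenic(c(2, 3), c(9, 7), reference_thresholds())
reclassify_cryptogenic <- function(pred, support, thresholds = reference_thresholds()) {
  stopifnot(length(pred) == length(support),
            all(as.character(1:4) %in% names(thresholds)))
  t_c <- as.numeric(thresholds[as.character(pred)])
  out <- ifelse(support >= t_c, as.character(pred), "persistently cryptogenic")
  factor(out, levels = c(as.character(1:4), "persistently cryptogenic"))
}

#' EHR signature features of reclassified cryptogenic strokes
#'
#' Among reclassified (non-abstained) cryptogenic samples, finds binary
#' features present in more than half of the samples of at least one
#' predicted class, and tests each for class specificity with a chi-squared
#' test (no continuity correction) of presence by predicted class.
#'
#' @param pred Predicted classes (1--4) for the reclassified samples
#'   (persistently cryptogenic samples excluded by the caller).
#' @param features Data frame or matrix of 0/1 features for those samples.
#' @param p_cut Class-specificity flag threshold (default 0.01).
#' @return Data frame with `feature`, per-class prevalences `prev1`..`prev4`,
#'   `p_value` and `class_specific`; features below the 50 percent bar in all
#'   classes are dropped.
#' @export
signature_features <- function(pred, features, p_cut = 0.01) {
  features <- as.data.frame(features)
  stopifnot(length(pred) == nrow(features), all(pred %in% 1:4))
  classes <- 1:4
  empty <- setdiff(classes, unique(pred))
  if (length(empty) > 0L)
    warning("no samples in predicted class(es): ", paste(empty, collapse = ", "))
  rows <- lapply(names(features), function(f) {
    x <- as.numeric(features[[f]])
    prev <- vapply(classes, function(cc) {
      idx <- pred == cc
      if (!any(idx)) NA_real_ else mean(x[idx], na.rm = TRUE)
    }, 1)
    if (!any(prev > 0.5, na.rm = TRUE)) return(NULL)
    tab <- table(factor(x > 0.5, levels = c(FALSE, TRUE)),
                 factor(pred, levels = intersect(classes, unique(pred))))
    p <- if (any(rowSums(tab) == 0)) 1 else tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(feature = f, prev1 = prev[1], prev2 = prev[2], prev3 = prev[3],
               prev4 = prev[4], p_value = p,
               class_specific = !is.na(p) && p < p_cut,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(0), prev1 = numeric(0),
                      prev2 = numeric(0), prev3 = numeric(0),
                      prev4 = numeric(0), p_value = numeric(0),
                      class_specific = logical(0))
  rownames(out) <- NULL
  out
}
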