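#' Published per-site etiology count reference
#'
#' Adjudicated TOAST etiology counts of the three published study cohorts
#' (two derivation sites and the external-validation site), shipped as a
#' reference input for cohort-composition arithmetic; pass to
#' [cohort_summary()] to reproduce the printed percentage breakdowns.
#'
#' @return Named list of per-site count vectors over codes 1--5.
#' @export
#' @examples
#' cohort_summary(etiology_reference_counts())
etiology_reference_counts <- function() {
  list(
    YNHH = c(`1` = 251, `2` = 418, `3` = 194, `4` = 113, `5` = 293),
    MGH = c(`1` = 314, `2` = 446, `3` = 160, `4` = 143, `5` = 430),
    MIMIC = c(`1` = 44, `2` = 256, `3` = 18, `4` = 88, `5` = 94)
  )
}

#' Published cryptogenic reclassification count reference
#'
#' The reported distribution of predicted etiologies among adjudicated
#' cryptogenic strokes after applying the first-quartile consensus-support
#' certainty heuristic, per cohort, together with the analyzed
#' non-cryptogenic sample counts needed to express results against the full
#' analyzed cohort.
#'
#' @return List with `counts` (data frame: `category` = predicted class
#'   1--4 or `"persistently cryptogenic"`, one count column per cohort) and
#'   `analyzed_noncryptogenic` (named vector of analyzed non-cryptogenic
#'   sample counts per cohort).
#' @export
cryptogenic_reference_counts <- function() {
  counts <- data.frame(
    category = c("1", "2", "3", "4", "persistently cryptogenic"),
    YNHH = c(55, 93, 30, 19, 88),
    MGH = c(89, 155, 30, 24, 111),
    MIMIC = c(26, 24, 5, 13, 26),
    stringsAsFactors = FALSE
  )
  list(counts = counts,
       analyzed_noncryptogenic = c(YNHH = 930, MGH = 1002, MIMIC = 405))
}

#' Summarize a cryptogenic reclassification outcome
#'
#' Given per-cohort counts of reclassified cryptogenic strokes (predicted
#' classes 1--4 plus the persistently cryptogenic remainder) and the
#' analyzed non-cryptogenic sample counts, computes the quantities a
#' reclassification analysis reports: per-cohort and merged predicted-class
#' shares among cryptogenic samples, the persistently cryptogenic share, the
#' baseline cryptogenic prevalence of the full analyzed cohort, the residual
#' cryptogenic prevalence after reclassification, and the relative reduction.
#'
#' @param ref As returned by [cryptogenic_reference_counts()] (the default),
#'   or the same structure computed from a cohort of your own.
#' @return List with `shares` (percentage of cryptogenic samples per
#'   category, per cohort and merged, one decimal), `persistent_pct`
#'   (merged persistently cryptogenic share of cryptogenic samples),
#'   `baseline_pct` (cryptogenic share of the full analyzed cohort),
#'   `residual_pct` (persistently cryptogenic share of the full analyzed
#'   cohort) and `relative_reduction_pct`, the last four unrounded.
#' @export
#' @examples
#' s <- reclassification_summary()
#' round(s$persistent_pct, 1)
reclassification_summary <- function(ref = cryptogenic_reference_counts()) {
  counts <- ref$counts
  cohorts <- setdiff(names(counts), "category")
  counts$Merged <- rowSums(counts[, cohorts, drop = FALSE])
  shares <- counts
  for (ch in c(cohorts, "Merged"))
    shares[[ch]] <- round(100 * counts[[ch]] / sum(counts[[ch]]), 1)
  n_cry <- sum(counts$Merged)
  n_persistent <- counts$Merged[counts$category == "persistently cryptogenic"]
  n_full <- n_cry + sum(ref$analyzed_noncryptogenic)
  baseline <- 100 * n_cry / n_full
  residual <- 100 * n_persistent / n_full
  list(
    shares = shares,
    persistent_pct = 100 * n_persistent / n_cry,
    baseline_pct = baseline,
    residual_pct = residual,
    relative_reduction_pct = 100 * (baseline - residual) / baseline
  )
}
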