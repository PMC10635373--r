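#' TOAST etiology labels
#'
#' The five mutually exclusive causative mechanisms of ischemic stroke per the
#' TOAST system. Codes 1--4 are the "non-cryptogenic" etiologies the classifier
#' is trained on; code 5 (cryptogenic) never appears as a training label and is
#' only ever an input to the reclassification heuristic.
#'
#' @return A data frame with columns `code` (integer 1--5), `display`
#'   (character) and `non_cryptogenic` (logical).
#' @export
#' @examples
#' toast_labels()
toast_labels <- function() {
  data.frame(
    code = 1:5,
    display = c(
      "large-artery atherosclerosis", "cardioembolism",
      "small-vessel disease", "other determined", "cryptogenic"
    ),
    non_cryptogenic = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default discretization rules for clinical-history and laboratory features
#'
#' The sixteen cutoff rules used to turn noisy continuous measurements into
#' 2-level (`high`/`normal`, one cutoff) or 3-level (`high`/`normal`/`low`,
#' two cutoffs) features. Hemoglobin ships as two sex-specific rows. The
#' boundary convention is strict: a value must exceed the (upper) cutoff to be
#' `high` and fall strictly below the lower cutoff to be `low`; ties are
#' `normal`.
#'
#' @return A data frame with one row per printed rule: `feature`, `sex`
#'   (`NA` when the rule is not sex-specific), `hi`, `lo` (`NA` for one-cutoff
#'   rules).
#' @export
#' @examples
#' discretization_rules()
discretization_rules <- function() {
  r <- function(feature, hi, lo = NA_real_, sex = NA_character_) {
    data.frame(feature = feature, sex = sex, hi = hi, lo = lo,
               stringsAsFactors = FALSE)
  }
  rbind(
    r("ejection_fraction", 40),
    r("nihss", 6),
    r("sodium", 136),
    r("bun", 24),
    r("alt", 36),
    r("ast", 36),
    r("wbc", 11),
    r("hematocrit", 46, 35),
    r("hemoglobin", 15.5, 11.7, sex = "female"),
    r("hemoglobin", 17.1, 13.2, sex = "male"),
    r("triglycerides", 200),
    r("hdl", 40),
    r("ldl", 100),
    r("tsh", 4.2),
    r("ptt", 29.9),
    r("a1c", 6.5)
  )
}

#' Discretize a continuous clinical value
#'
#' Applies a cutoff rule from [discretization_rules()] (or a user-supplied
#' table with the same columns). One-cutoff rules return `high` iff the value
#' strictly exceeds the cutoff, else `normal`; two-cutoff rules additionally
#' return `low` iff the value is strictly below the lower cutoff. Missing
#' values propagate to `NA`. Values already equal to one of the levels are
#' returned unchanged, so the operation is idempotent.
#'
#' @param feature Rule name, e.g. `"nihss"`.
#' @param value Numeric vector (or character already at a level).
#' @param sex Per-value sex (`"female"`/`"male"`), required for sex-specific
#'   rules such as hemoglobin. Recycled if length 1.
#' @param rules Rule table; defaults to the shipped sixteen.
#' @return Character vector over `c("high", "normal", "low")` with `NA` for
#'   missing inputs.
#' @export
#' @examples
#' discretize("nihss", c(8, 6, 3))
#' discretize("hemoglobin", 12, sex = "male")
discretize <- function(feature, value, sex = NULL,
                       rules = discretization_rules()) {
  sub <- rules[rules$feature == feature, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown feature in discretization rules: ", feature)
  if (is.character(value) || is.factor(value)) {
    value <- as.character(value)
    ok <- value %in% c("high", "normal", "low") | is.na(value)
    if (!all(ok)) stop("non-level character values for feature ", feature)
    return(value)
  }
  sexed <- !all(is.na(sub$sex))
  if (sexed) {
    if (is.null(sex)) stop("sex required to discretize feature ", feature)
    sex <- rep_len(as.character(sex), length(value))
  }
  out <- rep(NA_character_, length(value))
  for (i in seq_along(value)) {
    v <- value[i]
    if (is.na(v)) next
    if (sexed) {
      if (is.na(sex[i])) stop("sex required but missing for feature ", feature)
      row <- sub[sub$sex == sex[i], , drop = FALSE]
      if (nrow(row) == 0L) stop("no ", feature, " rule for sex ", sex[i])
    } else {
      row <- sub[1L, , drop = FALSE]
    }
    out[i] <- if (v > row$hi) "high"
      else if (!is.na(row$lo) && v < row$lo) "low"
      else "normal"
  }
  out
}

# internal constructor ------------------------------------------------------

#' Construct a feature matrix
#'
#' Bundles sample-by-feature values with a descriptor table (name, group,
#' kind) and per-sample metadata (site, age, sex, adjudicated TOAST label).
#' Feature groups follow the six-family taxonomy: `DEMO` (age, sex), `CUI`
#' (binary concept indicators), `RAD` (radiology), `HRT` (cardiac), `HEX`
#' (clinical history / exam) and `LAB` (laboratory).
#'
#' @param values Data frame of feature values (missing allowed), one column
#'   per descriptor row.
#' @param descriptors Data frame with columns `name`, `group`, `kind`
#'   (`binary`, `continuous` or `categorical`) and optionally `sex_specific`.
#' @param meta Data frame with at least `site` and `toast`; `age`, `sex`,
#'   `latent` and `id` are carried when present.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, meta) {
  stopifnot(is.data.frame(values), is.data.frame(descriptors), is.data.frame(meta))
  if (anyDuplicated(descriptors$name)) stop("duplicate feature names")
  if (!identical(sort(names(values)), sort(descriptors$name)))
    stop("values columns must match descriptor names")
  if (!all(descriptors$group %in% c("DEMO", "CUI", "RAD", "HRT", "HEX", "LAB")))
    stop("unknown feature group tag")
  if (nrow(values) != nrow(meta)) stop("meta rows must match sample count")
  if (is.null(descriptors$sex_specific)) descriptors$sex_specific <- FALSE
  values <- values[, descriptors$name, drop = FALSE]
  structure(list(values = values, descriptors = descriptors, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$descriptors$group)
  cat("feature_matrix:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (!is.null(x$meta$site))
    cat("  sites:", paste(names(table(x$meta$site)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Registry of named training-dataset configurations
#'
#' Enumerates the 24 feature-group dataset configurations the model sweep is
#' run over: three age+sex encoding variants, the seven single-group sets,
#' eight multi-group combinations (the all-group set, the five leave-one-out
#' sets, and the two discretized full sets), the two MaxInfo-filtered
#' variants, and the four PCA variants. The full discretized set
#' `combn1d.age.sex.v1` (age + sex + CUI + RAD + HRT + discretized HEX +
#' discretized LAB) is the flagship configuration.
#'
#' Suffix semantics: `v1` keeps age continuous, `v2` discretizes age at 65,
#' `v3` standardizes age; a `d` marks discretized HEX/LAB; `.maxinfo` filters
#' samples to those with at least four observed feature categories; `.pca`
#' requests train-anchored PCA reduction downstream.
#'
#' @return A named list of configurations, each a list with fields `name`,
#'   `groups` (character vector over the six family tags), `discretize`
#'   (logical: discretize HEX/LAB/EF-type continuous features),
#'   `age_encoding` (`"continuous"`, `"binary65"`, `"standardized"` or `NA`),
#'   `maxinfo_filter` (logical) and `pca` (logical).
#' @export
#' @examples
#' length(feature_group_registry())
#' feature_group_registry()[["combn1d.age.sex.v1"]]
feature_group_registry <- function() {
  cfg <- function(name, groups, discretize = FALSE, age_encoding = NA,
                  maxinfo_filter = FALSE, pca = FALSE) {
    list(name = name, groups = groups, discretize = discretize,
         age_encoding = age_encoding, maxinfo_filter = maxinfo_filter,
         pca = pca)
  }
  all5 <- c("CUI", "RAD", "HRT", "HEX", "LAB")
  demo <- "DEMO"
  out <- list(
    cfg("age.sex.v1", demo, age_encoding = "continuous"),
    cfg("age.sex.v2", demo, age_encoding = "binary65"),
    cfg("age.sex.v3", demo, age_encoding = "standardized"),
    cfg("hex",  "HEX"),
    cfg("hexd", "HEX", discretize = TRUE),
    cfg("lab",  "LAB"),
    cfg("labd", "LAB", discretize = TRUE),
    cfg("hrt",  "HRT"),
    cfg("rad",  "RAD"),
    cfg("cui",  "CUI"),
    cfg("combn1.age.sex.v1", c(demo, all5), age_encoding = "continuous"),
    cfg("combn2.age.sex.v1", c(demo, setdiff(all5, "CUI")), age_encoding = "continuous"),
    cfg("combn3.age.sex.v1", c(demo, setdiff(all5, "RAD")), age_encoding = "continuous"),
    cfg("combn4.age.sex.v1", c(demo, setdiff(all5, "HRT")), age_encoding = "continuous"),
    cfg("combn5.age.sex.v1", c(demo, setdiff(all5, "HEX")), age_encoding = "continuous"),
    cfg("combn6.age.sex.v1", c(demo, setdiff(all5, "LAB")), age_encoding = "continuous"),
    cfg("combn1d.age.sex.v1", c(demo, all5), discretize = TRUE, age_encoding = "continuous"),
    cfg("combn1d.age.sex.v2", c(demo, all5), discretize = TRUE, age_encoding = "binary65"),
    cfg("combn1d.age.sex.v1.maxinfo", c(demo, all5), discretize = TRUE,
        age_encoding = "continuous", maxinfo_filter = TRUE),
    cfg("combn1d.age.sex.v2.maxinfo", c(demo, all5), discretize = TRUE,
        age_encoding = "binary65", maxinfo_filter = TRUE),
    cfg("combn1d.age.sex.v1.pca", c(demo, all5), discretize = TRUE,
        age_encoding = "continuous", pca = TRUE),
    cfg("combn1d.age.sex.v2.pca", c(demo, all5), discretize = TRUE,
        age_encoding = "binary65", pca = TRUE),
    cfg("combn1d.age.sex.v1.maxinfo.pca", c(demo, all5), discretize = TRUE,
        age_encoding = "continuous", maxinfo_filter = TRUE, pca = TRUE),
    cfg("combn1d.age.sex.v2.maxinfo.pca", c(demo, all5), discretize = TRUE,
        age_encoding = "binary65", maxinfo_filter = TRUE, pca = TRUE)
  )
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Filter samples by observed feature-category information
#'
#' Keeps samples with non-missing content in at least `k` of the five
#' non-demographic feature categories (CUI, RAD, HRT, HEX, LAB). A category
#' counts as present when the sample has at least one observed value in any
#' of that category's columns.
#'
#' @param fm A [feature_matrix()].
#' @param k Minimum number of present categories (1--5); default 4.
#' @return A `feature_matrix` restricted to the qualifying samples (possibly
#'   zero rows).
#' @export
maxinfo_filter <- function(fm, k = 4L) {
  stopifnot(inherits(fm, "feature_matrix"), k >= 1, k <= 5)
  cats <- c("CUI", "RAD", "HRT", "HEX", "LAB")
  present <- sapply(cats, function(g) {
    cols <- fm$descriptors$name[fm$descriptors$group == g]
    if (length(cols) == 0L) return(rep(FALSE, nrow(fm$values)))
    rowSums(!is.na(fm$values[, cols, drop = FALSE])) > 0L
  })
  keep <- rowSums(present) >= k
  feature_matrix(fm$values[keep, , drop = FALSE], fm$descriptors,
                 fm$meta[keep, , drop = FALSE])
}

#' Assemble a training dataset from a feature-group configuration
#'
#' Subsets a feature matrix to the columns named by a registry configuration,
#' discretizing HEX/LAB-type continuous features (and ejection fraction) where
#' the configuration flags it, re-encoding age per the configuration's
#' variant, and applying the MaxInfo sample filter when set. When a second
#' cohort is supplied the result is restricted to the feature intersection of
#' the two, so a model trained on one site can be applied to the other.
#'
#' @param fm A [feature_matrix()].
#' @param config A configuration from [feature_group_registry()] or its name.
#' @param other Optional second `feature_matrix`; restricts to shared features.
#' @return A `feature_matrix` with the configured columns. Discretized columns
#'   become `categorical` descriptors over `high`/`normal`/`low`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n = 40, seed = 1))
#' ds <- build_dataset(coh, "combn1d.age.sex.v1")
#' dim(ds)
build_dataset <- function(fm, config, other = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(config)) {
    reg <- feature_group_registry()
    if (!config %in% names(reg)) stop("unknown dataset configuration: ", config)
    config <- reg[[config]]
  }
  missing_groups <- setdiff(config$groups, unique(fm$descriptors$group))
  if (length(missing_groups) > 0L)
    stop("groups absent from matrix: ", paste(missing_groups, collapse = ", "))
  desc <- fm$descriptors[fm$descriptors$group %in% config$groups, , drop = FALSE]
  if (!is.null(other)) {
    stopifnot(inherits(other, "feature_matrix"))
    desc <- desc[desc$name %in% other$descriptors$name, , drop = FALSE]
  }
  if (nrow(desc) == 0L) stop("empty dataset after filtering")
  vals <- fm$values[, desc$name, drop = FALSE]

  rules <- discretization_rules()
  if (isTRUE(config$discretize)) {
    for (j in seq_len(nrow(desc))) {
      nm <- desc$name[j]
      if (desc$group[j] %in% c("HEX", "LAB", "HRT") && nm %in% rules$feature &&
          desc$kind[j] == "continuous") {
        sexed <- !all(is.na(rules$sex[rules$feature == nm]))
        vals[[nm]] <- discretize(nm, vals[[nm]],
                                 sex = if (sexed) fm$meta$sex else NULL,
                                 rules = rules)
        desc$kind[j] <- "categorical"
      }
    }
  }
  if ("age" %in% desc$name && !is.na(config$age_encoding)) {
    if (config$age_encoding == "binary65") {
      vals$age <- as.numeric(vals$age > 65)
      desc$kind[desc$name == "age"] <- "binary"
    } else if (config$age_encoding == "standardized") {
      vals$age <- as.numeric(scale(vals$age))
    }
  }
  out <- feature_matrix(vals, desc, fm$meta)
  if (isTRUE(config$maxinfo_filter)) out <- maxinfo_filter(out, 4L)
  if (nrow(out$values) == 0L) stop("empty dataset after filtering")
  out
}

#' Per-site cohort composition summary
#'
#' Tabulates adjudicated etiology counts per site and pooled, with
#' percentages of each site's total rounded to one decimal, the way cohort
#' description tables are reported.
#'
#' @param meta Data frame with columns `site` and `toast` (codes 1--5), e.g.
#'   the `meta` component of a [feature_matrix()]. Alternatively a named list
#'   of per-site count vectors over the codes (printed-count input).
#' @return A data frame with one row per (site, etiology) plus pooled rows
#'   (`site = "pooled"`); columns `site`, `code`, `display`, `n`, `pct`.
#' @export
#' @examples
#' cohort_summary(list(A = c(`1` = 10, `2` = 20, `3` = 5, `4` = 5, `5` = 10)))
cohort_summary <- function(meta) {
  labs <- toast_labels()
  if (is.list(meta) && !is.data.frame(meta)) {
    counts <- lapply(meta, function(v) {
      v <- v[as.character(labs$code)]
      v[is.na(v)] <- 0
      as.numeric(v)
    })
  } else {
    if (nrow(meta) == 0L) stop("empty cohort")
    counts <- lapply(split(meta$toast, meta$site), function(x)
      as.numeric(table(factor(x, levels = labs$code))))
  }
  if (length(counts) == 0L) stop("empty cohort")
  counts$pooled <- Reduce(`+`, counts)
  out <- do.call(rbind, lapply(names(counts), function(s) {
    n <- counts[[s]]
    data.frame(site = s, code = labs$code, display = labs$display, n = n,
               pct = round(100 * n / sum(n), 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
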