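#' Write a cohort to CSV with a sidecar JSON schema
#'
#' The values and metadata go to `cohort.csv` (labels as the integer column
#' `toast`), the descriptor list and discretization rules to `schema.json`,
#' and optionally one rendered note per record under `notes/`, plus
#' `truth.csv` with the hidden latent classes when present.
#'
#' @param fm A [feature_matrix()].
#' @param dir Output directory (created if needed).
#' @param notes Also render and write per-record note files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(fm, dir, notes = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- fm$meta
  df <- cbind(meta[, setdiff(names(meta), "latent"), drop = FALSE], fm$values)
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE)
  schema <- list(descriptors = fm$descriptors,
                 discretization_rules = discretization_rules())
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(meta$latent))
    utils::write.csv(meta[, c("id", "latent")], file.path(dir, "truth.csv"),
                     row.names = FALSE)
  if (notes) {
    nd <- file.path(dir, "notes")
    dir.create(nd, showWarnings = FALSE)
    txt <- render_notes(fm)
    for (i in seq_along(txt))
      writeLines(txt[i], file.path(nd, paste0(meta$id[i], ".txt")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv` and `schema.json`.
#' @return A [feature_matrix()].
#' @export
read_cohort <- function(dir) {
  df <- utils::read.csv(file.path(dir, "cohort.csv"),
                        stringsAsFactors = FALSE)
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = TRUE)
  desc <- as.data.frame(schema$descriptors)
  meta_cols <- setdiff(names(df), desc$name)
  meta <- df[, meta_cols, drop = FALSE]
  tr <- file.path(dir, "truth.csv")
  if (file.exists(tr)) {
    truth <- utils::read.csv(tr, stringsAsFactors = FALSE)
    meta$latent <- truth$latent[match(meta$id, truth$id)]
  }
  feature_matrix(df[, desc$name, drop = FALSE], desc, meta)
}

#' Read a YAML configuration
#'
#' Recognized top-level keys mirror the tunable surfaces: `cutoffs` (rows
#' overriding [discretization_rules()]), `grids` (per-family data frames
#' overriding [default_grids()]), `impute` (`method`, `seed`), `pca`
#' (`thresholds`, `standardize`) and `generator` fields.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @keywords internal
"_PACKAGE"
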