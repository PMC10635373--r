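#' Default concept dictionary
#'
#' Maps each binary feature (CUI-style concept identifiers plus radiology,
#' cardiac and clinical-history indicators) to lowercase surface phrases, with
#' single-token negation cues and a token-window negation model. A toy
#' stand-in for full biomedical concept normalization: phrases are matched
#' literally, an indicator is 1 iff any occurrence of any phrase appears with
#' no negation cue within the preceding window.
#'
#' @param window Negation window in tokens (default 3).
#' @return A list with `entries` (named list id -> character phrases),
#'   `negation_cues`, `window`.
#' @export
default_concept_dictionary <- function(window = 3L) {
  entries <- list(
    C0004238 = c("atrial fibrillation", "afib"),
    C0020538 = c("hypertensive disease", "hypertension"),
    C0004153 = c("atherosclerosis"),
    C0398623 = c("hypercoagulability", "thrombophilia"),
    C0011849 = c("diabetes mellitus", "diabetes"),
    C0020473 = c("hyperlipidemia"),
    C0027051 = c("myocardial infarction"),
    C0149931 = c("migraine"),
    rad_frontal = c("frontal infarct"),
    rad_basal_ganglia = c("basal ganglia infarct"),
    rad_thalamus = c("thalamic infarct"),
    rad_mca_occlusion = c("middle cerebral artery occlusion"),
    rad_ica_occlusion = c("internal carotid artery occlusion"),
    rad_carotid_stenosis = c("carotid stenosis"),
    rad_hemorrhage = c("intracranial hemorrhage"),
    rad_cerebellar = c("cerebellar infarct"),
    hrt_left_atrial_enlargement = c("left atrial enlargement"),
    hrt_vegetation = c("valvular vegetation"),
    hrt_thrombus = c("intracardiac thrombus"),
    hrt_pfo = c("patent foramen ovale"),
    hrt_sinus_rhythm = c("sinus rhythm"),
    hex_tobacco = c("tobacco use"),
    hex_ethanol = c("alcohol use"),
    hex_drug_use = c("illicit drug use")
  )
  entries <- lapply(entries, tolower)
  list(entries = entries,
       negation_cues = c("no", "without", "denies"),
       window = as.integer(window))
}

# display names used in rendered laboratory/vital lines, keyed by feature
.numeric_display <- c(
  nihss = "NIHSS", systolic_bp = "Blood pressure",
  respiratory_rate = "Respiratory rate", ejection_fraction = "Ejection fraction",
  sodium = "Sodium", bun = "BUN", alt = "ALT", ast = "AST", wbc = "WBC",
  hematocrit = "Hematocrit", hemoglobin = "Hemoglobin",
  triglycerides = "Triglycerides", hdl = "HDL", ldl = "LDL", tsh = "TSH",
  ptt = "PTT", a1c = "A1C"
)

#' Render a synthetic discharge-summary note
#'
#' Turns one generated record into semi-structured text: an age/sex opener
#' ("<age> year old woman/man" with matching her/his pronouns), an NIHSS
#' line, vital-sign and laboratory lines ("Sodium 138.2"), imaging and
#' echocardiography phrases, and history phrases. Positive binary indicators
#' are embedded as their dictionary phrase, zero indicators as the negated
#' phrase ("No ..."), missing values are omitted. Section headers differ by
#' the record's site template style, content encoding does not, so every
#' embedded value is recoverable by [extract_note()].
#'
#' @param fm A [feature_matrix()] from [generate_cohort()].
#' @param i Row index of the record to render.
#' @param dict Concept dictionary (phrases used for rendering).
#' @return A single character string.
#' @export
render_note <- function(fm, i, dict = default_concept_dictionary()) {
  stopifnot(inherits(fm, "feature_matrix"), i >= 1, i <= nrow(fm$values))
  v <- fm$values[i, ]
  meta <- fm$meta[i, ]
  if (is.na(meta$age) || is.na(meta$sex)) stop("record demographics incomplete")
  style <- if (identical(meta$site, "site_b")) "b" else "a"
  female <- identical(meta$sex, "female")
  noun <- if (female) "woman" else "man"
  pro <- if (female) "Her" else "His"

  h <- function(a, b) if (style == "a") a else b
  num_line <- function(feat, unit = "") {
    x <- v[[feat]]
    if (is.null(x) || is.na(x)) return(NULL)
    paste0(.numeric_display[[feat]], " ", format(x, trim = TRUE, scientific = FALSE),
           unit, ".")
  }
  phrase_line <- function(feat) {
    x <- v[[feat]]
    if (is.null(x) || is.na(x)) return(NULL)
    p <- dict$entries[[feat]][1]
    if (x == 1) paste0(toupper(substring(p, 1, 1)), substring(p, 2), ".")
    else paste0("No ", p, ".")
  }
  grp_feats <- function(g, kind = NULL) {
    d <- fm$descriptors
    sel <- d$group == g & d$name %in% names(dict$entries)
    d$name[sel]
  }
  lines <- c(
    h("DISCHARGE SUMMARY", "FINAL SUMMARY OF HOSPITALIZATION"),
    h("HISTORY OF PRESENT ILLNESS:", "HPI:"),
    sprintf("The patient is a %d year old %s who presented with acute neurologic deficits.",
            as.integer(meta$age), noun),
    sprintf("%s initial exam was notable for focal deficits.", pro),
    num_line("nihss"),
    h("VITAL SIGNS:", "VITALS ON ADMISSION:"),
    if (!is.na(v$systolic_bp))
      sprintf("Blood pressure %d/%d.", as.integer(v$systolic_bp),
              as.integer(round(v$systolic_bp * 0.6))),
    num_line("respiratory_rate"),
    h("LABORATORY DATA:", "ADMISSION LABS:"),
    unlist(lapply(c("sodium", "bun", "alt", "ast", "wbc", "hematocrit",
                    "hemoglobin", "triglycerides", "hdl", "ldl", "tsh",
                    "ptt", "a1c"), num_line)),
    h("IMAGING:", "RADIOLOGY:"),
    unlist(lapply(grp_feats("RAD"), phrase_line)),
    h("CARDIAC STUDIES:", "CARDIOLOGY:"),
    num_line("ejection_fraction", unit = " %"),
    unlist(lapply(grp_feats("HRT"), phrase_line)),
    h("PAST MEDICAL HISTORY:", "PMH:"),
    unlist(lapply(grp_feats("CUI"), phrase_line)),
    h("SOCIAL HISTORY:", "SH:"),
    unlist(lapply(grp_feats("HEX"), phrase_line)),
    sprintf("%s hospital course was uncomplicated.", pro)
  )
  paste(unlist(lines), collapse = "\n")
}

#' Render every record of a cohort
#'
#' @inheritParams render_note
#' @return Character vector of notes, one per record.
#' @export
render_notes <- function(fm, dict = default_concept_dictionary()) {
  vapply(seq_len(nrow(fm$values)), function(i) render_note(fm, i, dict), "")
}

#' Extract age and sex from note text
#'
#' Age is parsed from the first "<integer> year old" pattern. Sex is assigned
#' by pronoun counting: female if "her" occurs more often than "his", male if
#' the reverse; equal counts (including both zero) yield a missing sex.
#'
#' @param text A single note string.
#' @return List with `age` (integer or `NA`) and `sex` (`"female"`,
#'   `"male"` or `NA`).
#' @export
#' @examples
#' extract_age_sex("72 year old woman ... her exam")
extract_age_sex <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  low <- tolower(text)
  m <- regmatches(low, regexpr("([0-9]+)[ -]year[ -]old", low))
  age <- if (length(m) == 0L) NA_integer_ else
    as.integer(sub("([0-9]+).*", "\\1", m))
  n_her <- sum(gregexpr("\\bher\\b", low)[[1]] > 0)
  n_his <- sum(gregexpr("\\bhis\\b", low)[[1]] > 0)
  sex <- if (n_her > n_his) "female" else if (n_his > n_her) "male" else NA_character_
  list(age = age, sex = sex)
}

# registered numeric extraction patterns (first match wins)
.numeric_patterns <- c(
  nihss = "\\bnihss[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  systolic_bp = "\\bblood pressure[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  respiratory_rate = "\\brespiratory rate[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  ejection_fraction = "\\bejection fraction[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  sodium = "\\bsodium[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  bun = "\\bbun[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  alt = "\\balt[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  ast = "\\bast[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  wbc = "\\bwbc[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  hematocrit = "\\bhematocrit[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  hemoglobin = "\\bhemoglobin[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  triglycerides = "\\btriglycerides[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  hdl = "\\bhdl[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  ldl = "\\bldl[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  tsh = "\\btsh[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  ptt = "\\bptt[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)",
  a1c = "\\ba1c[^0-9]{0,8}([0-9]+(\\.[0-9]+)?)"
)

#' Extract a registered numeric feature from note text
#'
#' The first occurrence of the feature's pattern wins; an unmatched pattern
#' yields `NA`, a malformed number yields `NA` with a warning.
#'
#' @param text A single note string.
#' @param feature One of the registered numeric features (NIHSS, blood
#'   pressure, respiratory rate, ejection fraction, or a laboratory value).
#' @return Numeric scalar or `NA`.
#' @export
#' @examples
#' extract_numeric("NIHSS 12 on arrival. Sodium 133.", "sodium")
extract_numeric <- function(text, feature) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!feature %in% names(.numeric_patterns))
    stop("no registered pattern for feature: ", feature)
  low <- tolower(text)
  m <- regexec(.numeric_patterns[[feature]], low)[[1]]
  if (m[1] == -1L) return(NA_real_)
  num <- substring(low, m[2], m[2] + attr(m, "match.length")[2] - 1L)
  out <- suppressWarnings(as.numeric(num))
  if (is.na(out)) warning("malformed number for feature ", feature)
  out
}

#' Tag concept indicators in note text
#'
#' Lowercases the text, matches every dictionary surface phrase, and sets an
#' indicator to 1 iff some occurrence of some phrase has no negation cue
#' within the preceding token window. Adding a non-negated occurrence can
#' therefore never flip an indicator from 1 to 0.
#'
#' @param text A single note string.
#' @param dict A dictionary from [default_concept_dictionary()].
#' @return Named integer vector of 0/1 indicators, one per dictionary entry.
#' @export
#' @examples
#' d <- default_concept_dictionary()
#' tag_concepts("history of atrial fibrillation", d)[["C0004238"]]
#' tag_concepts("no atrial fibrillation on telemetry", d)[["C0004238"]]
tag_concepts <- function(text, dict = default_concept_dictionary()) {
  stopifnot(length(dict$entries) > 0L)
  # negation scope never crosses a sentence/line boundary
  sentences <- strsplit(tolower(text), "[.;\n]+")[[1]]
  out <- stats::setNames(integer(length(dict$entries)), names(dict$entries))
  for (sent in sentences) {
    tok <- gregexpr("[a-z0-9']+", sent)[[1]]
    if (tok[1] == -1L) next
    tok_start <- as.integer(tok)
    tok_words <- regmatches(sent, list(tok))[[1]]
    for (id in names(dict$entries)) {
      if (out[[id]] == 1L) next
      for (phrase in dict$entries[[id]]) {
        pos <- gregexpr(paste0("\\b", phrase, "\\b"), sent)[[1]]
        pos <- pos[pos > 0]
        for (p in pos) {
          idx <- which(tok_start < p)          # tokens preceding the phrase
          win <- utils::tail(idx, dict$window)
          negated <- any(tok_words[win] %in% dict$negation_cues)
          if (!negated) { out[[id]] <- 1L; break }
        }
        if (out[[id]] == 1L) break
      }
    }
  }
  out
}

#' Extract all fields from a note
#'
#' Convenience wrapper combining [extract_age_sex()], every registered
#' [extract_numeric()] pattern and [tag_concepts()].
#'
#' @inheritParams tag_concepts
#' @return A named list: `age`, `sex`, one element per numeric feature, and
#'   one 0/1 element per dictionary concept.
#' @export
extract_note <- function(text, dict = default_concept_dictionary()) {
  demo <- extract_age_sex(text)
  nums <- lapply(names(.numeric_patterns), function(f) extract_numeric(text, f))
  names(nums) <- names(.numeric_patterns)
  c(demo, nums, as.list(tag_concepts(text, dict)))
}

#' Extract a cohort table from a set of notes
#'
#' @param texts Character vector of notes.
#' @inheritParams tag_concepts
#' @return Data frame with one row per note and one column per extracted
#'   field.
#' @export
extract_notes <- function(texts, dict = default_concept_dictionary()) {
  rows <- lapply(texts, function(tx) {
    f <- extract_note(tx, dict)
    f$sex <- if (is.na(f$sex)) NA_character_ else f$sex
    as.data.frame(f, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
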