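test_that("age and sex are recovered from text by pattern and pronouns", {
  r <- extract_age_sex("The patient is a 72 year old woman. Her exam was normal.")
  expect_equal(r$age, 72L)
  expect_equal(r$sex, "female")
  r2 <- extract_age_sex("His chest was clear. His gait was steady. His mood fine.")
  expect_equal(r2$sex, "male")
  expect_true(is.na(r2$age))
  # equal nonzero pronoun counts: sex stays missing rather than guessed
  r3 <- extract_age_sex("Her exam was stable and his records were reviewed.")
  expect_true(is.na(r3$sex))
  # pronouns are matched as words: 'history' and 'other' do not count
  r4 <- extract_age_sex("History of other conditions.")
  expect_true(is.na(r4$sex))
})

test_that("registered numeric patterns extract first-match values", {
  txt <- "NIHSS 12 initially, later NIHSS 4. Sodium 133. Blood pressure 150/90."
  expect_equal(extract_numeric(txt, "nihss"), 12)
  expect_equal(extract_numeric(txt, "sodium"), 133)
  expect_equal(extract_numeric(txt, "systolic_bp"), 150)
  expect_equal(discretize("sodium", extract_numeric(txt, "sodium")), "normal")
  expect_true(is.na(extract_numeric(txt, "ejection_fraction")))
  expect_error(extract_numeric(txt, "unregistered"), "no registered pattern")
})

test_that("concept tagging honors dictionary phrases and negation windows", {
  d <- default_concept_dictionary()
  expect_equal(tag_concepts("history of atrial fibrillation", d)[["C0004238"]], 1L)
  expect_equal(tag_concepts("no atrial fibrillation on telemetry", d)[["C0004238"]], 0L)
  expect_true(all(tag_concepts("", d) == 0L))
  # negation does not leak across sentence boundaries
  two <- "No intracardiac thrombus. Patent foramen ovale."
  tg <- tag_concepts(two, d)
  expect_equal(tg[["hrt_thrombus"]], 0L)
  expect_equal(tg[["hrt_pfo"]], 1L)
  # monotone: appending a non-negated occurrence never flips 1 -> 0
  base <- "atrial fibrillation was noted"
  for (extra in c(" and no atrial fibrillation later",
                  ". atrial fibrillation persisted")) {
    expect_equal(tag_concepts(paste0(base, extra), d)[["C0004238"]], 1L)
  }
})

test_that("rendered notes round-trip every embedded field exactly", {
  coh <- generate_cohort(generator_config(n = 50, seed = 77))
  notes <- render_notes(coh)
  ex <- extract_notes(notes)
  expect_equal(ex$age, coh$meta$age)
  expect_equal(ex$sex, coh$meta$sex)
  numeric_feats <- intersect(names(ex), coh$descriptors$name[
    coh$descriptors$kind == "continuous"])
  for (f in numeric_feats) {
    v <- coh$values[[f]]
    expect_equal(is.na(ex[[f]]), is.na(v), info = f)
    expect_equal(ex[[f]][!is.na(v)], v[!is.na(v)], info = f)
  }
  for (f in names(default_concept_dictionary()$entries)) {
    v <- coh$values[[f]]
    idx <- !is.na(v)
    expect_equal(ex[[f]][idx], as.integer(v[idx]), info = f)
  }
})

test_that("site templates differ in headers but not recoverable content", {
  cfg <- generator_config(n = 2, seed = 5, site_fractions = c(0.5, 0.5))
  coh <- suppressWarnings(generate_cohort(cfg))  # tiny-cohort warning expected
  coh$values[2, ] <- coh$values[1, ]
  coh$meta[2, c("age", "sex", "toast")] <- coh$meta[1, c("age", "sex", "toast")]
  coh$meta$site <- c("site_a", "site_b")
  n1 <- render_note(coh, 1); n2 <- render_note(coh, 2)
  expect_false(identical(strsplit(n1, "\n")[[1]][1], strsplit(n2, "\n")[[1]][1]))
  e1 <- extract_note(n1); e2 <- extract_note(n2)
  expect_equal(e1, e2)
})
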