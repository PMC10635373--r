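test_that("discretization follows the printed cutoff rules", {
  # one-cutoff rule: strictly above -> high, boundary and below -> normal
  expect_equal(discretize("nihss", c(8, 6, 3)), c("high", "normal", "normal"))
  expect_equal(discretize("sodium", c(137, 136, 120)),
               c("high", "normal", "normal"))
  # two-cutoff rule: between the cutoffs -> normal, strict boundaries
  expect_equal(discretize("hematocrit", c(40, 47, 30, 46, 35)),
               c("normal", "high", "low", "normal", "normal"))
  # sex-specific hemoglobin: 12.0 is low for a male, normal for a female
  expect_equal(discretize("hemoglobin", 12, sex = "male"), "low")
  expect_equal(discretize("hemoglobin", 12, sex = "female"), "normal")
  # missing propagates; already-discretized input is returned unchanged
  expect_true(is.na(discretize("nihss", NA_real_)))
  expect_equal(discretize("nihss", c("high", "normal")), c("high", "normal"))
  expect_error(discretize("not_a_feature", 1), "unknown feature")
  expect_error(discretize("hemoglobin", 12), "sex required")
})

test_that("the sixteen default rules ship and are total", {
  rules <- discretization_rules()
  expect_equal(nrow(rules), 16L)
  expect_true(all(rules$hi > rules$lo, na.rm = TRUE))
  for (f in unique(rules$feature)) {
    sexed <- !all(is.na(rules$sex[rules$feature == f]))
    v <- discretize(f, c(0.5, 50, 300),
                    sex = if (sexed) "female" else NULL)
    expect_true(all(v %in% c("high", "normal", "low")), info = f)
  }
})

test_that("the dataset registry enumerates the 24 configurations", {
  reg <- feature_group_registry()
  expect_length(reg, 24L)
  expect_true("combn1d.age.sex.v1" %in% names(reg))
  expect_equal(sum(vapply(reg, `[[`, TRUE, "maxinfo_filter")), 4L)
  expect_equal(sum(vapply(reg, `[[`, TRUE, "pca")), 4L)
})

test_that("build_dataset selects, discretizes and intersects columns", {
  coh <- small_cohort()
  ds <- build_dataset(coh, "combn1d.age.sex.v1")
  d <- coh$descriptors
  # full discretized set: all groups present, column count preserved
  expect_equal(ncol(ds$values), nrow(d))
  # rule-covered continuous HEX/LAB/EF features became categorical
  expect_true(all(ds$values$nihss %in% c("high", "normal", NA)))
  expect_true(all(ds$values$hemoglobin %in% c("high", "normal", "low", NA)))
  # identity subset on a single-group config
  cui <- build_dataset(coh, "cui")
  expect_equal(sort(names(cui$values)),
               sort(d$name[d$group == "CUI"]))
  expect_equal(cui$values, coh$values[, names(cui$values)])
  # cross-cohort intersection restricts to shared features
  donor <- coh
  drop <- c("tsh", "ptt", "a1c")
  donor$descriptors <- donor$descriptors[!donor$descriptors$name %in% drop, ]
  donor$values <- donor$values[, donor$descriptors$name]
  inter <- build_dataset(coh, "combn1d.age.sex.v1", other = donor)
  expect_equal(ncol(inter$values), nrow(d) - length(drop))
  expect_error(build_dataset(cui, "rad"), "absent")
})

test_that("MaxInfo keeps samples with enough observed categories", {
  coh <- small_cohort()
  fm <- coh
  # sample 1: blank out all HEX -> still 4 categories, kept at k = 4
  hex_cols <- fm$descriptors$name[fm$descriptors$group == "HEX"]
  lab_cols <- fm$descriptors$name[fm$descriptors$group == "LAB"]
  hrt_cols <- fm$descriptors$name[fm$descriptors$group == "HRT"]
  fm$values[1, hex_cols] <- NA
  # sample 2: only CUI + RAD observed -> dropped at k = 4
  fm$values[2, c(hex_cols, lab_cols, hrt_cols)] <- NA
  out <- maxinfo_filter(fm, 4)
  expect_true(fm$meta$id[1] %in% out$meta$id)
  expect_false(fm$meta$id[2] %in% out$meta$id)
  # fully observed cohort is unchanged
  full <- impute(coh, "pmm", seed = 1)
  expect_equal(nrow(maxinfo_filter(full, 5)$values), nrow(full$values))
})

test_that("cohort summaries report per-site percentages that close to 100", {
  cs <- cohort_summary(list(A = c(`1` = 10, `2` = 20, `3` = 5, `4` = 5,
                                  `5` = 10),
                            B = c(`1` = 3, `2` = 0, `3` = 1, `4` = 1, `5` = 5)))
  for (s in unique(cs$site))
    expect_lt(abs(sum(cs$pct[cs$site == s]) - 100), 0.3)
  expect_equal(cs$pct[cs$site == "B" & cs$code == 2], 0.0)
  # data-frame input path
  coh <- small_cohort()
  cs2 <- cohort_summary(coh$meta)
  expect_equal(sum(cs2$n[cs2$site == "pooled"]), nrow(coh$values))
  expect_error(cohort_summary(coh$meta[0, ]), "empty")
})

test_that("cohorts round-trip through CSV plus JSON schema", {
  coh <- generate_cohort(generator_config(n = 25, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, notes = TRUE)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "schema.json")))
  back <- read_cohort(dir)
  expect_equal(back$descriptors$name, coh$descriptors$name)
  expect_equal(back$meta$toast, coh$meta$toast)
  expect_equal(back$meta$latent, coh$meta$latent)
  expect_equal(back$values$sodium, coh$values$sodium)
  expect_length(list.files(file.path(dir, "notes")), 25L)
})
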