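test_that("generation is deterministic under the seed", {
  cfg <- generator_config(n = 80, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$meta, b$meta)
  c2 <- generate_cohort(generator_config(n = 80, seed = 100))
  expect_false(identical(a$values, c2$values))
})

test_that("label frequencies follow the configured priors", {
  coh <- acceptance_strong()$coh          # n = 2000, default priors
  priors <- c(0.21, 0.31, 0.13, 0.09, 0.26)
  n <- nrow(coh$values)
  freq <- as.numeric(table(factor(coh$meta$toast, 1:5))) / n
  se <- sqrt(priors * (1 - priors) / n)
  expect_true(all(abs(freq - priors) <= 3 * se))
})

test_that("zero-effect features carry no class signal", {
  coh <- generate_cohort(generator_config(n = 2000, seed = 21,
                                          effects = zero_effect_spec(),
                                          priors = c(0.25, 0.25, 0.25, 0.25, 0)))
  y <- coh$meta$toast
  for (f in c("C0004238", "rad_carotid_stenosis", "age", "nihss")) {
    v <- coh$values[[f]]
    keep <- !is.na(v)
    auc <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(response = y[keep] == 2, predictor = v[keep],
                levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))))
    expect_lt(abs(auc - 0.5), 0.05)
  }
})

test_that("missingness injection hits the configured group rates", {
  cfg <- generator_config(n = 1000, seed = 31,
                          sites = list(site_spec("s", missingness = c(LAB = 0))))
  coh <- generate_cohort(cfg)
  lab_cols <- coh$descriptors$name[coh$descriptors$group == "LAB"]
  expect_false(anyNA(coh$values[, lab_cols]))

  # rate 0.10: observed LAB completeness lands in [87%, 93%]
  m10 <- inject_missingness(coh, c(LAB = 0.10), seed = 1)
  comp <- mean(!is.na(as.matrix(m10$values[, lab_cols])))
  expect_gte(comp, 0.87); expect_lte(comp, 0.93)

  # rate 0.5: masked-cell count within 3 binomial SE of half
  m50 <- inject_missingness(coh, c(LAB = 0.5), seed = 2)
  cells <- length(lab_cols) * nrow(coh$values)
  miss <- sum(is.na(m50$values[, lab_cols]))
  expect_lt(abs(miss - cells / 2), 3 * sqrt(cells * 0.25))

  # observed cells unchanged
  same <- !is.na(m10$values$sodium)
  expect_equal(m10$values$sodium[same], coh$values$sodium[same])
})

test_that("the cryptogenic mixture controls latent classes and attenuation", {
  # no-class fraction 1: label 5 never carries a latent class
  cfg <- generator_config(n = 300, seed = 41,
                          cryptogenic = cryptogenic_spec(no_class_fraction = 1))
  coh <- generate_cohort(cfg)
  expect_true(all(is.na(coh$meta$latent[coh$meta$toast == 5])))
  expect_true(all(is.na(coh$meta$latent[coh$meta$toast != 5])))

  # stronger attenuation pulls cryptogenic-with-latent features toward the
  # latent class distribution (KS distance to class-2 AF rate decreases)
  ks_dist <- vapply(c(0.2, 1), function(a) {
    cc <- generate_cohort(generator_config(
      n = 4000, seed = 43,
      cryptogenic = cryptogenic_spec(attenuation = a, no_class_fraction = 0),
      sites = list(site_spec("s", missingness = c(CUI = 0)))))
    af <- cc$values$C0004238
    pure <- af[cc$meta$toast == 2]
    cry2 <- af[cc$meta$toast == 5 & !is.na(cc$meta$latent) & cc$meta$latent == 2]
    abs(mean(pure) - mean(cry2))
  }, 1)
  expect_lt(ks_dist[2], ks_dist[1])
})
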