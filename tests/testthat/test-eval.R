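test_that("the metric panel matches hand-computed confusion arithmetic", {
  perfect <- compute_metrics(c(1, 2, 3, 4, 1, 2, 3, 4), c(1, 2, 3, 4, 1, 2, 3, 4),
                             prob = diag(4)[c(1:4, 1:4), ])
  expect_equal(unname(perfect$overall[c("accuracy", "f1", "kappa", "aucroc")]),
               c(1, 1, 1, 1))
  # binary toy [[8,2],[3,7]]: po = 0.75, pe = 0.5, kappa = 0.5
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), rep(2, 2), rep(1, 3), rep(2, 7))
  m <- compute_metrics(truth, pred)
  expect_equal(unname(m$overall[["kappa"]]), 0.5)
  expect_equal(unname(m$overall[["accuracy"]]), 0.75)
  # accuracy equals class-support-weighted recall
  set.seed(13)
  t4 <- sample(1:4, 400, TRUE); p4 <- sample(1:4, 400, TRUE)
  m4 <- compute_metrics(t4, p4)
  w <- tabulate(t4, 4) / 400
  expect_equal(unname(m4$overall[["accuracy"]]),
               sum(w * m4$per_class$recall))
  expect_error(compute_metrics(rep(1, 10), rep(1, 10)), "two classes")
})

test_that("kappa is near zero for random labels over balanced classes", {
  set.seed(14)
  truth <- sample(1:4, 10000, TRUE)
  pred <- sample(1:4, 10000, TRUE)
  m <- compute_metrics(truth, pred)
  expect_lt(abs(m$overall[["kappa"]]), 0.05)
})

test_that("kappa bands follow the published bins", {
  expect_equal(kappa_band(0.629), "substantial")
  expect_equal(kappa_band(-0.1), "no agreement")
  expect_equal(kappa_band(0.41), "moderate")
  expect_equal(kappa_band(0.40), "fair")
  expect_equal(kappa_band(0.20), "slight")
  expect_equal(kappa_band(0.81), "almost perfect")
  expect_equal(kappa_band(0), "slight")
})

test_that("RMFCV splits partition exactly with balanced stratification", {
  y <- rep(1:4, times = c(30, 40, 20, 15))
  plan <- rmfcv_plan(folds = c(2, 5), reps = c(2, 1), base_seed = 9)
  sp <- rmfcv_splits(y, plan)
  expect_length(sp, 2 * 2 + 5)
  for (r in unique(vapply(sp, `[[`, 1L, "rep"))) {
    vals <- lapply(Filter(function(s) s$rep == r, sp), `[[`, "val")
    expect_equal(sort(unlist(vals)), seq_along(y))   # exact partition
    expect_equal(anyDuplicated(unlist(vals)), 0L)
  }
  # per-fold class counts differ from perfect apportionment by at most 1
  five <- Filter(function(s) s$folds == 5, sp)
  for (cc in 1:4) {
    per_fold <- vapply(five, function(s) sum(y[s$val] == cc), 1L)
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  # distinct repetitions use distinct derived seeds
  seeds <- unique(vapply(sp, `[[`, 1L, "seed"))
  expect_equal(length(seeds), 3L)
  expect_error(rmfcv_splits(rep(1:4, 3), rmfcv_plan()), "too small")
})

test_that("strata reports populate only observed age-sex cells", {
  set.seed(15)
  n <- 120
  truth <- sample(1:4, n, TRUE); pred <- truth
  pred[sample(n, 20)] <- sample(1:4, 20, TRUE)
  age <- rep(50, n); sex <- rep("female", n)
  rep1 <- strata_report(age, sex, truth, pred)
  expect_equal(rep1$n[rep1$stratum == "female"], n)
  expect_equal(rep1$n[rep1$stratum == "male"], 0)
  expect_true(is.na(rep1$accuracy[rep1$stratum == "male"]))
  expect_equal(rep1$n[rep1$stratum == "female,age<65"], n)
  # female + male sizes add to the total when sex is never missing
  sex2 <- sample(c("female", "male"), n, TRUE)
  age2 <- sample(40:90, n, TRUE)
  rep2 <- strata_report(age2, sex2, truth, pred)
  expect_equal(rep2$n[rep2$stratum == "female"] + rep2$n[rep2$stratum == "male"], n)
  expect_equal(rep2$n[rep2$stratum == "age>=65"] + rep2$n[rep2$stratum == "age<65"], n)
})

test_that("misclassification tables match a brute-force ranking", {
  set.seed(16)
  n <- 30
  truth <- rep(1:3, each = 10)
  pred <- truth; pred[c(1, 2, 11, 12, 21)] <- c(2, 3, 1, 3, 2)
  feats <- as.data.frame(matrix(rbinom(n * 12, 1, 0.5), n,
                                dimnames = list(NULL, paste0("f", 1:12))))
  tab <- misclassified_feature_table(truth, pred, feats, top = 10)
  for (cc in 1:3) {
    mis <- truth == cc & pred != cc
    cnt <- colSums(feats[mis, , drop = FALSE])
    brute <- names(cnt)[order(-cnt, names(cnt))][1:10]
    expect_equal(tab$feature[tab$class == cc], brute)
  }
  # a feature present everywhere counts every misclassified sample
  feats$always <- 1
  tab2 <- misclassified_feature_table(truth, pred, feats)
  expect_equal(tab2$count[tab2$class == 1 & tab2$feature == "always"],
               sum(truth == 1 & pred != 1))
  # no misclassification: empty table
  expect_equal(nrow(misclassified_feature_table(truth, truth, feats)), 0L)
})

test_that("univariate importance recovers planted effects and KS extremes", {
  expect_equal(unname(suppressWarnings(
    stats::ks.test(c(1, 2, 3), c(4, 5, 6))$statistic)), 1)
  set.seed(17)
  n <- 1000
  y <- sample(1:4, n, TRUE)
  x <- data.frame(noise1 = rnorm(n), noise2 = rnorm(n),
                  planted = rnorm(n) + (y == 2) * 1.5)
  imp <- univariate_importance(x, y)
  best <- imp[which.min(imp$t_p), ]
  expect_equal(best$feature, "planted")
  expect_equal(best$class, 2)
  # permuted labels: p-values behave like a null sample
  imp0 <- univariate_importance(x[, 1:2], sample(y))
  expect_gt(min(imp0$t_p), 1e-4)
})

test_that("Shapley attributions vanish for constant models and find markers", {
  set.seed(18)
  x <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("f", 1:5)))
  const <- function(z) matrix(0.25, nrow(z), 4)
  sh <- shap_adapter(const, x, background_k = 10, nsim = 5, seed = 1)
  expect_true(all(abs(sh$mean_abs) < 1e-12))
  # a model driven only by feature 1 ranks it first for its class
  f1model <- function(z) {
    p <- plogis(2 * z[, 1])
    cbind(p, (1 - p) / 3, (1 - p) / 3, (1 - p) / 3)
  }
  sh1 <- shap_adapter(f1model, x, background_k = 10, nsim = 10, seed = 2)
  expect_equal(sh1$ranking[["1"]][1], "f1")
  sh2 <- shap_adapter(f1model, x, background_k = 10, nsim = 10, seed = 2)
  expect_identical(sh1$mean_abs, sh2$mean_abs)
  expect_warning(out <- shap_adapter(const, x, y = rep(1:4, 10), nsim = 0),
                 "univariate")
  expect_true(is.data.frame(out))
})
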