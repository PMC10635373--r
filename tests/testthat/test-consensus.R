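test_that("ensemble statistics renormalize to hand-computed values", {
  rows <- rbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.6, 0.1, 0.1))
  expect_equal(ensemble_probs(rows, "MAX"),
               c(0.6, 0.6, 0.1, 0.1) / 1.4, tolerance = 1e-12)
  expect_equal(ensemble_probs(rows, "MIN"),
               c(0.2, 0.2, 0.1, 0.1) / 0.6, tolerance = 1e-12)
  # five identical rows: every statistic returns the row itself
  p <- c(0.4, 0.3, 0.2, 0.1)
  same <- matrix(rep(p, 5), 5, byrow = TRUE)
  for (s in c("MEAN", "MEDIAN", "MAX", "MIN"))
    expect_equal(ensemble_probs(same, s), p)
  # outputs are distributions; MEAN is permutation invariant
  set.seed(3)
  for (i in 1:20) {
    r <- matrix(stats::rexp(20), 5); r <- r / rowSums(r)
    for (s in c("MEAN", "MEDIAN", "MAX", "MIN"))
      expect_equal(sum(ensemble_probs(r, s)), 1)
    expect_equal(ensemble_probs(r, "MEAN"),
                 ensemble_probs(r[sample(5), ], "MEAN"))
    # pre-normalization ordering MAX >= MEAN >= MIN per class
    expect_true(all(apply(r, 2, max) >= colMeans(r) &
                      colMeans(r) >= apply(r, 2, min)))
  }
})

test_that("consensus voting counts nine members with stated tie-breaks", {
  u <- consensus_vote(rep(2, 9))
  expect_equal(u$label, 2); expect_equal(u$support, 9)
  v <- consensus_vote(c(1, 1, 1, 2, 2, 3, 3, 3, 3))
  expect_equal(v$label, 3); expect_equal(v$support, 4)
  expect_equal(unname(v$votes), c(3, 2, 4, 0))
  # 4-4 tie resolved by the higher MEAN-ensemble probability
  t1 <- consensus_vote(c(1, 1, 1, 1, 2, 2, 2, 2, 3), c(0.2, 0.5, 0.2, 0.1))
  expect_equal(t1$label, 2)
  # equal probabilities fall back to the lower class code
  t2 <- consensus_vote(c(1, 1, 1, 1, 2, 2, 2, 2, 3), rep(0.25, 4))
  expect_equal(t2$label, 1)
  # votes always total nine and plurality support is at least three
  set.seed(4)
  for (i in 1:50) {
    lab <- sample(1:4, 9, replace = TRUE)
    cv <- consensus_vote(lab, rep(0.25, 4))
    expect_equal(sum(cv$votes), 9)
    expect_gte(cv$support, 3)
  }
})

test_that("support thresholds interpolate quantiles per predicted class", {
  pred <- c(rep(1, 5), 2, 3, 4)
  sup <- c(7, 7, 8, 9, 9, 9, 9, 9)
  th <- quartile_thresholds(pred, sup, q = 0.25)
  expect_equal(th[["1"]], 7.0)
  expect_equal(th[["2"]], 9)
  expect_error(quartile_thresholds(rep(1, 4), rep(9, 4)), "never predicted")
  ref <- reference_thresholds()
  expect_equal(unname(ref[as.character(1:4)]), c(7, 9, 7.2, 7))
  expect_equal(attr(ref, "quantile"), 0.25)
})

test_that("cryptogenic reclassification abstains below class thresholds", {
  th <- reference_thresholds()
  out <- reclassify_cryptogenic(c(2, 3, 1, 4), c(9, 7, 7, 6), th)
  expect_equal(as.character(out),
               c("2", "persistently cryptogenic", "1",
                 "persistently cryptogenic"))
  # all-zero thresholds leave nothing cryptogenic
  none <- reclassify_cryptogenic(c(1, 2, 3, 4), c(3, 3, 3, 3),
                                 c(`1` = 0, `2` = 0, `3` = 0, `4` = 0))
  expect_false(any(none == "persistently cryptogenic"))
  # raising any threshold weakly increases the abstention count
  set.seed(6)
  pred <- sample(1:4, 200, TRUE); sup <- sample(3:9, 200, TRUE)
  base <- sum(reclassify_cryptogenic(pred, sup, th) == "persistently cryptogenic")
  for (cc in as.character(1:4)) {
    hi <- th; hi[cc] <- hi[cc] + 1
    expect_gte(sum(reclassify_cryptogenic(pred, sup, hi) ==
                     "persistently cryptogenic"), base)
  }
})

test_that("signature features flag class-specific prevalent indicators", {
  set.seed(7)
  n <- 200
  pred <- sample(1:4, n, TRUE)
  feats <- data.frame(
    everywhere = rep(1, n),
    class2_marker = ifelse(pred == 2, rbinom(n, 1, 0.9), rbinom(n, 1, 0.1)),
    rare = rbinom(n, 1, 0.05)
  )
  tab <- signature_features(pred, feats)
  expect_true("everywhere" %in% tab$feature)
  ev <- tab[tab$feature == "everywhere", ]
  expect_equal(ev$p_value, 1)
  expect_false(ev$class_specific)
  cm <- tab[tab$feature == "class2_marker", ]
  expect_lt(cm$p_value, 0.01)
  expect_true(cm$class_specific)
  expect_false("rare" %in% tab$feature)
  # chi-squared statistic matches the textbook 2x2 value without correction
  stat <- unname(stats::chisq.test(matrix(c(30, 10, 10, 30), 2),
                                   correct = FALSE)$statistic)
  expect_equal(stat, 20)
  expect_warning(signature_features(rep(1, 10), feats[1:10, , drop = FALSE]),
                 "no samples")
})
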