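test_that("ROC points and trapezoid AUC match concordance on frozen cases", {
  # perfect separation
  expect_equal(roc_points(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  # cases {1,2} vs non-cases {0,1}: concordance = (1 + .5 + 1 + 1)/4 = 0.875
  expect_equal(roc_points(c(1, 2, 0, 1), c(1, 1, 0, 0))$auc, 0.875)
  # label flip complements the AUC
  expect_equal(roc_points(c(1, 2, 0, 1), c(0, 0, 1, 1))$auc, 1 - 0.875)
  # constant scores
  expect_equal(auc_with_ci(rep(3, 20), rep(c(0, 1), 10))$auc, 0.5)
  expect_error(roc_points(1:5, rep(1, 5)), "degenerate")
})

test_that("trapezoid AUC equals brute-force pairwise concordance on random data", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(0:7, n, replace = TRUE)
    expect_equal(roc_points(s, y)$auc, auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong AUC interval agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  s <- c(rnorm(60, 1), rnorm(80))
  y <- rep(c(1, 0), c(60, 80))
  mine <- auc_with_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, ci[c(1, 3)], tolerance = 1e-8)

  # also on a discrete 0-7 score with heavy ties
  si <- sample(0:7, 150, replace = TRUE, prob = c(4, 3, 2, 2, 1, 1, 1, 1))
  yi <- rbinom(150, 1, plogis(si - 3))
  mi <- auc_with_ci(si, yi)
  ri <- pROC::roc(yi, si, quiet = TRUE, direction = "<")
  expect_equal(mi$auc, as.numeric(pROC::auc(ri)), tolerance = 1e-12)
  expect_equal(mi$ci, as.numeric(pROC::ci.auc(ri, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
})

test_that("cutoff table arithmetic, intervals and edge cases are correct", {
  # TP=8, FP=2, FN=2, TN=8 at cutoff 1 on binary scores
  s <- rep(c(1, 0, 1, 0), c(8, 2, 2, 8))
  y <- rep(c(1, 1, 0, 0), c(8, 2, 2, 8))
  ct <- cutoff_table(s, y, 1)
  expect_equal(ct$sn, 0.8)
  expect_equal(ct$sp, 0.8)
  expect_equal(ct$ppv, 0.8)
  expect_equal(ct$npv, 0.8)
  expect_equal(ct$efficiency, 0.8)
  expect_equal(ct$youden_sum, 1.6)
  expect_equal(ct$youden_j, 0.6)
  # Clopper-Pearson interval equals binom.test
  expect_equal(c(ct$sn_lo, ct$sn_hi),
               as.numeric(binom.test(8, 10)$conf.int))

  sim <- simulate_cohort(sim_config(seed = 35))
  m <- sim$cohort$responses[, scale_items7]
  sc <- rowSums(m); y2 <- sim$cohort$caseness
  tab <- cutoff_table(sc, y2, 1:7)
  # SN non-increasing, SP non-decreasing in the cutoff
  expect_true(all(diff(tab$sn) <= 0))
  expect_true(all(diff(tab$sp) >= 0))
  # PPV/NPV via Bayes from SN, SP and prevalence agree exactly
  prev <- mean(y2)
  bayes_ppv <- tab$sn * prev / (tab$sn * prev + (1 - tab$sp) * (1 - prev))
  bayes_npv <- tab$sp * (1 - prev) / (tab$sp * (1 - prev) + (1 - tab$sn) * prev)
  expect_equal(tab$ppv, bayes_ppv, tolerance = 1e-12)
  expect_equal(tab$npv, bayes_npv, tolerance = 1e-12)
  # perfect-specificity cutoffs flag an infinite PLR; SN = 1 gives NLR 0
  if (any(tab$sp == 1)) expect_true(all(tab$plr_infinite[tab$sp == 1]))
  if (any(tab$sn == 1)) expect_true(all(tab$nlr[tab$sn == 1] == 0))
  expect_error(cutoff_table(sc, y2, 99), "range")
})

test_that("cut-score selection maximizes the Youden sum and privileges sensitivity", {
  pub <- starmh_published_cutoffs()
  tab <- data.frame(cutoff = pub$cutoff, sn = pub$sn_pct / 100,
                    youden_sum = (pub$sn_pct + pub$sp_pct) / 100)
  sel <- youden_select(tab, sn_floor = 0.90)
  expect_equal(sel$optimal_cutoff, 3)
  expect_equal(sel$sensitivity_privileged_cutoff, 2)
  # ties resolve to the lower cutoff
  tie <- data.frame(cutoff = c(2, 3), sn = c(0.9, 0.8), youden_sum = c(1.5, 1.5))
  expect_equal(youden_select(tie)$optimal_cutoff, 2)
})

test_that("optimism correction is seed-deterministic and near-null for noise scores", {
  set.seed(36)
  y <- rbinom(200, 1, 0.33)
  s <- sample(0:7, 200, replace = TRUE)
  o1 <- optimism_corrected_auc(s, y, n_boot = 100, seed = 9)
  o2 <- optimism_corrected_auc(s, y, n_boot = 100, seed = 9)
  expect_identical(o1$corrected_auc, o2$corrected_auc)
  expect_lte(o1$corrected_auc, o1$apparent_auc + 0.01)
  expect_lt(abs(o1$apparent_auc - 0.5), 0.1)

  # monotone-link invariance: apparent AUC equals the raw score's rank AUC
  sim <- simulate_cohort(sim_config(seed = 37))
  sc <- rowSums(sim$cohort$responses[, scale_items7])
  cs <- sim$cohort$caseness
  o <- optimism_corrected_auc(sc, cs, n_boot = 60, seed = 10)
  expect_equal(o$apparent_auc, auc_with_ci(sc, cs)$auc, tolerance = 1e-12)
})
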