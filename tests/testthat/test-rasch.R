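test_that("elementary symmetric functions match brute-force pattern enumeration", {
  set.seed(4)
  for (m in c(3, 6, 10)) {
    eps <- exp(runif(m, -2, 2))
    expect_equal(esf(eps), esf_brute(eps), tolerance = 1e-10)
  }
})

test_that("two-item CML recovers the closed-form log odds of discordant patterns", {
  # n10 = 9, n01 = 3 -> beta2 - beta1 = ln 3; sum-zero (-0.549, +0.549)
  x <- rbind(matrix(c(1L, 0L), 9, 2, byrow = TRUE),
             matrix(c(0L, 1L), 3, 2, byrow = TRUE),
             matrix(c(1L, 1L), 5, 2, byrow = TRUE),
             matrix(c(0L, 0L), 4, 2, byrow = TRUE))
  colnames(x) <- c("one", "two")
  fit <- fit_cml(x)
  expect_equal(unname(diff(fit$difficulties)), log(3), tolerance = 1e-7)
  expect_equal(unname(fit$difficulties), c(-log(3) / 2, log(3) / 2),
               tolerance = 1e-7)

  # symmetric discordant counts -> both difficulties zero
  xs <- rbind(matrix(c(1L, 0L), 6, 2, byrow = TRUE),
              matrix(c(0L, 1L), 6, 2, byrow = TRUE),
              matrix(c(1L, 1L), 4, 2, byrow = TRUE))
  colnames(xs) <- c("one", "two")
  expect_equal(unname(fit_cml(xs)$difficulties), c(0, 0), tolerance = 1e-8)
})

test_that("fitted difficulties are sum-zero and reproduce the item margins", {
  m <- sim_scale_matrix(n = 250, seed = 12)
  fit <- suppressWarnings(fit_cml(m))
  expect_true(fit$converged)
  expect_lt(abs(sum(fit$difficulties)), 1e-8)
  # margin reproduction: conditional expected item scores equal observed
  scores <- sort(unique(fit$raw_scores[fit$raw_scores > 0 & fit$raw_scores < 7]))
  n_r <- as.numeric(table(factor(fit$raw_scores[fit$raw_scores > 0 &
                                                  fit$raw_scores < 7],
                                 levels = scores)))
  cp <- starmh:::cml_cond_probs(-fit$difficulties, scores)
  expect_equal(unname(colSums(n_r * cp$pi1)), unname(fit$item_margins),
               tolerance = 1e-6)
})

test_that("inestimable items are named and degenerate inputs rejected", {
  m <- sim_scale_matrix(n = 80, seed = 13)
  m[, "crazy"] <- 0L
  expect_error(suppressWarnings(fit_cml(m)), "crazy")
  expect_error(fit_cml(m[, 1, drop = FALSE]), ">= 2 items")
})

test_that("ML abilities solve the score equation and are monotone in raw score", {
  # 7 items all beta = 0, raw score 5 -> theta = ln(5/2)
  b0 <- setNames(rep(0, 7), paste0("i", 1:7))
  expect_equal(starmh:::solve_ability(b0, 5), log(5 / 2), tolerance = 1e-8)

  # symmetric difficulty set, raw m/2 -> theta 0
  bs <- setNames(c(-1, -0.5, 0.5, 1), paste0("i", 1:4))
  expect_equal(starmh:::solve_ability(bs, 2), 0, tolerance = 1e-8)

  m <- sim_scale_matrix(n = 200, seed = 14)
  fit <- suppressWarnings(fit_cml(m))
  ab <- estimate_abilities(fit)
  st <- fit$score_table
  expect_true(all(diff(st$theta[!st$extreme]) > 0))
  expect_true(all(is.na(ab$theta[ab$extreme])))
  expect_true(all(ab$extreme[ab$raw_score %in% c(0, 7)]))
  # ability depends on the raw score only
  expect_equal(ab$theta, st$theta[ab$raw_score + 1L])
})

test_that("difficulty recovery from the published truth is accurate at n = 1000", {
  set.seed(140)
  truth <- setNames(starmh_difficulties()$difficulty, scale_items7)
  # trait N(0, 1.5): the standard recovery design for these difficulties
  rmse2 <- replicate(5, {
    m <- sim_scale_matrix(n = 1000, seed = sample.int(1e6, 1),
                          trait_mean_noncase = 0, trait_mean_case = 0,
                          trait_sd = 1.5)
    fit <- suppressWarnings(fit_cml(m))
    mean((fit$difficulties[scale_items7] - truth)^2)
  })
  expect_lt(sqrt(mean(rmse2)), 0.10)
})

test_that("CML difficulties are invariant to a location shift of the abilities", {
  set.seed(15)
  truth <- setNames(starmh_difficulties()$difficulty, scale_items7)
  gen <- function(th) {
    p <- plogis(outer(th, truth, "-"))
    array(rbinom(length(p), 1L, p), dim(p), dimnames = list(NULL, names(truth)))
  }
  th <- rnorm(3000, 0, 1.5)
  f1 <- suppressWarnings(fit_cml(gen(th)))
  f2 <- suppressWarnings(fit_cml(gen(th + 1.5)))
  expect_lt(max(abs(f1$difficulties - f2$difficulties)), 0.15)
})

test_that("item fit statistics are calibrated under the model and detect miscoding", {
  set.seed(16)
  truth <- setNames(starmh_difficulties()$difficulty, scale_items7)
  in_band <- logical(0)
  for (i in 1:40) {
    th <- rnorm(500, -0.5, 1.5)
    p <- plogis(outer(th, truth, "-"))
    m <- array(rbinom(length(p), 1L, p), dim(p),
               dimnames = list(NULL, names(truth)))
    fit <- suppressWarnings(fit_cml(m))
    fi <- item_fit(fit)
    in_band <- c(in_band, fi$outfit_msq > 0.60 & fi$outfit_msq < 1.40 &
                   fi$infit_msq > 0.60 & fi$infit_msq < 1.40)
    if (i == 1) {
      expect_true(all(fi$p_bonferroni >= 0 & fi$p_bonferroni <= 1))
      expect_equal(fi$chi2, fi$outfit_msq * fi$df + fi$outfit_msq,
                   tolerance = 1e-6)  # chi2 = n * outfit, df = n - 1
    }
  }
  expect_gte(mean(in_band), 0.95)

  # a deliberately inverted item misfits on outfit
  m <- sim_scale_matrix(n = 500, seed = 17)
  m[, "pain"] <- 1L - m[, "pain"]
  fit <- suppressWarnings(fit_cml(m))
  fi <- item_fit(fit)
  expect_gt(fi$outfit_msq[fi$item == "pain"], 1.40)
  expect_true(fi$misfit[fi$item == "pain"])
})

test_that("reliability indices behave at independence and degenerate spread", {
  # statistically independent coin items: mean inter-item r near zero
  set.seed(18)
  coins <- array(rbinom(1000 * 6, 1L, 0.5), c(1000, 6),
                 dimnames = list(NULL, paste0("c", 1:6)))
  fit <- suppressWarnings(fit_cml(coins))
  rel <- reliability(fit, coins)
  expect_lt(abs(rel$mean_interitem_r), 0.05)

  # every person at the same raw score: ability variance zero, PSI undefined
  pat <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L), c(1L, 0L, 1L, 0L))
  m0 <- pat[rep(1:3, each = 12), ]
  colnames(m0) <- paste0("i", 1:4)
  f0 <- fit_cml(m0)
  r0 <- reliability(f0, m0)
  expect_false(r0$psi_defined)
  expect_true(is.na(r0$psi))
})
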