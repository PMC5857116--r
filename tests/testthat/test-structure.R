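test_that("bivariate normal CDF matches a numerical-integration oracle", {
  oracle <- function(h, k, r) {
    integrate(function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2)),
              -Inf, h, rel.tol = 1e-12)$value
  }
  for (v in list(c(0.3, -0.7, 0.6), c(-1, 1.5, -0.8), c(0, 0, 0.3),
                 c(2, 2, 0.95), c(-0.5, 0.5, 0))) {
    expect_equal(pbvnorm(v[1], v[2], v[3]), oracle(v[1], v[2], v[3]),
                 tolerance = 1e-9)
  }
})

test_that("tetrachoric correlation recovers the latent correlation", {
  set.seed(19)
  z1 <- rnorm(5000)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(5000)
  tab <- table(factor(as.integer(z1 > 0.5), levels = 0:1),
               factor(as.integer(z2 > 0.2), levels = 0:1))
  expect_equal(tetrachoric_2x2(tab), 0.5, tolerance = 0.07)

  # a zero cell gets the continuity correction rather than +/-1
  tab0 <- matrix(c(10, 0, 5, 10), 2)
  expect_true(abs(tetrachoric_2x2(tab0)) < 0.999)

  m <- sim_scale_matrix(n = 150, seed = 20)
  R <- tetrachoric_matrix(m)
  expect_true(isSymmetric(R))
  expect_equal(unname(diag(R)), rep(1, 7))
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
})

test_that("fixed-margin sampler preserves every margin and reaches the full set", {
  m <- sim_scale_matrix(n = 40, seed = 22)
  smp <- sample_fixed_margins(m, margin_sampler(burn_in = 50, thin = 4,
                                                n_samples = 50, seed = 1))
  rs <- unname(rowSums(m)); cs <- unname(colSums(m))
  for (s in seq_len(dim(smp)[3])) {
    expect_identical(rowSums(smp[, , s]), rs)
    expect_identical(colSums(smp[, , s]), cs)
  }

  # 2x2 identity: the reference set is exactly {itself, the swap}
  x2 <- rbind(c(1L, 0L), c(0L, 1L))
  dimnames(x2) <- list(c("a", "b"), c("i", "j"))
  s2 <- sample_fixed_margins(x2, margin_sampler(10, 1, 300, seed = 2))
  keys <- apply(s2, 3, paste, collapse = "")
  expect_setequal(unique(keys), c("1001", "0110"))
})

test_that("the sampler is uniform over an exhaustively enumerated reference set", {
  set.seed(23)
  x <- array(rbinom(24, 1L, 0.5), c(6, 4),
             dimnames = list(paste0("p", 1:6), paste0("i", 1:4)))
  ref <- enum_fixed_margins(rowSums(x), colSums(x))
  expect_gt(length(ref), 3)
  ref_keys <- vapply(ref, paste, character(1), collapse = "")
  smp <- sample_fixed_margins(x, margin_sampler(burn_in = 100, thin = 25,
                                                n_samples = 4000, seed = 3))
  keys <- apply(smp, 3, paste, collapse = "")
  expect_true(all(keys %in% ref_keys))
  counts <- table(factor(keys, levels = ref_keys))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("T1 reports all pairs, pins duplicated items, ignores person order", {
  m <- sim_scale_matrix(n = 120, seed = 24)
  t1 <- ponocny_t1(m, margin_sampler(200, 8, 300, seed = 4))
  expect_equal(nrow(t1), choose(7, 2))
  expect_true(all(t1$p >= 1 / 301 & t1$p <= 1))

  # duplicated item: agreement is maximal, p at the smallest attainable level
  md <- cbind(m[, 1:3], dup = m[, 3])
  colnames(md) <- c(colnames(m)[1:3], "dup")
  t1d <- ponocny_t1(md, margin_sampler(200, 8, 300, seed = 5))
  dup_row <- t1d[t1d$item_i == colnames(m)[3] & t1d$item_j == "dup", ]
  expect_equal(dup_row$statistic, nrow(md))
  expect_lt(dup_row$p, 0.05)
  expect_true(dup_row$flagged)

  # person reordering: identical statistics, p equal up to Monte Carlo error
  perm <- sample(nrow(m))
  t1p <- ponocny_t1(m[perm, ], margin_sampler(200, 8, 300, seed = 6))
  expect_identical(t1$statistic, t1p$statistic)
  # p-values agree up to Monte Carlo resampling error
  expect_lt(max(abs(t1$p - t1p$p)), 0.25)
})

test_that("parallel analysis is deterministic under a seed and monotone in the statistic", {
  m <- sim_scale_matrix(n = 150, seed = 25)
  fit <- suppressWarnings(fit_cml(m))
  pa1 <- modified_parallel_analysis(m, fit, n_mc = 100, seed = 42)
  pa2 <- modified_parallel_analysis(m, fit, n_mc = 100, seed = 42)
  expect_identical(pa1$p, pa2$p)
  expect_identical(pa1$null_second_eigenvalues, pa2$null_second_eigenvalues)
  expect_true(pa1$p >= 0 && pa1$p <= 1)

  # holding the null sample fixed, p is monotone in the observed eigenvalue
  nulls <- pa1$null_second_eigenvalues
  p_of <- function(obs) (1 + sum(nulls >= obs)) / (length(nulls) + 1)
  obs_grid <- sort(runif(20, min(nulls), max(nulls)))
  expect_true(all(diff(vapply(obs_grid, p_of, numeric(1))) <= 0))

  expect_error(modified_parallel_analysis(m, fit, n_mc = 50), ">= 100")
})
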