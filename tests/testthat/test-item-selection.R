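test_that("diagnostic filter computes SN/SP/kappa and retains correctly", {
  set.seed(1)
  case <- rbinom(200, 1L, 0.4)
  m <- cbind(perfect = case,
             coin = rbinom(200, 1L, 0.5))
  storage.mode(m) <- "integer"
  rec <- item_diagnostic_filter(m, case)
  perf <- rec[rec$item == "perfect", ]
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$kappa, 1)
  expect_true(perf$retained)
  expect_false(rec$retained[rec$item == "coin"])
  expect_error(item_diagnostic_filter(m, rep(1L, 200)), "degenerate")

  # 2x2 arithmetic: TP=8, FN=2, FP=3, TN=7
  item <- rep(c(1L, 0L, 1L, 0L), c(8, 2, 3, 7))
  cs <- rep(c(1L, 1L, 0L, 0L), c(8, 2, 3, 7))
  r2 <- item_diagnostic_filter(cbind(x = item), cs, sn_min = 0, sp_min = 0)
  expect_equal(r2$sensitivity, 0.80)
  expect_equal(r2$specificity, 0.70)
  expect_equal(r2$predictive_accuracy, 0.75)
})

test_that("kappa z-test holds its type-I rate for independent items", {
  set.seed(202)
  retained <- logical(800)
  for (i in seq_along(retained)) {
    item <- array(rbinom(500, 1L, 0.3), c(500, 1), dimnames = list(NULL, "x"))
    case <- rbinom(500, 1L, 0.33)
    retained[i] <- item_diagnostic_filter(item, case,
                                          sn_min = 0, sp_min = 0)$retained
  }
  rate <- mean(retained)
  expect_lte(rate, 0.05 * 1.4)
  expect_gte(rate, 0.02)
})

test_that("Spearman/accuracy filter applies both floors; rho equals phi for binary pairs", {
  set.seed(7)
  case <- rbinom(300, 1L, 0.4)
  m <- cbind(same = case, weak = rbinom(300, 1L, 0.4))
  storage.mode(m) <- "integer"
  rec <- item_diagnostic_filter(m, case, sn_min = 0, sp_min = 0)
  out <- spearman_accuracy_filter(rec)
  expect_true(out$retained[out$item == "same"])
  expect_equal(out$spearman_rho[out$item == "same"], 1)

  # TP=8, TN=7, N=20 -> accuracy 0.75 drops at floor 0.85
  expect_false(out$retained[out$item == "weak"] &&
                 out$predictive_accuracy[out$item == "weak"] < 0.85)

  # Spearman rho of two binary vectors equals the Pearson phi coefficient:
  # brute-force rank computation as oracle over 100 random pairs
  for (i in 1:100) {
    a <- rbinom(40, 1, runif(1, 0.2, 0.8))
    b <- rbinom(40, 1, runif(1, 0.2, 0.8))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(cor(rank(a), rank(b)), cor(a, b), tolerance = 1e-12)
  }

  # order stability: sequential filters equal the joint predicate
  joint <- rec$retained & rec$spearman_rho >= 0.7 & rec$predictive_accuracy >= 0.85
  expect_identical(out$retained, joint)
})

test_that("CART retention finds split items, including jointly predictive pairs", {
  set.seed(11)
  n <- 400
  case <- rbinom(n, 1L, 0.4)
  m <- cbind(signal = case, n1 = rbinom(n, 1L, 0.5), n2 = rbinom(n, 1L, 0.5))
  storage.mode(m) <- "integer"
  cs <- cart_select(m, case)
  # exhaustive split-enumeration oracle: the item with the largest Gini gain
  gini_gain <- function(x, y) {
    imp <- function(p) 2 * p * (1 - p)
    p <- mean(y)
    pl <- mean(y[x == 0]); pr <- mean(y[x == 1])
    imp(p) - mean(x == 0) * imp(pl) - mean(x == 1) * imp(pr)
  }
  gains <- apply(m, 2, gini_gain, y = case)
  expect_equal(as.character(cs$tree$frame$var[1]), names(which.max(gains)))
  expect_true("signal" %in% cs$retained)

  # XOR-like pair: jointly but not marginally predictive
  a <- rbinom(n, 1L, 0.5); b <- rbinom(n, 1L, 0.5)
  y <- as.integer(xor(a, b))
  flip <- rbinom(n, 1L, 0.05) == 1L
  y[flip] <- 1L - y[flip]
  mx <- cbind(ia = a, ib = b, nz = rbinom(n, 1L, 0.5))
  storage.mode(mx) <- "integer"
  cx <- cart_select(mx, y)
  expect_true(all(c("ia", "ib") %in% cx$retained))

  # depth 0 returns nothing; constant caseness errors
  expect_length(cart_select(m, case, max_depth = 0L)$retained, 0L)
  expect_error(cart_select(m, rep(1L, n)), "degenerate")

  # person-shuffling invariance of the retained set
  perm <- sample(n)
  cp <- cart_select(m[perm, ], case[perm])
  expect_setequal(cp$retained, cs$retained)
})

test_that("endorsement-specificity curves flag items endorsed at rest-score 0", {
  # item endorsed by 30% of persons whose other items are all 0
  set.seed(5)
  n <- 400
  others <- array(0L, c(n, 2), dimnames = list(NULL, c("a", "b")))
  others[1:100, "a"] <- 1L
  sleepy <- integer(n)
  rest0 <- rowSums(others) == 0
  sleepy[rest0] <- rbinom(sum(rest0), 1L, 0.30)
  m <- cbind(others, sleepy = sleepy)
  res <- endorsement_specificity_flag(m, threshold = 0.25)
  expect_true("sleepy" %in% res$flagged)
  expect_false("b" %in% res$flagged)  # never endorsed at rest-score 0
  ok <- !is.na(res$curves$prop_endorsed)
  expect_true(all(res$curves$prop_endorsed[ok] >= 0 &
                    res$curves$prop_endorsed[ok] <= 1))
  expect_true(all(c("rest_score") %in% names(res$curves)))
  expect_true(all(c("total_score") %in% names(res$curves_total)))
})

test_that("under the Rasch generator only the easy item approaches the flag level", {
  # two items at difficulty -2 and +2 under a matched trait distribution:
  # the easy item is endorsed at rest-score 0 far more often
  set.seed(31)
  n <- 5000
  th <- rnorm(n, -1, 1.5)
  diffs <- c(easy = -2, hard = 2, mid1 = 0, mid2 = 0)
  p <- plogis(outer(th, diffs, "-"))
  m <- array(rbinom(n * 4, 1L, p), dim(p), dimnames = list(NULL, names(diffs)))
  res <- endorsement_specificity_flag(m, threshold = 0.30)
  at0 <- res$curves[res$curves$rest_score == 0, ]
  expect_gt(at0$prop_endorsed[at0$item == "easy"],
            at0$prop_endorsed[at0$item == "hard"] + 0.1)
  expect_false("hard" %in% res$flagged)
})
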