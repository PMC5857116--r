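test_that("cohort CSV loading round-trips, counts malformed cells, enforces integrity", {
  df <- data.frame(person_id = c("a", "b", "c"),
                   i1 = c(1, 0, 1), i2 = c(0, 1, 1), i3 = c(1, 1, 0),
                   mini_mdd = c(1, 0, 0), mini_ptsd = c(0, 0, 1),
                   sex = c("m", "f", "m"))
  sch <- cohort_schema(items = c("i1", "i2", "i3"), covariates = "sex")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(df, path, row.names = FALSE)
  co <- load_cohort(path, sch)
  expect_equal(n_persons(co), 3L)
  expect_equal(unname(co$responses[, "i1"]), c(1L, 0L, 1L))
  expect_equal(unname(co$caseness), c(1L, 0L, 1L))
  expect_equal(co$covariates$sex, df$sex)
  expect_equal(attr(co, "n_malformed"), 0L)

  # write -> reload round-trips bit-identically
  out <- data.frame(person_id = rownames(co$responses), co$responses,
                    mini_mdd = df$mini_mdd, mini_ptsd = df$mini_ptsd,
                    sex = df$sex)
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  write.csv(out, path2, row.names = FALSE)
  expect_identical(load_cohort(path2, sch)$responses, co$responses)

  # "NA"/"NaN"/"" are accepted missing spellings, anything else is malformed
  df$i2 <- c("0", "NA", "oops")
  write.csv(df, path, row.names = FALSE)
  expect_warning(co3 <- load_cohort(path, sch), "1 malformed")
  expect_true(all(is.na(co3$responses[2:3, "i2"])))
  expect_equal(attr(co3, "n_malformed"), 1L)

  df$person_id <- c("a", "a", "c")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_cohort(path, sch), "integrity")
  expect_error(load_cohort(path, cohort_schema(items = "nope")), "schema")
})

test_that("Likert dichotomization maps >= threshold to 1 and rejects bad input", {
  long <- data.frame(person_id = rep("p1", 4),
                     item_id = paste0("q", 1:4), value = 1:4)
  bm <- dichotomize_likert(long, threshold = 3L)
  expect_equal(unname(bm["p1", ]), c(0L, 0L, 1L, 1L))

  wide <- rbind(c(1, 3, NA), c(4, 2, 2))
  colnames(wide) <- paste0("q", 1:3)
  bm2 <- dichotomize_likert(wide, 3L)
  expect_equal(unname(bm2[1, ]), c(0L, 1L, NA))
  expect_error(dichotomize_likert(wide, 1L), "threshold")
  expect_error(dichotomize_likert(rbind(c(1, 5, 2)), 3L), "non-Likert")
  expect_error(dichotomize_likert(rbind(long, long[1, ]), 3L), "duplicate")

  # idempotence: re-encoding binary data as Likert endpoints and
  # re-dichotomizing is the identity
  b <- sim_scale_matrix(n = 40, seed = 2)
  lik <- ifelse(b == 1L, 4L, 1L)
  expect_identical(unname(dichotomize_likert(lik, 3L)), unname(b))
})

test_that("incomplete-case dropping reproduces the 7-of-192 accounting", {
  set.seed(10)
  resp <- array(rbinom(192 * 7, 1L, 0.3), c(192, 7),
                dimnames = list(sprintf("p%03d", 1:192), scale_items7))
  resp[cbind(sample(192, 7), sample(7, 7, replace = TRUE))] <- NA_integer_
  co <- new_cohort(resp)
  res <- drop_incomplete(co)
  expect_equal(n_persons(res$cohort), 185L)
  expect_equal(res$accounting$n_missing_omitted, 7L)
  expect_equal(res$accounting$n_analyzed, 185L)
  expect_equal(res$accounting$omitted_pct, 3.6)
  # person order preserved
  expect_identical(rownames(res$cohort$responses),
                   rownames(resp)[rowSums(is.na(resp)) == 0])

  # no missing cells: identity
  co2 <- new_cohort(resp[rowSums(is.na(resp)) == 0, ])
  res2 <- drop_incomplete(co2)
  expect_equal(res2$accounting$n_missing_omitted, 0L)
  expect_identical(res2$cohort$responses, co2$responses)

  # everyone incomplete on the requested item: degenerate
  resp3 <- resp; resp3[, 1] <- NA_integer_
  expect_error(drop_incomplete(new_cohort(resp3), colnames(resp3)[1]),
               "degenerate")
})

test_that("endorsement percentages use the stated denominator", {
  m <- rbind(matrix(1L, 62, 2), matrix(0L, 122, 2), matrix(NA_integer_, 1, 2))
  colnames(m) <- c("sleep", "other")
  m[185, "other"] <- 0L
  tab <- endorsement_table(m, denominator = 185)
  sleep <- tab[tab$item == "sleep", ]
  expect_equal(sleep$pct_yes, 33.5)
  expect_equal(sleep$n_yes + sleep$n_no, 184L)
  # zero endorsement
  m0 <- cbind(never = rep(0L, 20), x = rep(c(0L, 1L), 10))
  expect_equal(endorsement_table(m0)$pct_yes[1], 0)
  # with the retained-n denominator, yes% + no% <= 100, = 100 when complete
  b <- sim_scale_matrix(n = 60, seed = 3)
  tb <- endorsement_table(b)
  expect_true(all(round(100 * tb$n_yes / 60, 1) +
                    round(100 * tb$n_no / 60, 1) == 100))
  expect_error(endorsement_table(m, denominator = 100), "denominator")
})

test_that("participation rate matches the published recruitment arithmetic", {
  rec <- starmh_recruitment()
  acc <- sample_accounting(setNames(rec$recruited, rec$site),
                           setNames(rec$declined, rec$site))
  ps <- participation_summary(acc)
  expect_equal(ps$rate_pct, 66.9)
  expect_equal(participation_summary(sample_accounting(10L, 0L))$rate_pct, 100)
  expect_equal(participation_summary(sample_accounting(1L, 3L))$rate_pct, 25)
  expect_error(participation_summary(sample_accounting(0L, 0L)), "degenerate")
  expect_error(sample_accounting(-1L), "non-negative")
})
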