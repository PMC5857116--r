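#!/usr/bin/env Rscript

# Score the screen exactly as fielded (early exit on the two screen-in items,
# 7-item sum against the cut-score) and reproduce the sample-accounting
# arithmetic of the validation study from its published recruitment counts.
# Reads the cohort CSV written by 01_simulate_cohort.R.

suppressPackageStartupMessages(library(starmh))

items9 <- c("item_1", "item_2", starmh_difficulties()$item)
co <- load_cohort("results/cohort.csv",
                  cohort_schema(items = items9))

res <- drop_incomplete(co, items9)
cl <- classify_cohort(res$cohort, scale_definition())
endo <- endorsement_table(
  res$cohort$responses[, starmh_difficulties()$item])

dir.create("results", showWarnings = FALSE)
write.csv(cl$outcomes, "results/screen_outcomes.csv", row.names = FALSE)
write.csv(endo, "results/endorsement_table.csv", row.names = FALSE)

cat(sprintf("Analyzed %d of %d persons (%.1f%% omitted for missing responses)\n",
            res$accounting$n_analyzed, n_persons(co),
            res$accounting$omitted_pct))
cat(sprintf("Screen-positive %.1f%%, of which immediate screen-in %.1f%%\n",
            100 * cl$prop_positive, 100 * cl$prop_early_exit))

# published recruitment arithmetic
rec <- starmh_recruitment()
acc <- sample_accounting(setNames(rec$recruited, rec$site),
                         setNames(rec$declined, rec$site))
ps <- participation_summary(acc)
cat(sprintf("Published recruitment counts give a participation rate of %.1f%% (per site: %s)\n",
            ps$rate_pct,
            paste(sprintf("%s %.1f%%", names(ps$per_site_pct),
                          ps$per_site_pct), collapse = ", ")))
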