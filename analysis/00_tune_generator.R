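#!/usr/bin/env Rscript

# Calibration of the synthetic-cohort generator.
#
# The validation study's raw responses are not deposited, so the generator's
# trait mixture must be chosen to reproduce the study's observed geometry:
# ~31% per-item endorsement, 7-item score AUC ~0.91 against caseness at 33%
# prevalence, and mean inter-item correlation ~0.46. This grid searches the
# non-case trait mean and case shift for several trait SDs and records, for
# the best (endorsement, AUC) match per SD, the implied inter-item
# correlation. The package defaults (-2.5, +1.0, SD 1.5) come from this grid:
# SD 1.5 is the unique setting that also matches the inter-item correlation.
# This script is reference documentation for that one-off choice; it does not
# feed back into the package at run time.

suppressPackageStartupMessages(library(starmh))

set.seed(20180316)
beta <- setNames(starmh_difficulties()$difficulty, starmh_difficulties()$item)

eval_geom <- function(mu0, mu1, sdv, n = 20000) {
  case <- rbinom(n, 1, 0.33)
  th <- rnorm(n, ifelse(case == 1, mu1, mu0), sdv)
  p <- plogis(outer(th, beta, "-"))
  x <- array(rbinom(n * 7, 1, p), dim(p))
  sc <- rowSums(x)
  r <- rank(sc); n1 <- sum(case)
  auc <- (sum(r[case == 1]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
  cm <- cor(x)
  c(endorse = mean(x), auc = auc, rbar = mean(cm[upper.tri(cm)]))
}

grid <- list()
for (sdv in c(1.0, 1.5, 2.0, 2.5)) {
  best <- NULL
  for (mu0 in seq(-5, -1, 0.25)) {
    for (mu1 in seq(mu0 + 1.5, mu0 + 6, 0.25)) {
      g <- eval_geom(mu0, mu1, sdv, n = 4000)
      loss <- 10 * abs(g["endorse"] - 0.31) + 20 * abs(g["auc"] - 0.912)
      if (is.null(best) || loss < best$loss) {
        best <- list(mu0 = mu0, mu1 = mu1, loss = loss)
      }
    }
  }
  g <- eval_geom(best$mu0, best$mu1, sdv)
  grid[[length(grid) + 1]] <- data.frame(
    trait_sd = sdv, mu_noncase = best$mu0, mu_case = best$mu1,
    endorsement = round(g["endorse"], 3), auc = round(g["auc"], 3),
    mean_interitem_r = round(g["rbar"], 3), row.names = NULL)
  cat(sprintf("sd=%.1f: mu0=%.2f mu1=%.2f endorse=%.3f auc=%.3f rbar=%.3f\n",
              sdv, best$mu0, best$mu1, g["endorse"], g["auc"], g["rbar"]))
}

dir.create("results", showWarnings = FALSE)
write.csv(do.call(rbind, grid), "results/generator_tuning.csv",
          row.names = FALSE)
cat("Target geometry: endorsement 0.31, AUC 0.912, mean inter-item r 0.46.\n")
cat("Grid written to results/generator_tuning.csv\n")
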