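#' Validation-run configuration
#'
#' Bundles every tunable of the full validation pipeline. Defaults mirror the
#' validation study where it states a value (bootstrap 200, parallel analysis
#' 2000 Monte Carlo samples, cut-score grid 1-7, sensitivity floor 0.90) and
#' this package's documented conventions elsewhere.
#'
#' @param scale a [scale_definition()].
#' @param cutoffs cut-scores for the accuracy table.
#' @param n_mc_parallel Monte Carlo samples for parallel analysis.
#' @param sampler a [margin_sampler()] for the T1 test.
#' @param n_boot bootstrap resamples for optimism correction.
#' @param sn_floor sensitivity floor for cut-score selection.
#' @param dif_groupings covariate columns to test for DIF (NULL = all cohort
#'   covariates).
#' @param drop_flagged_items items to drop after the endorsement-specificity
#'   stage; flagged items are reported but never dropped automatically.
#' @param endorsement_flag_threshold rest-score-0 endorsement flag level.
#' @return Object of class `validation_config`.
#' @export
validation_config <- function(scale = scale_definition(),
                              cutoffs = NULL,
                              n_mc_parallel = 2000L,
                              sampler = margin_sampler(),
                              n_boot = 200L,
                              sn_floor = 0.90,
                              dif_groupings = NULL,
                              drop_flagged_items = character(0),
                              endorsement_flag_threshold = 0.30) {
  structure(list(scale = scale, cutoffs = cutoffs,
                 n_mc_parallel = as.integer(n_mc_parallel), sampler = sampler,
                 n_boot = as.integer(n_boot), sn_floor = sn_floor,
                 dif_groupings = dif_groupings,
                 drop_flagged_items = as.character(drop_flagged_items),
                 endorsement_flag_threshold = endorsement_flag_threshold),
            class = "validation_config")
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", reason = res$value)
  }
  report
}

config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full validation pipeline on a cohort
#'
#' Executes, in order: incomplete-case accounting, endorsement table,
#' endorsement-specificity flagging, scale scoring, Rasch CML fit, item fit,
#' reliability, modified parallel analysis, the T1 local-dependence test, the
#' DIF screen over all groupings, ROC/AUC with optimism correction, the
#' per-cutoff accuracy table, and cut-score selection. A failing stage is
#' recorded and the pipeline continues wherever dependencies allow. The run
#' is deterministic under `seed`. When `out_dir` is given every table is also
#' written as CSV together with a JSON summary and run metadata.
#'
#' @param cohort a `starmh_cohort` containing the screen-in and scale items.
#' @param config a [validation_config()].
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional output directory.
#' @return A `validation_report` list: `accounting`, `endorsement`,
#'   `specificity`, `classification`, `rasch`, `item_fit`, `reliability`,
#'   `parallel`, `t1`, `dif`, `roc`, `optimism`, `cutoffs`, `selection`,
#'   `meta`, plus `stages` (per-stage status).
#' @export
run_validation_report <- function(cohort, config = validation_config(),
                                  seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "starmh_cohort"),
            inherits(config, "validation_config"))
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4L)
  scale <- config$scale
  report <- list(stages = list(),
                 meta = list(seed = seed,
                             package_version = as.character(packageVersion("starmh")),
                             r_version = as.character(getRversion()),
                             config_md5 = config_fingerprint(config),
                             timestamp = format(Sys.time(), tz = "UTC")))

  all_items <- c(scale$screen_in_items, scale$scale_items)
  all_items <- intersect(all_items, colnames(cohort$responses))
  dropres <- drop_incomplete(cohort, all_items)
  report$accounting <- dropres$accounting
  cc <- dropres$cohort
  scale_items <- setdiff(scale$scale_items, config$drop_flagged_items)
  scale_eff <- scale_definition(intersect(scale$screen_in_items, colnames(cc$responses)),
                                scale_items,
                                min(scale$cutoff, length(scale_items)))
  sm <- cc$responses[, scale_items, drop = FALSE]

  report <- run_stage(report, "endorsement",
                      endorsement_table(cc$responses[, scale$scale_items, drop = FALSE]))
  report <- run_stage(report, "specificity",
                      endorsement_specificity_flag(
                        cc$responses[, scale$scale_items, drop = FALSE],
                        config$endorsement_flag_threshold))
  report <- run_stage(report, "classification",
                      classify_cohort(cc, scale_eff, early_exit = TRUE))
  report <- run_stage(report, "rasch", fit_cml(sm))
  if (!is.null(report$rasch)) {
    report <- run_stage(report, "item_fit", item_fit(report$rasch))
    report <- run_stage(report, "reliability", reliability(report$rasch, sm))
    report <- run_stage(report, "parallel",
                        modified_parallel_analysis(sm, report$rasch,
                                                   n_mc = config$n_mc_parallel,
                                                   seed = stage_seeds[1]))
  }
  sampler <- config$sampler
  sampler$seed <- stage_seeds[2]
  report <- run_stage(report, "t1", ponocny_t1(sm, sampler))

  if (!is.null(cc$covariates)) {
    groupings <- cc$covariates
    if (!is.null(config$dif_groupings)) {
      groupings <- groupings[intersect(config$dif_groupings, names(groupings))]
    }
    total <- rowSums(sm)
    report <- run_stage(report, "dif", dif_analysis(sm, groupings))
  }

  if (!is.null(cc$caseness)) {
    scores <- rowSums(sm)
    case <- cc$caseness
    keep <- !is.na(case)
    report <- run_stage(report, "roc", {
      rp <- roc_points(scores[keep], case[keep])
      ci <- auc_with_ci(scores[keep], case[keep])
      list(points = rp$points, auc = ci$auc, auc_ci = ci$ci)
    })
    report <- run_stage(report, "optimism",
                        optimism_corrected_auc(scores[keep], case[keep],
                                               n_boot = config$n_boot,
                                               seed = stage_seeds[3]))
    report <- run_stage(report, "cutoffs", {
      cuts <- config$cutoffs
      if (is.null(cuts)) cuts <- seq_len(length(scale_items))
      cuts <- cuts[cuts >= min(scores[keep]) & cuts <= max(scores[keep])]
      cutoff_table(scores[keep], case[keep], cuts)
    })
    if (!is.null(report$cutoffs)) {
      report <- run_stage(report, "selection",
                          youden_select(report$cutoffs, config$sn_floor))
    }
  }
  class(report) <- "validation_report"
  if (!is.null(out_dir)) write_validation_report(report, out_dir)
  report
}

#' Write a validation report to a directory
#'
#' One CSV per tabular section, a JSON summary of the scalar results, and the
#' run metadata (seed, versions, config fingerprint).
#'
#' @param report a `validation_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_validation_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  }
  if (!is.null(report$endorsement)) wcsv(report$endorsement, "endorsement")
  if (!is.null(report$specificity)) {
    wcsv(report$specificity$curves, "endorsement_specificity_curves")
    wcsv(report$specificity$curves_total, "endorsement_specificity_curves_total")
  }
  if (!is.null(report$classification)) wcsv(report$classification$outcomes, "screen_outcomes")
  if (!is.null(report$rasch)) {
    fit <- report$rasch
    tab <- data.frame(item = names(fit$difficulties),
                      difficulty = unname(fit$difficulties),
                      se = unname(fit$difficulty_se))
    if (!is.null(report$item_fit)) {
      tab <- merge(tab, report$item_fit, by = "item", sort = FALSE)
    }
    wcsv(tab, "rasch_items")
    wcsv(estimate_abilities(fit), "person_abilities")
  }
  if (!is.null(report$t1)) wcsv(report$t1, "t1_pairs")
  if (!is.null(report$dif)) wcsv(report$dif, "dif")
  if (!is.null(report$roc)) wcsv(report$roc$points, "roc_points")
  if (!is.null(report$cutoffs)) wcsv(report$cutoffs, "cutoff_table")

  summary <- list(
    meta = report$meta,
    stages = report$stages,
    accounting = list(n_screened = sum(report$accounting$recruited_per_site),
                      n_missing_omitted = report$accounting$n_missing_omitted,
                      n_analyzed = report$accounting$n_analyzed,
                      omitted_pct = report$accounting$omitted_pct),
    screen_positive_prop = report$classification$prop_positive,
    early_exit_prop = report$classification$prop_early_exit,
    flagged_items = report$specificity$flagged,
    psi = report$reliability$psi,
    mean_interitem_r = report$reliability$mean_interitem_r,
    parallel_p = report$parallel$p,
    t1_min_p = if (!is.null(report$t1)) min(report$t1$p),
    auc = report$roc$auc, auc_ci = report$roc$auc_ci,
    corrected_auc = report$optimism$corrected_auc,
    optimal_cutoff = report$selection$optimal_cutoff,
    sensitivity_privileged_cutoff = report$selection$sensitivity_privileged_cutoff
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
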