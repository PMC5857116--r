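check_two_class <- function(caseness) {
  cls <- unique(caseness[!is.na(caseness)])
  if (length(cls) < 2L) {
    stop("degenerate input: caseness must contain both classes", call. = FALSE)
  }
}

#' ROC curve points and trapezoid AUC
#'
#' One operating point per observed threshold "score >= c", plus the (0,0) and
#' (1,1) endpoints; the AUC is the trapezoid area, which for a discrete score
#' equals the Mann-Whitney concordance (ties counted half).
#'
#' @param scores per-person test score.
#' @param caseness per-person 0/1 reference diagnosis.
#' @return List of class `roc_curve`: `points` (data frame `threshold`,
#'   `sensitivity`, `one_minus_specificity`) and `auc`.
#' @export
roc_points <- function(scores, caseness) {
  ok <- !is.na(scores) & !is.na(caseness)
  scores <- scores[ok]; caseness <- as.integer(caseness[ok])
  check_two_class(caseness)
  thr <- sort(unique(scores))
  sn <- vapply(thr, function(c) mean(scores[caseness == 1L] >= c), numeric(1))
  fpr <- vapply(thr, function(c) mean(scores[caseness == 0L] >= c), numeric(1))
  pts <- data.frame(threshold = c(-Inf, thr, Inf),
                    sensitivity = c(1, sn, 0),
                    one_minus_specificity = c(1, fpr, 0))
  pts <- pts[order(pts$one_minus_specificity, pts$sensitivity), ]
  auc <- sum(diff(pts$one_minus_specificity) *
               (head(pts$sensitivity, -1) + pts$sensitivity[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

# Mann-Whitney concordance AUC via midranks
auc_concordance <- function(scores, caseness) {
  ok <- !is.na(scores) & !is.na(caseness)
  scores <- scores[ok]; caseness <- as.integer(caseness[ok])
  n1 <- sum(caseness == 1L); n0 <- sum(caseness == 0L)
  r <- rank(scores)
  (sum(r[caseness == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney concordance estimator; its variance follows
#' DeLong's structural-components method and the interval is Wald, clipped to
#' `[0, 1]`. A warning is issued when either class has fewer than 10 persons.
#'
#' @inheritParams roc_points
#' @param conf_level confidence level.
#' @return List: `auc`, `se`, `ci` (length-2), `n_case`, `n_noncase`.
#' @export
auc_with_ci <- function(scores, caseness, conf_level = 0.95) {
  ok <- !is.na(scores) & !is.na(caseness)
  scores <- scores[ok]; caseness <- as.integer(caseness[ok])
  check_two_class(caseness)
  xs <- scores[caseness == 1L]; ys <- scores[caseness == 0L]
  m <- length(xs); n <- length(ys)
  if (min(m, n) < 10L) warning("fewer than 10 persons in a class; CI unreliable",
                               call. = FALSE)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1))
  auc <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, se = se,
       ci = pmin(1, pmax(0, c(auc - z * se, auc + z * se))),
       n_case = m, n_noncase = n)
}

#' Bootstrap optimism-corrected AUC (Harrell's algorithm)
#'
#' Fits the univariable logistic model `caseness ~ score`; on each bootstrap
#' resample the model is refit and the optimism is the AUC of the bootstrap
#' model on its own sample minus its AUC on the original data. The corrected
#' AUC is the apparent AUC minus the mean optimism. Resamples containing a
#' single class are redrawn (and counted). Because the model is monotone in a
#' single predictor, the apparent AUC equals the score's rank AUC and the
#' correction measures sampling optimism only.
#'
#' @inheritParams roc_points
#' @param n_boot bootstrap resamples (>= 50; the validation study used 200).
#' @param seed optional integer seed.
#' @return List: `apparent_auc`, `mean_optimism`, `corrected_auc`, `n_boot`,
#'   `n_redrawn`.
#' @export
optimism_corrected_auc <- function(scores, caseness, n_boot = 200L,
                                   seed = NULL) {
  if (n_boot < 50L) stop("n_boot must be >= 50", call. = FALSE)
  ok <- !is.na(scores) & !is.na(caseness)
  scores <- scores[ok]; caseness <- as.integer(caseness[ok])
  check_two_class(caseness)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  full <- glm(caseness ~ scores, family = binomial())
  apparent <- auc_concordance(fitted(full), caseness)
  optimism <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(caseness[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    yb <- caseness[idx]; sb <- scores[idx]
    fb <- glm(yb ~ sb, family = binomial())
    pred_boot <- plogis(coef(fb)[1] + coef(fb)[2] * sb)
    pred_orig <- plogis(coef(fb)[1] + coef(fb)[2] * scores)
    optimism[b] <- auc_concordance(pred_boot, yb) -
      auc_concordance(pred_orig, caseness)
  }
  list(apparent_auc = apparent, mean_optimism = mean(optimism),
       corrected_auc = apparent - mean(optimism), n_boot = n_boot,
       n_redrawn = n_redrawn)
}

# log-method CI for a likelihood ratio (Simel et al.)
lr_ci <- function(lr, se_log, z) {
  if (!is.finite(lr) || lr <= 0) return(c(NA_real_, NA_real_))
  exp(log(lr) + c(-1, 1) * z * se_log)
}

#' Per-cutoff diagnostic accuracy table
#'
#' For each cut-score "score >= c": sensitivity, specificity, predictive
#' values and efficiency (raw accuracy) with Clopper-Pearson 95% intervals;
#' positive and negative likelihood ratios with log-method intervals; and the
#' Youden sum SN + SP (as printed in the validation study's accuracy table)
#' together with the conventional `J = SN + SP - 1`.
#'
#' @inheritParams roc_points
#' @param cutoffs integer cut-scores (must lie within the score range).
#' @param conf_level confidence level for all intervals.
#' @return Data frame with one row per cutoff; likelihood ratios at perfect
#'   specificity are `Inf` (flagged via `plr_infinite`).
#' @export
cutoff_table <- function(scores, caseness, cutoffs = NULL, conf_level = 0.95) {
  ok <- !is.na(scores) & !is.na(caseness)
  scores <- scores[ok]; caseness <- as.integer(caseness[ok])
  check_two_class(caseness)
  if (is.null(cutoffs)) cutoffs <- sort(unique(scores[scores > min(scores)]))
  if (any(cutoffs < min(scores) | cutoffs > max(scores))) {
    stop("cutoffs must lie within the observed score range", call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  cp <- function(k, n) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(k, n, conf.level = conf_level)$conf.int)
  }
  rows <- lapply(cutoffs, function(cc) {
    pos <- as.integer(scores >= cc)
    tp <- sum(pos == 1L & caseness == 1L); fn <- sum(pos == 0L & caseness == 1L)
    fp <- sum(pos == 1L & caseness == 0L); tn <- sum(pos == 0L & caseness == 0L)
    n <- tp + fn + fp + tn
    sn <- tp / (tp + fn); sp <- tn / (tn + fp)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    eff <- (tp + tn) / n
    plr <- if (sp < 1) sn / (1 - sp) else Inf
    nlr <- if (sn == 1) 0 else if (sp > 0) (1 - sn) / sp else Inf
    se_log_plr <- sqrt(max(0, 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)))
    se_log_nlr <- sqrt(max(0, 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)))
    sn_ci <- cp(tp, tp + fn); sp_ci <- cp(tn, tn + fp)
    ppv_ci <- cp(tp, tp + fp); npv_ci <- cp(tn, tn + fn)
    eff_ci <- cp(tp + tn, n)
    plr_ci <- lr_ci(plr, se_log_plr, z); nlr_ci <- lr_ci(nlr, se_log_nlr, z)
    data.frame(cutoff = cc, tp = tp, fn = fn, fp = fp, tn = tn,
               sn = sn, sn_lo = sn_ci[1], sn_hi = sn_ci[2],
               sp = sp, sp_lo = sp_ci[1], sp_hi = sp_ci[2],
               plr = plr, plr_lo = plr_ci[1], plr_hi = plr_ci[2],
               nlr = nlr, nlr_lo = nlr_ci[1], nlr_hi = nlr_ci[2],
               ppv = ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
               npv = npv, npv_lo = npv_ci[1], npv_hi = npv_ci[2],
               efficiency = eff, efficiency_lo = eff_ci[1],
               efficiency_hi = eff_ci[2],
               youden_sum = sn + sp, youden_j = sn + sp - 1,
               plr_infinite = !is.finite(plr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the operating cut-score
#'
#' The optimal cut-score maximizes the Youden sum SN + SP (ties broken toward
#' the lower cutoff); the sensitivity-privileged cut-score maximizes
#' specificity subject to a sensitivity floor — the highest cutoff whose
#' sensitivity is still at least `sn_floor` — implementing the validation
#' study's preference for a highly sensitive screen.
#'
#' @param table a [cutoff_table()] (or any data frame with `cutoff`, `sn`,
#'   `youden_sum`).
#' @param sn_floor sensitivity floor for the privileged choice.
#' @return List: `optimal_cutoff`, `sensitivity_privileged_cutoff` (NA when no
#'   cutoff meets the floor).
#' @export
youden_select <- function(table, sn_floor = 0.90) {
  stopifnot(nrow(table) > 0L, all(c("cutoff", "sn", "youden_sum") %in% names(table)))
  ord <- order(table$cutoff)
  tab <- table[ord, ]
  best <- tab$cutoff[which.max(tab$youden_sum)]   # which.max takes first = lowest
  meets <- tab$cutoff[tab$sn >= sn_floor]
  list(optimal_cutoff = best,
       sensitivity_privileged_cutoff = if (length(meets)) max(meets) else NA)
}
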