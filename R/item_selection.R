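#' Cohen's kappa for two binary vectors with an asymptotic null z-test
#'
#' Agreement beyond chance between a candidate item and caseness. The
#' significance test is the asymptotic z-test of kappa against 0 using the
#' standard error under independence (Fleiss); no continuity correction.
#'
#' @param x,y 0/1 vectors (pairwise-complete).
#' @return List with `kappa`, `se0`, `z`, `p` (two-sided) and `p_greater`.
#' @export
kappa_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) stop("no complete pairs", call. = FALSE)
  po <- mean(x == y)
  px <- mean(x); py <- mean(y)
  pe <- px * py + (1 - px) * (1 - py)
  if (pe >= 1) return(list(kappa = NA_real_, se0 = NA_real_, z = NA_real_,
                           p = NA_real_, p_greater = NA_real_))
  kap <- (po - pe) / (1 - pe)
  # H0 variance (Fleiss/Everitt): marginals fixed, kappa = 0
  p_i <- c(1 - px, px); q_i <- c(1 - py, py)
  se0 <- sqrt(pe + pe^2 - sum(p_i * q_i * (p_i + q_i))) / ((1 - pe) * sqrt(n))
  z <- kap / se0
  list(kappa = kap, se0 = se0, z = z,
       p = 2 * pnorm(-abs(z)), p_greater = pnorm(z, lower.tail = FALSE))
}

# 2x2 confusion counts of a binary item against caseness
item_confusion <- function(item, caseness) {
  ok <- !is.na(item) & !is.na(caseness)
  item <- item[ok]; caseness <- caseness[ok]
  c(tp = sum(item == 1L & caseness == 1L),
    fn = sum(item == 0L & caseness == 1L),
    fp = sum(item == 1L & caseness == 0L),
    tn = sum(item == 0L & caseness == 0L))
}

#' Per-item diagnostic filter (sensitivity/specificity/kappa stage)
#'
#' First stage of the derivation cascade: each candidate item is crossed with
#' caseness; items are retained when item sensitivity and specificity meet the
#' floors and the item-caseness kappa is significantly greater than zero.
#' The derivation study used floors of 85% sensitivity and 75% specificity.
#'
#' @param matrix binary response matrix of candidate items.
#' @param caseness per-person 0/1 reference diagnosis (both classes present).
#' @param sn_min,sp_min retention floors for sensitivity and specificity.
#' @param alpha significance level for the one-sided kappa z-test.
#' @return Data frame of `ItemDiagnosticRecord`s: `item`, `sensitivity`,
#'   `specificity`, `kappa`, `chi2_p`, `spearman_rho`, `predictive_accuracy`,
#'   `retained`, `stage_dropped`.
#' @export
item_diagnostic_filter <- function(matrix, caseness, sn_min = 0.85,
                                   sp_min = 0.75, alpha = 0.05) {
  matrix <- as_response_matrix(matrix)
  caseness <- as.integer(caseness)
  cls <- unique(caseness[!is.na(caseness)])
  if (length(cls) < 2L) {
    stop("degenerate input: caseness must contain both classes", call. = FALSE)
  }
  recs <- lapply(colnames(matrix), function(it) {
    x <- matrix[, it]
    cc <- item_confusion(x, caseness)
    sn <- unname(cc["tp"] / (cc["tp"] + cc["fn"]))
    sp <- unname(cc["tn"] / (cc["tn"] + cc["fp"]))
    acc <- unname((cc["tp"] + cc["tn"]) / sum(cc))
    kt <- kappa_test(x, caseness)
    ok <- !is.na(x) & !is.na(caseness)
    chi2_p <- if (length(unique(x[ok])) < 2L) 1 else
      suppressWarnings(chisq.test(table(x[ok], caseness[ok]),
                                  correct = FALSE)$p.value)
    rho <- if (length(unique(x[ok])) < 2L) 0 else
      suppressWarnings(cor(x[ok], caseness[ok], method = "spearman"))
    keep <- !is.na(sn) && !is.na(sp) && sn >= sn_min && sp >= sp_min &&
      !is.na(kt$p_greater) && kt$p_greater < alpha
    data.frame(item = it, sensitivity = sn, specificity = sp,
               kappa = kt$kappa, chi2_p = chi2_p, spearman_rho = rho,
               predictive_accuracy = acc, retained = keep,
               stage_dropped = if (keep) NA_character_ else "diagnostic",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Spearman-correlation / predictive-accuracy filter
#'
#' Second stage of the derivation cascade: among surviving items, retain those
#' whose Spearman correlation with caseness and raw predictive accuracy
#' (TP+TN)/N meet the floors (0.7 and 0.85 in the derivation study).
#'
#' @param records data frame from [item_diagnostic_filter()].
#' @param rho_min,acc_min retention floors.
#' @return The records with `retained`/`stage_dropped` updated.
#' @export
spearman_accuracy_filter <- function(records, rho_min = 0.7, acc_min = 0.85) {
  stopifnot(all(c("spearman_rho", "predictive_accuracy") %in% names(records)))
  drop <- records$retained &
    (is.na(records$spearman_rho) | records$spearman_rho < rho_min |
       records$predictive_accuracy < acc_min)
  records$retained[drop] <- FALSE
  records$stage_dropped[drop] <- "spearman_accuracy"
  records
}

#' CART retention stage
#'
#' Fits a Gini classification tree of caseness on the candidate items and
#' retains the items actually used as split variables, mirroring the
#' derivation study's CART stage. Backed by [rpart::rpart()] with no pruning
#' (`cp = 0`) and the depth/leaf-size controls exposed here.
#'
#' @param matrix binary response matrix (>= 2 candidate items).
#' @param caseness per-person 0/1, not constant.
#' @param max_depth maximum tree depth (0 returns an empty retained set).
#' @param min_leaf minimum persons per leaf.
#' @return List with `retained` (character vector of split items) and `tree`
#'   (the rpart fit, or NULL when `max_depth = 0`) and `description`
#'   (indented text rendering of the splits).
#' @export
cart_select <- function(matrix, caseness, max_depth = 5L, min_leaf = 5L) {
  matrix <- as_response_matrix(matrix)
  if (ncol(matrix) < 2L) stop("need >= 2 candidate items", call. = FALSE)
  caseness <- as.integer(caseness)
  if (length(unique(caseness[!is.na(caseness)])) < 2L) {
    stop("degenerate input: constant caseness", call. = FALSE)
  }
  if (max_depth == 0L) {
    return(list(retained = character(0), tree = NULL,
                description = "root only (max_depth = 0)"))
  }
  df <- data.frame(.case = factor(caseness), matrix, check.names = FALSE)
  fit <- rpart::rpart(
    .case ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth, minbucket = min_leaf,
                                   minsplit = 2L * min_leaf, cp = 0,
                                   xval = 0L, maxcompete = 0L,
                                   maxsurrogate = 0L))
  vars <- as.character(fit$frame$var)
  retained <- unique(vars[vars != "<leaf>"])
  list(retained = retained, tree = fit,
       description = paste(utils::capture.output(print(fit)), collapse = "\n"))
}

#' Endorsement-specificity curves and low-variance flagging
#'
#' For each item, the probability of endorsement conditional on the rest-score
#' (the total over the other items). Items endorsed with high probability even
#' by persons who endorse nothing else carry little diagnostic specificity:
#' the validation study dropped its sleep item for a ~30% endorsement rate at
#' rest-score 0. The inclusive-total variant (x-axis = total score including
#' the item, as plotted in the study) is also returned.
#'
#' @param matrix binary response matrix (>= 2 items).
#' @param threshold flag items with `P(endorse | rest-score = 0) >= threshold`.
#' @return List with `flagged` (character vector), `curves` (data frame:
#'   `item`, `rest_score`, `n`, `prop_endorsed`) and `curves_total` (same with
#'   `total_score` including the item).
#' @export
endorsement_specificity_flag <- function(matrix, threshold = 0.30) {
  matrix <- as_response_matrix(matrix)
  m <- ncol(matrix)
  if (m < 2L) stop("need >= 2 items", call. = FALSE)
  curves <- list(); curves_tot <- list()
  for (it in colnames(matrix)) {
    x <- matrix[, it]
    rest <- rowSums(matrix[, setdiff(colnames(matrix), it), drop = FALSE])
    ok <- !is.na(x) & !is.na(rest)
    for (k in 0:(m - 1L)) {
      sel <- ok & rest == k
      curves[[length(curves) + 1L]] <- data.frame(
        item = it, rest_score = k, n = sum(sel),
        prop_endorsed = if (any(sel)) mean(x[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    tot <- rest + x
    for (k in 0:m) {
      sel <- ok & tot == k
      curves_tot[[length(curves_tot) + 1L]] <- data.frame(
        item = it, total_score = k, n = sum(sel),
        prop_endorsed = if (any(sel)) mean(x[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, curves)
  curves_tot <- do.call(rbind, curves_tot)
  at0 <- curves[curves$rest_score == 0L, ]
  flagged <- at0$item[!is.na(at0$prop_endorsed) &
                        at0$prop_endorsed >= threshold]
  list(flagged = flagged, curves = curves, curves_total = curves_tot)
}
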