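#' Nagelkerke R-squared of a binomial model
#'
#' `[1 - (L0/L)^(2/n)] / [1 - L0^(2/n)]` with `L0` the intercept-only
#' likelihood, computed from log-likelihoods.
#'
#' @param ll,ll0 model and intercept-only log-likelihoods.
#' @param n observations.
#' @return R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll, ll0, n) {
  cs <- 1 - exp(2 * (ll0 - ll) / n)
  maxr2 <- 1 - exp(2 * ll0 / n)
  if (maxr2 <= 0) return(0)
  min(1, max(0, cs / maxr2))
}

# logistic log-likelihood given linear predictor
logit_ll <- function(y, eta) sum(y * eta - log1p(exp(eta)))

# Firth-penalized logistic regression: IRLS on the modified score equation
# (Jeffreys prior). Returns coefficients and the penalized log-likelihood.
firth_logit <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtW <- t(X * W)
    info <- XtW %*% X
    infoinv <- solve(info + diag(1e-10, ncol(X)))
    h <- rowSums((X %*% infoinv) * (X * W))
    U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(infoinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  info <- t(X * (p * (1 - p))) %*% X
  ll_pen <- logit_ll(y, eta) + 0.5 * determinant(info)$modulus[1]
  list(coef = beta, loglik = ll_pen)
}

looks_separated <- function(fit) {
  p <- fitted(fit)
  !fit$converged || any(p < 1e-8 | p > 1 - 1e-8) ||
    any(abs(coef(fit)) > 15, na.rm = TRUE)
}

#' Differential item functioning for one item by logistic regression
#'
#' Nested logistic models of the item on the matching total score: `M0:
#' item ~ score` versus `M2: item ~ score + group + score:group`, compared by
#' a likelihood-ratio test on 2 degrees of freedom (joint uniform and
#' non-uniform DIF; set `uniform_only = TRUE` for the 1-df uniform test
#' `M1: item ~ score + group`). The effect size is the Nagelkerke R-squared
#' difference, classified negligible (< 0.035), moderate (0.035-0.07) or
#' large (> 0.07). Under complete separation the result is flagged and all
#' three likelihoods are recomputed with Firth's penalty.
#'
#' @param matrix binary response matrix containing the scale items.
#' @param group per-person factor/vector with exactly two levels.
#' @param item_id column of `matrix` to test.
#' @param score matching variable; defaults to the total score over all
#'   columns of `matrix` (including the studied item).
#' @param uniform_only use the 1-df uniform-DIF test.
#' @return One-row data frame: `item`, `lr_chi2`, `df`, `p_raw`, `delta_r2`,
#'   `effect_class`, `separation`.
#' @export
dif_logistic_item <- function(matrix, group, item_id, score = NULL,
                              uniform_only = FALSE) {
  x <- as_response_matrix(matrix)
  y <- x[, item_id]
  if (is.null(score)) score <- rowSums(x)
  g <- factor(group)
  ok <- !is.na(y) & !is.na(score) & !is.na(g)
  y <- y[ok]; sc <- as.numeric(score[ok]); g <- droplevels(g[ok])
  if (nlevels(g) != 2L) {
    stop("group must have exactly two represented levels", call. = FALSE)
  }
  if (length(unique(y)) < 2L) stop("item is constant", call. = FALSE)
  n <- length(y)
  gnum <- as.numeric(g) - 1
  m0 <- glm(y ~ sc, family = binomial())
  m2 <- if (uniform_only) glm(y ~ sc + gnum, family = binomial())
        else glm(y ~ sc * gnum, family = binomial())
  mnull <- glm(y ~ 1, family = binomial())
  separation <- looks_separated(m0) || looks_separated(m2)
  if (separation) {
    X0 <- cbind(1, sc)
    X2 <- if (uniform_only) cbind(1, sc, gnum) else cbind(1, sc, gnum, sc * gnum)
    ll0 <- firth_logit(X0, y)$loglik
    ll2 <- firth_logit(X2, y)$loglik
    llnull <- firth_logit(cbind(rep(1, n)), y)$loglik
  } else {
    ll0 <- as.numeric(logLik(m0))
    ll2 <- as.numeric(logLik(m2))
    llnull <- as.numeric(logLik(mnull))
  }
  df <- if (uniform_only) 1L else 2L
  lr <- max(0, 2 * (ll2 - ll0))
  dr2 <- max(0, nagelkerke_r2(ll2, llnull, n) - nagelkerke_r2(ll0, llnull, n))
  data.frame(item = item_id, lr_chi2 = lr, df = df,
             p_raw = pchisq(lr, df, lower.tail = FALSE),
             delta_r2 = dr2,
             effect_class = if (dr2 < 0.035) "negligible"
                            else if (dr2 <= 0.07) "moderate" else "large",
             separation = separation, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values probabilities in `[0, 1]`.
#' @return Adjusted probabilities, clipped at 1.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' DIF screen across items and grouping variables
#'
#' Runs [dif_logistic_item()] for every scale item against every grouping
#' covariate (each dichotomous), adjusting p-values by Benjamini-Hochberg
#' within each grouping family across the items — the validation study's
#' families of 7 item tests per covariate.
#'
#' @param matrix binary response matrix of the scale items.
#' @param groupings data frame of per-person grouping covariates; each column
#'   must have exactly two represented levels.
#' @inheritParams dif_logistic_item
#' @return Long data frame: `item`, `grouping`, `lr_chi2`, `df`, `p_raw`,
#'   `p_bh`, `delta_r2`, `effect_class`, `separation`.
#' @export
dif_analysis <- function(matrix, groupings, uniform_only = FALSE) {
  x <- as_response_matrix(matrix)
  groupings <- as.data.frame(groupings, stringsAsFactors = FALSE)
  out <- list()
  for (gname in names(groupings)) {
    rows <- lapply(colnames(x), function(it) {
      r <- dif_logistic_item(x, groupings[[gname]], it,
                             uniform_only = uniform_only)
      r$grouping <- gname
      r
    })
    fam <- do.call(rbind, rows)
    fam$p_bh <- bh_adjust(fam$p_raw)
    out[[gname]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("item", "grouping", "lr_chi2", "df", "p_raw", "p_bh",
          "delta_r2", "effect_class", "separation")]
}
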