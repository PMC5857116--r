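#' Elementary symmetric functions of item easiness parameters
#'
#' The conditional likelihood of the dichotomous Rasch model factors through
#' the elementary symmetric functions (ESFs) of the item easiness parameters
#' `eps_i = exp(-beta_i)`: `gamma_r(eps)` sums `prod(eps[S])` over all item
#' subsets `S` of size `r`. Computed with the summation recursion in the log
#' domain for numerical stability.
#'
#' @param eps positive easiness parameters (one per item).
#' @return Numeric vector `gamma_0 .. gamma_m`.
#' @export
esf <- function(eps) exp(log_esf(log(eps)))

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

log_esf <- function(log_eps) {
  m <- length(log_eps)
  lg <- c(0, rep(-Inf, m))
  for (i in seq_len(m)) {
    r <- (i + 1):2
    lg[r] <- logsumexp2(lg[r], log_eps[i] + lg[r - 1L])
  }
  lg
}

# log ESFs of eps with item i (and optionally j) removed
log_esf_drop <- function(log_eps, drop) log_esf(log_eps[-drop])

# conditional item-score probabilities pi_i(r) = P(x_i = 1 | raw score r)
# and pairwise pi_ij(r), for all r in `scores`
cml_cond_probs <- function(log_eps, scores, pairwise = FALSE) {
  m <- length(log_eps)
  lg <- log_esf(log_eps)
  lgi <- lapply(seq_len(m), function(i) log_esf_drop(log_eps, i))
  pi1 <- matrix(0, length(scores), m)   # rows: scores, cols: items
  for (si in seq_along(scores)) {
    r <- scores[si]
    for (i in seq_len(m)) {
      pi1[si, i] <- exp(log_eps[i] + lgi[[i]][r] - lg[r + 1L]) # gamma_{r-1}^{(i)}
    }
  }
  pi2 <- NULL
  if (pairwise) {
    pi2 <- array(0, c(length(scores), m, m))
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      lgij <- log_esf(log_eps[-c(i, j)])
      for (si in seq_along(scores)) {
        r <- scores[si]
        v <- if (r >= 2L) exp(log_eps[i] + log_eps[j] + lgij[r - 1L] - lg[r + 1L]) else 0
        pi2[si, i, j] <- pi2[si, j, i] <- v
      }
    }
  }
  list(pi1 = pi1, pi2 = pi2, log_gamma = lg)
}

#' Fit the dichotomous Rasch model by conditional maximum likelihood
#'
#' Item difficulties maximize the likelihood conditional on the person raw
#' scores, eliminating the person parameters; the ESFs are evaluated with the
#' log-domain summation recursion and the likelihood is maximized by Newton
#' iterations with analytic gradient and Hessian (the conditional item-score
#' covariance matrix). Difficulties are reported in the sum-zero convention;
#' standard errors come from the observed conditional information via the
#' delta method. Persons with missing cells are dropped (with a warning);
#' persons with zero or perfect raw scores carry no conditional information
#' and are excluded from estimation, but still receive (undefined) abilities.
#'
#' @param matrix binary response matrix (>= 2 items).
#' @param tol convergence threshold on the gradient infinity-norm.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `rasch_fit` with elements `difficulties`,
#'   `difficulty_se` (sum-zero scale), `abilities`, `ability_se` (per person;
#'   NA for extreme raw scores), `score_table` (ability per raw score),
#'   `expected`, `residuals` (persons x items, non-extreme complete persons),
#'   `raw_scores`, `item_margins`, `loglik`, `iterations`, `converged`.
#' @export
fit_cml <- function(matrix, tol = 1e-8, max_iter = 100L) {
  xm <- as_response_matrix(matrix)
  m <- ncol(xm)
  if (m < 2L) stop("need >= 2 items", call. = FALSE)
  complete <- rowSums(is.na(xm)) == 0L
  if (!all(complete)) {
    warning(sprintf("%d persons with missing cells dropped from CML fit",
                    sum(!complete)), call. = FALSE)
  }
  x <- xm[complete, , drop = FALSE]
  raw <- rowSums(x)
  nonextreme <- raw > 0L & raw < m
  xe <- x[nonextreme, , drop = FALSE]
  if (!nrow(xe)) stop("no persons with non-extreme raw scores", call. = FALSE)
  s <- colSums(xe)
  bad <- s == 0L | s == nrow(xe)
  if (any(bad)) {
    stop("inestimable item(s) (all 0 or all 1 among non-extreme persons): ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  score_levels <- sort(unique(rowSums(xe)))
  n_r <- as.numeric(table(factor(rowSums(xe), levels = score_levels)))

  # identification during iteration: beta_1 = 0; report sum-zero afterwards
  beta <- log((nrow(xe) - s) / s)
  beta <- beta - beta[1L]
  free <- 2:m
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    cp <- cml_cond_probs(-beta, score_levels, pairwise = TRUE)
    exp_s <- colSums(n_r * cp$pi1)
    grad <- -s + exp_s              # d(-l)/d(beta) has opposite sign; see below
    # l(beta) = -sum_i beta_i s_i - sum_r n_r log gamma_r  =>
    # dl/dbeta_i = -s_i + sum_r n_r pi_i(r)
    H <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      H[i, j] <- if (i == j) {
        -sum(n_r * cp$pi1[, i] * (1 - cp$pi1[, i]))
      } else {
        -sum(n_r * (cp$pi2[, i, j] - cp$pi1[, i] * cp$pi1[, j]))
      }
    }
    if (max(abs(grad[free])) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- solve(H[free, free, drop = FALSE], grad[free])
    beta[free] <- beta[free] - step
  }
  loglik <- -sum(beta * s) - sum(n_r * cml_cond_probs(-beta, score_levels)$log_gamma[score_levels + 1L])

  # sum-zero normalization + delta-method SEs
  beta_star <- beta - mean(beta)
  V_free <- solve(-H[free, free, drop = FALSE])
  J <- matrix(-1 / m, m, m - 1L)
  J[cbind(free, seq_len(m - 1L))] <- J[cbind(free, seq_len(m - 1L))] + 1
  V_star <- J %*% V_free %*% t(J)
  se <- sqrt(pmax(diag(V_star), 0))
  names(beta_star) <- names(se) <- colnames(x)

  st <- ability_table(beta_star, m)
  theta_all <- st$theta[match(rowSums(x), st$raw_score)]
  theta_se_all <- st$se[match(rowSums(x), st$raw_score)]
  abilities <- ability_se <- rep(NA_real_, nrow(xm))
  names(abilities) <- names(ability_se) <- rownames(xm)
  abilities[complete] <- theta_all
  ability_se[complete] <- theta_se_all

  use <- complete & !is.na(abilities)
  expected <- plogis(outer(abilities[use], beta_star, "-"))
  obs <- xm[use, , drop = FALSE]
  w <- expected * (1 - expected)
  residuals <- (obs - expected) / sqrt(w)

  structure(list(difficulties = beta_star, difficulty_se = se,
                 abilities = abilities, ability_se = ability_se,
                 score_table = st, expected = expected,
                 residuals = residuals, observed = obs,
                 raw_scores = rowSums(x),
                 item_margins = s, n_nonextreme = nrow(xe),
                 loglik = loglik, iterations = iter, converged = converged),
            class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf("Rasch CML fit: %d items, %d non-extreme persons, logLik %.2f (%s)\n",
              length(x$difficulties), x$n_nonextreme, x$loglik,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "NOT converged"))
  print(round(data.frame(difficulty = x$difficulties, se = x$difficulty_se), 3))
  invisible(x)
}

# ML ability for (possibly fractional) raw score r given difficulties
solve_ability <- function(difficulties, r) {
  f <- function(th) sum(plogis(th - difficulties)) - r
  uniroot(f, c(-35, 35), tol = 1e-10)$root
}

ability_table <- function(difficulties, m) {
  rs <- 0:m
  theta <- rep(NA_real_, m + 1L)
  se <- rep(NA_real_, m + 1L)
  extreme <- rs == 0L | rs == m
  for (r in rs[!extreme]) {
    th <- solve_ability(difficulties, r)
    p <- plogis(th - difficulties)
    theta[r + 1L] <- th
    se[r + 1L] <- 1 / sqrt(sum(p * (1 - p)))
  }
  data.frame(raw_score = rs, theta = theta, se = se, extreme = extreme)
}

#' Maximum-likelihood person abilities
#'
#' The ML ability depends on the raw score only and solves
#' `sum_i P(theta, beta_i) = r`; zero and perfect raw scores have no finite
#' ML estimate and are flagged.
#'
#' @param fit a `rasch_fit`.
#' @return Data frame: `person_id`, `raw_score`, `theta`, `se`, `extreme`.
#' @export
estimate_abilities <- function(fit) {
  stopifnot(inherits(fit, "rasch_fit"))
  m <- length(fit$difficulties)
  data.frame(person_id = names(fit$raw_scores),
             raw_score = unname(fit$raw_scores),
             theta = unname(fit$abilities[names(fit$raw_scores)]),
             se = unname(fit$ability_se[names(fit$raw_scores)]),
             extreme = unname(fit$raw_scores == 0L | fit$raw_scores == m),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Wilson-Hilferty standardization of a mean-square fit statistic
msq_to_t <- function(msq, var_msq) {
  q <- sqrt(pmax(var_msq, .Machine$double.eps))
  (msq^(1 / 3) - 1) * (3 / q) + q / 3
}

#' Item fit statistics (outfit/infit mean squares, standardized fit, chi-square)
#'
#' Standardized residuals `z = (x - E)/sqrt(E(1-E))` are formed over the
#' non-extreme complete persons. Outfit is the unweighted mean square of `z`;
#' infit the information-weighted mean square. The t-statistics use the
#' Wilson-Hilferty cube-root transformation with the standard kurtosis-based
#' variance. The per-item chi-square is the sum of squared residuals on
#' `n - 1` degrees of freedom; its p-value is Bonferroni-adjusted by the
#' number of items. Conventional quality bands: mean squares in (0.60, 1.40),
#' t in (-2.5, 2.5).
#'
#' @param fit a `rasch_fit`.
#' @param msq_limits,t_limits flagging bands.
#' @return Data frame: `item`, `outfit_msq`, `infit_msq`, `outfit_t`,
#'   `infit_t`, `chi2`, `df`, `p`, `p_bonferroni`, `misfit`.
#' @export
item_fit <- function(fit, msq_limits = c(0.60, 1.40), t_limits = c(-2.5, 2.5)) {
  stopifnot(inherits(fit, "rasch_fit"))
  E <- fit$expected; X <- fit$observed
  W <- E * (1 - E)
  C <- W * (1 - 3 * W)            # E[(x-E)^4] for a Bernoulli cell
  Z2 <- (X - E)^2 / W
  n <- nrow(X); m <- ncol(X)
  out <- lapply(seq_len(m), function(i) {
    z2 <- Z2[, i]; w <- W[, i]; cc <- C[, i]
    outfit <- mean(z2)
    infit <- sum((X[, i] - E[, i])^2) / sum(w)
    var_out <- sum(cc / w^2) / n^2 - 1 / n
    var_in <- sum(cc - w^2) / sum(w)^2
    chi2 <- sum(z2)
    p <- pchisq(chi2, df = n - 1L, lower.tail = FALSE)
    data.frame(item = colnames(X)[i], outfit_msq = outfit, infit_msq = infit,
               outfit_t = msq_to_t(outfit, var_out),
               infit_t = msq_to_t(infit, var_in),
               chi2 = chi2, df = n - 1L, p = p,
               p_bonferroni = min(1, p * m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$misfit <- out$outfit_msq < msq_limits[1] | out$outfit_msq > msq_limits[2] |
    out$infit_msq < msq_limits[1] | out$infit_msq > msq_limits[2] |
    out$outfit_t < t_limits[1] | out$outfit_t > t_limits[2] |
    out$infit_t < t_limits[1] | out$infit_t > t_limits[2]
  out
}

#' Internal-consistency indices: PSI and mean inter-item correlation
#'
#' The person separation index is the separation-reliability form
#' `(observed ability variance - mean squared ability SE) / observed ability
#' variance`, clipped to `[0, 1]`; it reads like Cronbach's alpha. Following
#' the convention of the reference Rasch implementations (e.g. the eRm
#' package's separation reliability), the observed ability variance is taken
#' over all complete persons — zero and perfect raw scores enter through
#' abilities extrapolated linearly from the two adjacent interior raw
#' scores — while the mean squared standard error averages the persons whose
#' ML ability (and hence SE) is defined. For short scales the mean
#' inter-item Pearson correlation (pairwise-complete) is reported alongside.
#'
#' @param fit a `rasch_fit`.
#' @param matrix the binary response matrix the fit was computed from.
#' @return List with `psi` (NA with `psi_defined = FALSE` when the observed
#'   ability variance is zero) and `mean_interitem_r`.
#' @export
reliability <- function(fit, matrix) {
  stopifnot(inherits(fit, "rasch_fit"))
  x <- as_response_matrix(matrix)
  m <- length(fit$difficulties)
  st <- fit$score_table
  th_by_score <- st$theta
  # linear extrapolation of the ability table to the extreme raw scores
  th_by_score[1L] <- st$theta[2L] - (st$theta[3L] - st$theta[2L])
  th_by_score[m + 1L] <- st$theta[m] + (st$theta[m] - st$theta[m - 1L])
  raw <- fit$raw_scores
  th <- th_by_score[raw + 1L]
  se <- st$se[raw + 1L]            # NA at extreme scores
  n_def <- sum(!is.na(se))
  if (length(th) < 2L || n_def < 2L) {
    stop("need >= 2 non-extreme persons", call. = FALSE)
  }
  v <- var(th)
  if (v <= 0) {
    psi <- NA_real_; defined <- FALSE
  } else {
    psi <- min(1, max(0, (v - mean(se^2, na.rm = TRUE)) / v)); defined <- TRUE
  }
  cm <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r_bar <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  list(psi = psi, psi_defined = defined, mean_interitem_r = r_bar)
}
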