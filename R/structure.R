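#' Configuration for the fixed-margin matrix sampler
#'
#' Defaults: 1000 burn-in sweeps, 16 sweeps between samples, 500 samples; one
#' sweep is `nrow(matrix)` attempted checkerboard-swap proposals.
#'
#' @param burn_in burn-in length in sweeps.
#' @param thin sweeps between retained samples.
#' @param n_samples number of matrices to emit.
#' @param seed optional integer seed applied before the chain runs.
#' @return Object of class `margin_sampler`.
#' @export
margin_sampler <- function(burn_in = 1000L, thin = 16L, n_samples = 500L,
                           seed = NULL) {
  stopifnot(burn_in >= 0L, thin >= 1L, n_samples >= 1L)
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "margin_sampler")
}

#' Sample binary matrices with the observed margins
#'
#' MCMC over 2x2 checkerboard swaps (alternating rectangles), which preserve
#' every row and column sum exactly; the symmetric proposal makes the
#' stationary distribution uniform over the margin-fixed reference set. This
#' is the reference set underlying quasi-exact nonparametric Rasch tests.
#'
#' @param matrix binary response matrix without missing cells.
#' @param sampler a [margin_sampler()].
#' @return 3-d integer array `persons x items x n_samples` with attribute
#'   `accepted` (number of accepted swaps). If no swap is ever accepted and
#'   the matrix admits none, the observed matrix is emitted with a warning.
#' @export
sample_fixed_margins <- function(matrix, sampler = margin_sampler()) {
  matrix <- as_response_matrix(matrix)
  if (anyNA(matrix)) stop("matrix must have no missing cells", call. = FALSE)
  stopifnot(inherits(sampler, "margin_sampler"))
  if (!is.null(sampler$seed)) set.seed(sampler$seed)
  sweep <- nrow(matrix)
  res <- margin_chain_cpp(matrix, sampler$burn_in * sweep,
                          sampler$thin * sweep, sampler$n_samples)
  if (res$accepted == 0 && !has_checkerboard(matrix)) {
    warning("matrix admits no margin-preserving swap; emitting the observed matrix",
            call. = FALSE)
  }
  out <- res$samples
  attr(out, "accepted") <- res$accepted
  out
}

# does any 2x2 submatrix form a checkerboard?
has_checkerboard <- function(m) {
  cs <- utils::combn(ncol(m), 2L)
  for (k in seq_len(ncol(cs))) {
    a <- m[, cs[1L, k]]; b <- m[, cs[2L, k]]
    if (any(a == 1L & b == 0L) && any(a == 0L & b == 1L)) return(TRUE)
  }
  FALSE
}

#' Ponocny's T1 quasi-exact test for local dependence
#'
#' For every item pair the statistic counts persons with equal responses on
#' the two items (both 0 or both 1); under fixed margins this is a monotone
#' function of the both-positive count, so large values indicate positive
#' local dependence ("increased inter-item correlation"). The one-sided
#' p-value is the proportion of margin-fixed sampled matrices whose statistic
#' reaches the observed one, with the observed matrix included (add-one rule),
#' so p is never zero.
#'
#' @param matrix binary response matrix without missing cells.
#' @param sampler a [margin_sampler()].
#' @param alpha flagging level for local dependence.
#' @return Data frame with one row per item pair: `item_i`, `item_j`,
#'   `statistic`, `p`, `flagged`.
#' @export
ponocny_t1 <- function(matrix, sampler = margin_sampler(), alpha = 0.05) {
  x <- as_response_matrix(matrix)
  samples <- sample_fixed_margins(x, sampler)
  m <- ncol(x); n <- nrow(x)
  pairs <- utils::combn(m, 2L)
  cs <- colSums(x)
  agree_from_cross <- function(cross) {
    # agreements(i,j) = n - s_i - s_j + 2 * n11(i,j); margins are fixed
    n - outer(cs, cs, "+") + 2 * cross
  }
  obs_agree <- agree_from_cross(crossprod(x))
  n_samples <- dim(samples)[3L]
  exceed <- array(0L, c(m, m))
  for (s in seq_len(n_samples)) {
    ag <- agree_from_cross(crossprod(samples[, , s]))
    exceed <- exceed + (ag >= obs_agree)
  }
  out <- data.frame(
    item_i = colnames(x)[pairs[1L, ]],
    item_j = colnames(x)[pairs[2L, ]],
    statistic = obs_agree[t(pairs)],
    p = (1 + exceed[t(pairs)]) / (n_samples + 1),
    stringsAsFactors = FALSE
  )
  out$flagged <- out$p < alpha
  out
}

#' Modified parallel analysis for unidimensionality
#'
#' Compares the second eigenvalue of the inter-item tetrachoric correlation
#' matrix with its Monte Carlo distribution under the fitted unidimensional
#' Rasch model. Null datasets are drawn conditionally on each person's
#' observed raw score: under the Rasch model the raw score is sufficient for
#' the person parameter, so the conditional pattern distribution given the
#' score depends only on the fitted difficulties and no assumption about the
#' latent trait distribution is needed (point-estimate abilities would
#' miscalibrate the null). A non-significant p-value is consistent with
#' unidimensionality.
#'
#' @param matrix binary response matrix (complete cases are used; at most 16
#'   items, since the conditional sampler enumerates response patterns).
#' @param fit the `rasch_fit` for `matrix`.
#' @param n_mc number of Monte Carlo null datasets (>= 100; the validation
#'   study used 2000).
#' @param seed optional integer seed.
#' @return List of class `parallel_analysis`: `p`, `observed_second_eigenvalue`,
#'   `null_second_eigenvalues`, `n_mc`, `seed`.
#' @export
modified_parallel_analysis <- function(matrix, fit, n_mc = 2000L, seed = NULL) {
  stopifnot(inherits(fit, "rasch_fit"))
  if (n_mc < 100L) stop("n_mc must be >= 100", call. = FALSE)
  if (!fit$converged) stop("Rasch fit did not converge", call. = FALSE)
  x <- as_response_matrix(matrix)
  x <- x[rowSums(is.na(x)) == 0L, , drop = FALSE]
  m <- ncol(x)
  if (m > 16L) stop("conditional pattern sampler supports at most 16 items",
                    call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  second_ev <- function(mm) eigen(tetrachoric_matrix(mm), symmetric = TRUE,
                                  only.values = TRUE)$values[2L]
  obs <- second_ev(x)
  raw <- rowSums(x)
  cs <- conditional_pattern_tables(fit$difficulties)
  groups <- split(seq_len(nrow(x)), raw)
  null_ev <- vapply(seq_len(n_mc), function(i) {
    sim <- x
    for (g in names(groups)) {
      tab <- cs[[as.integer(g) + 1L]]
      idx <- groups[[g]]
      pick <- sample.int(nrow(tab$pats), length(idx), replace = TRUE,
                         prob = tab$w)
      sim[idx, ] <- tab$pats[pick, , drop = FALSE]
    }
    suppressWarnings(second_ev(sim))
  }, numeric(1))
  structure(list(p = (1 + sum(null_ev >= obs)) / (n_mc + 1),
                 observed_second_eigenvalue = obs,
                 null_second_eigenvalues = null_ev,
                 n_mc = n_mc, seed = seed),
            class = "parallel_analysis")
}

# per raw score r: all response patterns with that score and their
# conditional probabilities prod(eps^x) / gamma_r under the Rasch model
conditional_pattern_tables <- function(difficulties) {
  m <- length(difficulties)
  eps <- exp(-difficulties)
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))[, seq_len(m), drop = FALSE]
  colnames(pats) <- names(difficulties)
  rs <- rowSums(pats)
  lapply(0:m, function(r) {
    pr <- pats[rs == r, , drop = FALSE]
    w <- exp(pr %*% log(eps))
    list(pats = pr, w = as.numeric(w / sum(w)))
  })
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("Modified parallel analysis: second eigenvalue %.3f, p = %.3f (%d MC samples)\n",
              x$observed_second_eigenvalue, x$p, x$n_mc))
  invisible(x)
}
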