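# Gauss-Legendre nodes/weights on [0, 1] via Golub-Welsch (symmetric
# tridiagonal Jacobi matrix); cached at first use.
gauss_legendre01 <- local({
  cache <- NULL
  function(n = 32L) {
    if (!is.null(cache)) return(cache)
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    Jm <- matrix(0, n, n)
    Jm[cbind(i, i + 1L)] <- b; Jm[cbind(i + 1L, i)] <- b
    e <- eigen(Jm, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1L, ]^2
    ord <- order(x)
    cache <<- list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
    cache
  }
})

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard bivariate normal with correlation `rho`,
#' by Gauss-Legendre quadrature of Plackett's identity
#' `d Phi2 / d rho = phi2(h, k; rho)` from the independence baseline.
#'
#' @param h,k upper integration limits.
#' @param rho correlation in (-1, 1).
#' @return The probability.
#' @export
pbvnorm <- function(h, k, rho) {
  gl <- gauss_legendre01()
  r <- rho * gl$nodes
  omr2 <- 1 - r^2
  dens <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * omr2)) / (2 * pi * sqrt(omr2))
  pnorm(h) * pnorm(k) + rho * sum(gl$weights * dens)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate for a 2x2 table of two dichotomized normal
#' variables: thresholds are set from the margins and the correlation solves
#' the observed both-positive cell probability. Cells of zero receive a 0.5
#' continuity correction.
#'
#' @param tab 2x2 table of counts, rows = first item (0, 1), cols = second.
#' @return Correlation estimate in `[-0.999, 0.999]`.
#' @export
tetrachoric_2x2 <- function(tab) {
  tab <- as.numeric(tab)  # n00, n10, n01, n11 in column-major order
  if (any(tab == 0)) tab <- tab + 0.5
  n <- sum(tab)
  p1 <- (tab[2] + tab[4]) / n   # P(x = 1)
  p2 <- (tab[3] + tab[4]) / n   # P(y = 1)
  p11 <- tab[4] / n
  h <- qnorm(1 - p1); k <- qnorm(1 - p2)
  # P(Z1 > h, Z2 > k) = Phi2(-h, -k, rho)
  f <- function(rho) pbvnorm(-h, -k, rho) - p11
  lo <- f(-0.999); hi <- f(0.999)
  if (lo >= 0) return(-0.999)
  if (hi <= 0) return(0.999)
  uniroot(f, c(-0.999, 0.999), tol = 1e-8)$root
}

#' Inter-item tetrachoric correlation matrix
#'
#' Pairwise-complete tetrachoric correlations between all item pairs. If the
#' resulting matrix is not positive semi-definite it is smoothed by clipping
#' negative eigenvalues (with a warning) and rescaling to unit diagonal.
#'
#' @param matrix binary response matrix.
#' @return Correlation matrix with attribute `smoothed` (logical).
#' @export
tetrachoric_matrix <- function(matrix) {
  matrix <- as_response_matrix(matrix)
  m <- ncol(matrix)
  R <- diag(m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ok <- !is.na(matrix[, i]) & !is.na(matrix[, j])
    tab <- table(factor(matrix[ok, i], levels = 0:1),
                 factor(matrix[ok, j], levels = 0:1))
    R[i, j] <- R[j, i] <- tetrachoric_2x2(tab)
  }
  dimnames(R) <- list(colnames(matrix), colnames(matrix))
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    warning("tetrachoric matrix not positive semi-definite; smoothing by eigenvalue clipping",
            call. = FALSE)
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    dimnames(R) <- list(colnames(matrix), colnames(matrix))
    smoothed <- TRUE
  }
  attr(R, "smoothed") <- smoothed
  R
}
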