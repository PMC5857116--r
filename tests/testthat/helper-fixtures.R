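# shared fixtures and independent oracles used across test files

scale_items7 <- starmh_difficulties()$item

# simulate a scale-item response matrix at the package's default geometry
sim_scale_matrix <- function(n = 185, seed = 1, ...) {
  sim <- simulate_cohort(sim_config(n_persons = n, seed = seed, ...))
  sim$cohort$responses[, scale_items7]
}

# brute-force elementary symmetric functions by pattern enumeration
esf_brute <- function(eps) {
  m <- length(eps)
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))
  rs <- rowSums(pats)
  vapply(0:m, function(r) {
    sum(apply(pats[rs == r, , drop = FALSE], 1L, function(x) prod(eps^x)))
  }, numeric(1))
}

# brute-force AUC as pairwise concordance (wins + half ties)
auc_brute <- function(scores, caseness) {
  xs <- scores[caseness == 1]
  ys <- scores[caseness == 0]
  tot <- 0
  for (x in xs) tot <- tot + sum(x > ys) + 0.5 * sum(x == ys)
  tot / (length(xs) * length(ys))
}

# brute-force BH step-up adjustment from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[ord[i]] / i)
    adj[ord[i]] <- prev
  }
  pmin(adj, 1)
}

# enumerate every 0/1 matrix with the given row and column sums
enum_fixed_margins <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  row_opts <- lapply(row_sums, function(r) {
    if (r == 0) return(list(integer(nc)))
    cols <- utils::combn(nc, r)
    lapply(seq_len(ncol(cols)), function(j) {
      v <- integer(nc); v[cols[, j]] <- 1L; v
    })
  })
  out <- list()
  rec <- function(i, acc, colsum) {
    if (any(colsum > col_sums)) return()
    if (i > nr) {
      if (all(colsum == col_sums)) out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return()
    }
    for (v in row_opts[[i]]) rec(i + 1L, c(acc, list(v)), colsum + v)
  }
  rec(1L, list(), integer(nc))
  out
}
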