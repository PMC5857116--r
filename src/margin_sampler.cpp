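#include <Rcpp.h>
using namespace Rcpp;

// Metropolis chain over 0/1 matrices with fixed row and column margins.
// Proposal: pick two rows and two columns uniformly; if the 2x2 submatrix is
// a checkerboard ([1,0;0,1] or [0,1;1,0]) swap it, which preserves every
// margin. The proposal is symmetric, so the stationary distribution is
// uniform over the margin-fixed reference set (connected under such swaps).
// Uses R's RNG so results are reproducible under set.seed().

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List margin_chain_cpp(IntegerMatrix x0, int burn_in_props, int thin_props,
                      int n_samples) {
  IntegerMatrix x = clone(x0);
  const int nr = x.nrow(), nc = x.ncol();
  double accepted = 0.0;
  IntegerVector out(static_cast<R_xlen_t>(nr) * nc * n_samples);

  auto run = [&](long props) {
    for (long t = 0; t < props; ++t) {
      int r1 = runif_int(nr), r2 = runif_int(nr);
      int c1 = runif_int(nc), c2 = runif_int(nc);
      if (r1 == r2 || c1 == c2) continue;
      int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
      if (a == d && b == c && a != b) {
        x(r1, c1) = b; x(r1, c2) = a; x(r2, c1) = d; x(r2, c2) = c;
        accepted += 1.0;
      }
    }
  };

  run(burn_in_props);
  for (int s = 0; s < n_samples; ++s) {
    run(thin_props);
    R_xlen_t off = static_cast<R_xlen_t>(s) * nr * nc;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        out[off + static_cast<R_xlen_t>(j) * nr + i] = x(i, j);
  }
  out.attr("dim") = IntegerVector::create(nr, nc, n_samples);
  return List::create(_["samples"] = out, _["accepted"] = accepted);
}
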