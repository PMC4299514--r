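#include <Rcpp.h>
using namespace Rcpp;

// Hit-and-run walk on the box-constrained affine face.
//
// The walk lives in {x0 + N t : lb <= x <= ub}: directions are isotropic in
// the null-space basis N (free coordinates only), the step is uniform on
// the feasible segment, and every `thin`-th state after `burn_in` steps is
// recorded. Uses R's RNG so runs are reproducible under set.seed().
//
// [[Rcpp::export(name = ".hit_and_run_walk")]]
NumericMatrix hit_and_run_walk(NumericMatrix N, NumericVector lb,
                               NumericVector ub, NumericVector x0,
                               int n, int burn_in, int thin) {
  const int nf = N.nrow(), k = N.ncol();
  NumericVector x = clone(x0);
  NumericVector d(nf);
  NumericMatrix out(n, nf);
  const int total = burn_in + n * thin;
  int recorded = 0;
  for (int step = 1; step <= total; ++step) {
    // random direction in the affine hull
    double norm = 0.0;
    NumericVector z = rnorm(k);
    for (int i = 0; i < nf; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += N(i, j) * z[j];
      d[i] = s;
      norm += s * s;
    }
    if (norm < 1e-28) continue;
    norm = std::sqrt(norm);
    // feasible segment [tlo, thi] along d
    double tlo = -INFINITY, thi = INFINITY;
    for (int i = 0; i < nf; ++i) {
      double di = d[i] / norm;
      d[i] = di;
      if (std::fabs(di) < 1e-13) continue;
      double a = (lb[i] - x[i]) / di, b = (ub[i] - x[i]) / di;
      double lo = a < b ? a : b, hi = a < b ? b : a;
      if (lo > tlo) tlo = lo;
      if (hi < thi) thi = hi;
    }
    if (!(thi > tlo) || !std::isfinite(thi) || !std::isfinite(tlo)) continue;
    double t = tlo + unif_rand() * (thi - tlo);
    for (int i = 0; i < nf; ++i) {
      x[i] += t * d[i];
      if (x[i] < lb[i]) x[i] = lb[i];       // rounding guard
      if (x[i] > ub[i]) x[i] = ub[i];
    }
    if (step > burn_in && (step - burn_in) % thin == 0) {
      for (int i = 0; i < nf; ++i) out(recorded, i) = x[i];
      ++recorded;
    }
  }
  // pathological (blocked) walks: pad with the last state
  for (; recorded < n; ++recorded)
    for (int i = 0; i < nf; ++i) out(recorded, i) = x[i];
  return out;
}
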