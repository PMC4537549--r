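#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method kernel.
//
// The network is passed in flattened form: per reaction a law type
// (0 = mass action, 1 = Michaelis-Menten), scalar parameters, ragged
// substrate index/coefficient arrays addressed by offsets, and an optional
// ragged inhibitor list (non-competitive factor 1/(1 + x/Ki)).
// Unit-volume convention: propensities equal macroscopic fluxes evaluated
// at the copy-number state. Uses R's RNG so set.seed() governs
// reproducibility.

static double propensity(int j, const NumericVector& x,
                         const IntegerVector& type,
                         const NumericVector& p1, const NumericVector& p2,
                         const IntegerVector& sub_off,
                         const IntegerVector& sub_idx,
                         const IntegerVector& sub_coef,
                         const IntegerVector& inh_off,
                         const IntegerVector& inh_idx,
                         const NumericVector& inh_ki) {
  double a;
  if (type[j] == 0) { // mass action: k * prod x^coef
    a = p1[j];
    for (int q = sub_off[j]; q < sub_off[j + 1]; ++q) {
      for (int c = 0; c < sub_coef[q]; ++c) a *= x[sub_idx[q]];
    }
  } else { // MM on first substrate: Vmax * s / (Km + s)
    double s = x[sub_idx[sub_off[j]]];
    a = p1[j] * s / (p2[j] + s);
  }
  for (int q = inh_off[j]; q < inh_off[j + 1]; ++q) {
    a /= 1.0 + x[inh_idx[q]] / inh_ki[q];
  }
  return a > 0 ? a : 0.0;
}

// [[Rcpp::export]]
NumericVector ssa_run(IntegerMatrix stoich, IntegerVector type,
                      NumericVector p1, NumericVector p2,
                      IntegerVector sub_off, IntegerVector sub_idx,
                      IntegerVector sub_coef, IntegerVector inh_off,
                      IntegerVector inh_idx, NumericVector inh_ki,
                      NumericVector x0, NumericVector record_times,
                      int n_paths) {
  const int N = stoich.nrow(), R = stoich.ncol(), T = record_times.size();
  NumericVector out(Dimension(n_paths, T, N));
  NumericVector x(N), a(R);
  RNGScope scope;

  for (int path = 0; path < n_paths; ++path) {
    for (int i = 0; i < N; ++i) x[i] = x0[i];
    double t = 0.0;
    int rec = 0;
    while (rec < T) {
      double a0 = 0.0;
      for (int j = 0; j < R; ++j) {
        a[j] = propensity(j, x, type, p1, p2, sub_off, sub_idx, sub_coef,
                          inh_off, inh_idx, inh_ki);
        a0 += a[j];
      }
      double t_next;
      if (a0 <= 0.0) {
        t_next = R_PosInf; // absorbed: state stays constant
      } else {
        t_next = t + R::rexp(1.0 / a0);
      }
      while (rec < T && record_times[rec] < t_next) {
        for (int i = 0; i < N; ++i)
          out[path + n_paths * (rec + T * i)] = x[i];
        ++rec;
      }
      if (rec >= T) break;
      if (!R_FINITE(t_next)) break;
      t = t_next;
      double u = R::unif_rand() * a0, cum = 0.0;
      int j = R - 1;
      for (int q = 0; q < R; ++q) {
        cum += a[q];
        if (u <= cum) { j = q; break; }
      }
      for (int i = 0; i < N; ++i) x[i] += stoich(i, j);
    }
    if (path % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
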