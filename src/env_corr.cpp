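// All-pairs orthogonalized envelope correlation over sliding windows.
//
// For a reference ROI j with analytic signal X and another ROI i with
// analytic signal Y, the zero-phase-lag component of Y along X is removed:
//   Y_perp_X(t) = Im( Y(t) * conj(X(t)) / |X(t)| ),
// the envelope of the (real) orthogonalized series is its absolute value,
// and the directional coupling is the Pearson correlation of that envelope
// with |X| over each window. The undirected pair value averages both
// directions. Window sums are read off cumulative sums, so the cost is
// O(n^2 T) in the recording length rather than in the (overlapping)
// total window length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double pearson_from_sums(double n, double sx, double sxx,
                                       double sy, double syy, double sxy,
                                       bool& degenerate) {
  const double vx = n * sxx - sx * sx;
  const double vy = n * syy - sy * sy;
  if (vx <= 0.0 || vy <= 0.0) { degenerate = true; return 0.0; }
  degenerate = false;
  return (n * sxy - sx * sy) / std::sqrt(vx * vy);
}

// re, im: n_rois x n_samples real/imaginary parts of the analytic signals.
// starts, stops: 0-based half-open window bounds (samples).
// Returns: `values` (n x n x n_windows cube, symmetric slices, NaN
// diagonal) and `zero_var` (count of directional correlations defined as 0
// because an envelope had no variance in the window).
// [[Rcpp::export]]
Rcpp::List env_corr_cpp(const arma::mat& re, const arma::mat& im,
                        const arma::ivec& starts, const arma::ivec& stops) {
  const uword n = re.n_rows;
  const uword W = starts.n_elem;
  const uword T = re.n_cols;
  if (im.n_rows != n || im.n_cols != T) Rcpp::stop("re/im shape mismatch");
  if (stops.n_elem != W) Rcpp::stop("starts/stops length mismatch");
  for (uword w = 0; w < W; ++w) {
    if (starts[w] < 0 || stops[w] <= starts[w] + 1 ||
        static_cast<uword>(stops[w]) > T)
      Rcpp::stop("invalid window bounds");
  }

  // time-major copies: one contiguous column per ROI
  const mat A = re.t();                 // T x n, real part
  const mat B = im.t();                 // T x n, imaginary part
  const mat E = sqrt(A % A + B % B);    // envelopes

  cube out(n, n, W);
  unsigned long zero_var = 0;

  // cumulative sums of e and e^2 per ROI, prefixed with 0
  mat ce(T + 1, n), ce2(T + 1, n);
  for (uword i = 0; i < n; ++i) {
    const double* e = E.colptr(i);
    double* c = ce.colptr(i);
    double* c2 = ce2.colptr(i);
    c[0] = 0.0; c2[0] = 0.0;
    double s = 0.0, s2 = 0.0;
    for (uword t = 0; t < T; ++t) {
      s += e[t]; s2 += e[t] * e[t];
      c[t + 1] = s; c2[t + 1] = s2;
    }
  }

  std::vector<double> Rj(T), Ij(T), cd(T + 1), cd2(T + 1), cde(T + 1);

  // per-ROI envelope maxima: a residual negligible relative to its own
  // envelope (e.g. proportional signals) carries no orthogonal
  // information and must not correlate rounding noise
  vec emaxs(n);
  for (uword i = 0; i < n; ++i) emaxs[i] = E.col(i).max();

  for (uword j = 0; j < n; ++j) {
    const double* ej = E.colptr(j);
    const double emax = E.col(j).max();
    const double eps = 1e-12 * emax;
    const bool all_valid = (emax > 0.0) && (E.col(j).min() >= eps);

    if (!all_valid) {
      // guarded fallback: per window, drop samples with negligible |X_j|
      const vec ejv = E.col(j);
      for (uword w = 0; w < W; ++w) {
        const uword a = static_cast<uword>(starts[w]);
        const uword b = static_cast<uword>(stops[w]);
        uvec valid = find(ejv.subvec(a, b - 1) >= eps) + a;
        if (valid.n_elem < 2) {
          zero_var += n - 1;
          for (uword i = 0; i < n; ++i) out(i, j, w) = 0.0;
          continue;
        }
        const vec ev = ejv.elem(valid);
        const vec Rv = vec(A.col(j)).elem(valid) / ev;
        const vec Iv = vec(B.col(j)).elem(valid) / ev;
        const double m = static_cast<double>(ev.n_elem);
        const double se = accu(ev), se2 = dot(ev, ev);
        for (uword i = 0; i < n; ++i) {
          if (i == j) { out(i, j, w) = 0.0; continue; }
          const vec dv = abs(vec(B.col(i)).elem(valid) % Rv -
                             vec(A.col(i)).elem(valid) % Iv);
          if (dv.max() < 1e-10 * E.col(i).max()) {
            ++zero_var;
            out(i, j, w) = 0.0;
            continue;
          }
          bool deg;
          const double r = pearson_from_sums(m, accu(dv), dot(dv, dv),
                                             se, se2, dot(dv, ev), deg);
          if (deg) ++zero_var;
          out(i, j, w) = r;
        }
      }
      continue;
    }

    // fast path: unit phasor of the reference, cumulative sums of the
    // orthogonalized envelope per target ROI
    {
      const double* aj = A.colptr(j);
      const double* bj = B.colptr(j);
      for (uword t = 0; t < T; ++t) {
        Rj[t] = aj[t] / ej[t];
        Ij[t] = bj[t] / ej[t];
      }
    }
    const double* cej = ce.colptr(j);
    const double* ce2j = ce2.colptr(j);

    for (uword i = 0; i < n; ++i) {
      if (i == j) {
        for (uword w = 0; w < W; ++w) out(i, j, w) = 0.0;
        continue;
      }
      const double* ai = A.colptr(i);
      const double* bi = B.colptr(i);
      double s = 0.0, s2 = 0.0, sde = 0.0, dmax = 0.0;
      cd[0] = 0.0; cd2[0] = 0.0; cde[0] = 0.0;
      for (uword t = 0; t < T; ++t) {
        const double v = std::fabs(bi[t] * Rj[t] - ai[t] * Ij[t]);
        if (v > dmax) dmax = v;
        s += v; s2 += v * v; sde += v * ej[t];
        cd[t + 1] = s; cd2[t + 1] = s2; cde[t + 1] = sde;
      }
      if (dmax < 1e-10 * emaxs[i]) {
        zero_var += W;
        for (uword w = 0; w < W; ++w) out(i, j, w) = 0.0;
        continue;
      }
      for (uword w = 0; w < W; ++w) {
        const uword a = static_cast<uword>(starts[w]);
        const uword b = static_cast<uword>(stops[w]);
        const double m = static_cast<double>(b - a);
        bool deg;
        const double r = pearson_from_sums(
            m, cd[b] - cd[a], cd2[b] - cd2[a],
            cej[b] - cej[a], ce2j[b] - ce2j[a],
            cde[b] - cde[a], deg);
        if (deg) ++zero_var;
        out(i, j, w) = r;
      }
    }
  }

  for (uword w = 0; w < W; ++w) {
    mat sym = 0.5 * (out.slice(w) + out.slice(w).t());
    sym.diag().fill(datum::nan);
    out.slice(w) = sym;
  }

  return Rcpp::List::create(Rcpp::Named("values") = out,
                            Rcpp::Named("zero_var") = zero_var);
}
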