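#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classical normalized Lomb-Scargle periodogram on a uniform frequency grid
// f_k = f0 + k * df, k = 0..nf-1, for unevenly sampled (t, y).
//
// Uses the phase-shift (tau) formulation. Trigonometric terms across the
// frequency grid are obtained by complex rotation per sample (two extra
// multiplies per frequency instead of two transcendental calls), which is
// what makes the sliding-window feature extraction tractable.
//
// y is centred internally; normalization is by 2 * sample variance (n-1
// denominator), the classical form in which pure white noise has expected
// ordinate ~1 at every frequency. Degenerate input (variance ~0) yields an
// all-zero spectrum.
static void ls_power(const double* t, const double* y, int n,
                     double f0, double df, int nf, double* P,
                     std::vector<double>& C, std::vector<double>& S,
                     std::vector<double>& C2, std::vector<double>& S2) {
  std::fill(C.begin(), C.end(), 0.0);
  std::fill(S.begin(), S.end(), 0.0);
  std::fill(C2.begin(), C2.end(), 0.0);
  std::fill(S2.begin(), S2.end(), 0.0);

  double mean = 0.0;
  for (int j = 0; j < n; ++j) mean += y[j];
  mean /= n;
  double var = 0.0;
  for (int j = 0; j < n; ++j) var += (y[j] - mean) * (y[j] - mean);
  var /= (n - 1);
  if (var < 1e-20) {
    std::fill(P, P + nf, 0.0);
    return;
  }

  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < n; ++j) {
    const double yc = y[j] - mean;
    const double w0 = twopi * f0 * t[j];
    const double wd = twopi * df * t[j];
    double c = std::cos(w0), s = std::sin(w0);
    const double cd = std::cos(wd), sd = std::sin(wd);
    for (int k = 0; k < nf; ++k) {
      C[k]  += yc * c;
      S[k]  += yc * s;
      C2[k] += c * c - s * s;   // cos(2 w t)
      S2[k] += 2.0 * s * c;     // sin(2 w t)
      const double cn = c * cd - s * sd;
      s = s * cd + c * sd;
      c = cn;
    }
  }

  for (int k = 0; k < nf; ++k) {
    const double R = std::hypot(C2[k], S2[k]);
    // Sum cos^2(w(t - tau)) = (n + R)/2, sum sin^2 = (n - R)/2
    const double phi = std::atan2(S2[k], C2[k]); // 2 w tau
    const double ct = std::cos(0.5 * phi), st = std::sin(0.5 * phi);
    const double Cc = C[k] * ct + S[k] * st;
    const double Ss = S[k] * ct - C[k] * st;
    const double denc = 0.5 * (n + R);
    const double dens = 0.5 * (n - R);
    double p = 0.0;
    if (denc > 1e-12) p += Cc * Cc / denc;
    if (dens > 1e-12) p += Ss * Ss / dens;
    P[k] = p / (2.0 * var);
  }
}

// [[Rcpp::export]]
NumericVector ls_periodogram_cpp(NumericVector t, NumericVector y,
                                 double f0, double df, int nf) {
  const int n = t.size();
  if (y.size() != n) stop("t and y must have equal length");
  if (n < 2) stop("need at least 2 samples");
  if (nf < 1 || df <= 0 || f0 <= 0) stop("invalid frequency grid");
  NumericVector P(nf);
  std::vector<double> C(nf), S(nf), C2(nf), S2(nf);
  ls_power(t.begin(), y.begin(), n, f0, df, nf, P.begin(), C, S, C2, S2);
  return P;
}

// Per-window summary features for a batch of half-open windows [lo, hi):
// returns an n_win x 5 matrix (n_beats, mean, sd, LF, HF). Band powers are
// the mean normalized ordinate over grid frequencies in [b_lo, b_hi).
// Windows with fewer than 3 samples get NA spectral features; fewer than 2,
// NA mean/sd as well. `t` must be sorted ascending.
// [[Rcpp::export]]
NumericMatrix window_hrv_cpp(NumericVector t, NumericVector y,
                             NumericVector w_lo, NumericVector w_hi,
                             double f0, double df, int nf,
                             double lf_lo, double lf_hi,
                             double hf_lo, double hf_hi) {
  const int n = t.size(), nw = w_lo.size();
  if (y.size() != n) stop("t and y must have equal length");
  if (w_hi.size() != nw) stop("window bound length mismatch");
  NumericMatrix out(nw, 5);
  colnames(out) = CharacterVector::create("n_beats", "mean_s", "sd_s",
                                          "lf", "hf");
  std::vector<double> P(nf), C(nf), S(nf), C2(nf), S2(nf);

  // band membership on the grid (half-open, tolerant to fp rounding)
  std::vector<int> lf_idx, hf_idx;
  for (int k = 0; k < nf; ++k) {
    const double f = f0 + k * df;
    if (f >= lf_lo - 1e-9 && f < lf_hi - 1e-9) lf_idx.push_back(k);
    if (f >= hf_lo - 1e-9 && f < hf_hi - 1e-9) hf_idx.push_back(k);
  }
  if (lf_idx.empty() || hf_idx.empty())
    stop("frequency grid does not cover the requested bands");

  for (int w = 0; w < nw; ++w) {
    const double lo = w_lo[w], hi = w_hi[w];
    const double* tb = t.begin();
    const int i0 = std::lower_bound(tb, tb + n, lo) - tb;
    const int i1 = std::lower_bound(tb, tb + n, hi) - tb; // [lo, hi)
    const int m = i1 - i0;
    out(w, 0) = m;
    if (m < 2) {
      out(w, 1) = NA_REAL; out(w, 2) = NA_REAL;
      out(w, 3) = NA_REAL; out(w, 4) = NA_REAL;
      continue;
    }
    double mean = 0.0;
    for (int j = i0; j < i1; ++j) mean += y[j];
    mean /= m;
    double ss = 0.0;
    for (int j = i0; j < i1; ++j) ss += (y[j] - mean) * (y[j] - mean);
    out(w, 1) = mean;
    out(w, 2) = std::sqrt(ss / (m - 1));
    if (m < 3) {
      out(w, 3) = NA_REAL; out(w, 4) = NA_REAL;
      continue;
    }
    ls_power(tb + i0, y.begin() + i0, m, f0, df, nf, P.data(), C, S, C2, S2);
    double lf = 0.0, hf = 0.0;
    for (int k : lf_idx) lf += P[k];
    for (int k : hf_idx) hf += P[k];
    out(w, 3) = lf / lf_idx.size();
    out(w, 4) = hf / hf_idx.size();
  }
  return out;
}
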