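// The 22-feature canonical time-series characterization set ("catch22"),
// reimplemented from the published feature definitions. Each feature is a
// scalar summary of one univariate series (here: one 30-s epoch of one
// EEG/EOG channel). Features that are defined on z-scored input z-score
// internally; callers pass the raw epoch.
//
// Degenerate inputs (constant series, too-short series) yield NaN here and
// are imputed downstream (extract_features() replaces non-finite with 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double PI_ = 3.14159265358979323846;

arma::vec zscore(const arma::vec& y) {
  double m = arma::mean(y);
  double s = arma::stddev(y);  // n-1 denominator
  if (s <= 0.0 || !std::isfinite(s)) return arma::vec(y.n_elem, arma::fill::value(arma::datum::nan));
  return (y - m) / s;
}

// Biased autocorrelation via FFT, lags 0..n-1 (acf[0] = 1).
arma::vec acf_fft(const arma::vec& y) {
  int n = y.n_elem;
  int nfft = 1;
  while (nfft < 2 * n) nfft <<= 1;
  arma::vec yc = y - arma::mean(y);
  arma::vec pad(nfft, arma::fill::zeros);
  pad.subvec(0, n - 1) = yc;
  arma::cx_vec F = arma::fft(pad);
  arma::vec s = arma::real(arma::ifft(arma::cx_vec(F % arma::conj(F))));
  arma::vec out(n);
  double s0 = s(0);
  if (s0 <= 0.0) { out.fill(arma::datum::nan); return out; }
  for (int k = 0; k < n; ++k) out(k) = s(k) / s0;
  return out;
}

// First lag at which the acf is <= 0 (or maxtau if it never crosses).
int first_zero_ac(const arma::vec& ac, int maxtau) {
  int ind = 1;
  int lim = std::min<int>(maxtau, ac.n_elem - 1);
  while (ind < lim && ac(ind) > 0) ++ind;
  return ind;
}

double histogram_mode(const arma::vec& z, int nbins) {
  double lo = z.min(), hi = z.max();
  if (!(hi > lo)) return arma::datum::nan;
  double bw = (hi - lo) / nbins;
  std::vector<int> counts(nbins, 0);
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    int b = (int)((z(i) - lo) / bw);
    if (b >= nbins) b = nbins - 1;
    if (b < 0) b = 0;
    counts[b]++;
  }
  int maxc = *std::max_element(counts.begin(), counts.end());
  double sum = 0.0; int nmax = 0;
  for (int b = 0; b < nbins; ++b) {
    if (counts[b] == maxc) { sum += lo + bw * (b + 0.5); nmax++; }
  }
  return sum / nmax;
}

// Linear interpolated first crossing of the acf below 1/e.
double f1ecac(const arma::vec& ac) {
  double thresh = std::exp(-1.0);
  int n = ac.n_elem;
  for (int i = 0; i < n - 1; ++i) {
    if (ac(i + 1) < thresh) {
      double denom = ac(i + 1) - ac(i);
      if (denom == 0.0) return i + 1;
      return i + (thresh - ac(i)) / denom;
    }
  }
  return (double)n;
}

int first_min_ac(const arma::vec& ac) {
  int n = ac.n_elem;
  for (int i = 1; i < n - 1; ++i) {
    if (ac(i) < ac(i - 1) && ac(i) < ac(i + 1)) return i;
  }
  return n;
}

// Auto mutual information (even-width bins) at a given lag.
double histogram_ami_even(const arma::vec& z, int tau, int nbins) {
  int n = z.n_elem;
  if (n <= tau + 1) return arma::datum::nan;
  double lo = z.min() - 0.1, hi = z.max() + 0.1;
  double bw = (hi - lo) / nbins;
  int m = n - tau;
  arma::mat joint(nbins, nbins, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    int b1 = std::min(nbins - 1, (int)((z(i) - lo) / bw));
    int b2 = std::min(nbins - 1, (int)((z(i + tau) - lo) / bw));
    joint(b1, b2) += 1.0;
  }
  joint /= (double)m;
  arma::vec px = arma::sum(joint, 1);
  arma::rowvec py = arma::sum(joint, 0);
  double ami = 0.0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j)
      if (joint(i, j) > 0)
        ami += joint(i, j) * std::log(joint(i, j) / (px(i) * py(j)));
  return ami;
}

int longstretch(const std::vector<int>& b, int target) {
  int best = 0, cur = 0;
  for (size_t i = 0; i < b.size(); ++i) {
    if (b[i] == target) { cur++; if (cur > best) best = cur; }
    else cur = 0;
  }
  return best;
}

// Equiprobable ternary coarse-graining (quantile thresholds at 1/3, 2/3).
arma::ivec ternarize(const arma::vec& y) {
  int n = y.n_elem;
  arma::vec srt = arma::sort(y);
  double q1 = srt((arma::uword)std::ceil(n / 3.0) - 1);
  double q2 = srt((arma::uword)std::ceil(2.0 * n / 3.0) - 1);
  arma::ivec s(n);
  for (int i = 0; i < n; ++i) s(i) = (y(i) <= q1) ? 0 : (y(i) <= q2 ? 1 : 2);
  return s;
}

double transition_matrix_sumdiagcov(const arma::vec& z, int tau) {
  int n = z.n_elem;
  int nd = (n - 1) / tau + 1;
  if (nd < 4) return arma::datum::nan;
  arma::vec yd(nd);
  for (int i = 0; i < nd; ++i) yd(i) = z(i * tau);
  arma::ivec s = ternarize(yd);
  arma::mat T(3, 3, arma::fill::zeros);
  for (int i = 0; i < nd - 1; ++i) T(s(i), s(i + 1)) += 1.0;
  T /= (double)(nd - 1);
  arma::mat C = arma::cov(T);  // covariance between the 3 columns
  return arma::trace(C);
}

// Least-squares cubic spline (one interior knot at n/2) detrend.
arma::vec spline_detrend(const arma::vec& y) {
  int n = y.n_elem;
  double k = (n - 1) / 2.0;
  arma::mat X(n, 5);
  for (int i = 0; i < n; ++i) {
    double t = (double)i;
    X(i, 0) = 1.0; X(i, 1) = t; X(i, 2) = t * t; X(i, 3) = t * t * t;
    double d = t - k;
    X(i, 4) = d > 0 ? d * d * d : 0.0;
  }
  arma::vec beta = arma::solve(X, y);
  return y - X * beta;
}

double periodicity_wang(const arma::vec& y, double th) {
  int n = y.n_elem;
  if (n < 12) return 0.0;
  arma::vec yd = spline_detrend(y);
  arma::vec ac = acf_fft(yd);
  int maxlag = std::max(3, n / 3);
  maxlag = std::min<int>(maxlag, ac.n_elem - 1);
  // first trough, then first peak after it exceeding the threshold
  int trough = -1;
  for (int i = 1; i < maxlag; ++i) {
    if (ac(i) < ac(i - 1) && ac(i) < ac(i + 1)) { trough = i; break; }
  }
  if (trough < 0) return 0.0;
  for (int i = trough + 1; i < maxlag; ++i) {
    if (ac(i) > ac(i - 1) && ac(i) > ac(i + 1) && ac(i) > th) return (double)i;
  }
  return 0.0;
}

double embed2_dist_expfit_meandiff(const arma::vec& z, const arma::vec& ac) {
  int n = z.n_elem;
  int tau = first_zero_ac(ac, n);
  if (tau > n / 10) tau = n / 10;
  if (tau < 1) tau = 1;
  int m = n - tau;             // embedded points (z_i, z_{i+tau})
  if (m < 10) return arma::datum::nan;
  int nd = m - 1;
  arma::vec d(nd);
  for (int i = 0; i < nd; ++i) {
    double dx = z(i + 1) - z(i);
    double dy = z(i + tau + 1) - z(i + tau);
    d(i) = std::sqrt(dx * dx + dy * dy);
  }
  double l = arma::mean(d);
  if (!(l > 0)) return arma::datum::nan;
  // histogram with Scott's-rule bin width, compared against Exp(mean) pdf
  double sd = arma::stddev(d);
  double bw = 3.5 * sd * std::pow((double)nd, -1.0 / 3.0);
  double lo = d.min(), hi = d.max();
  if (!(bw > 0) || !(hi > lo)) return arma::datum::nan;
  int nbins = (int)std::ceil((hi - lo) / bw);
  if (nbins < 1) nbins = 1;
  bw = (hi - lo) / nbins;
  std::vector<int> counts(nbins, 0);
  for (int i = 0; i < nd; ++i) {
    int b = std::min(nbins - 1, (int)((d(i) - lo) / bw));
    counts[b]++;
  }
  double acc = 0.0;
  for (int b = 0; b < nbins; ++b) {
    double center = lo + bw * (b + 0.5);
    double obs = counts[b] / ((double)nd * bw);
    double expct = std::exp(-center / l) / l;
    acc += std::fabs(obs - expct);
  }
  return acc / nbins;
}

double automutual_info_fmmi(const arma::vec& ac, int n) {
  int maxtau = std::min(40, (int)std::ceil(n / 2.0));
  arma::vec ami(maxtau + 1);
  for (int k = 1; k <= maxtau; ++k) {
    double r = ac(k);
    if (r * r >= 1.0) r = r > 0 ? 0.999999 : -0.999999;
    ami(k) = -0.5 * std::log(1.0 - r * r);
  }
  for (int i = 2; i < maxtau; ++i) {
    if (ami(i) < ami(i - 1) && ami(i) < ami(i + 1)) return (double)i;
  }
  return (double)maxtau;
}

// Fenwick tree over sample positions; supports k-th order-statistic queries
// so the median exceedance time at every threshold costs O(log n).
struct PosBit {
  int n;
  std::vector<int> t;
  explicit PosBit(int n_) : n(n_), t(n_ + 1, 0) {}
  void add(int i) { for (++i; i <= n; i += i & -i) t[i]++; }
  int kth(int k) const {  // 0-based position of the k-th smallest (k >= 1)
    int pos = 0, rem = k;
    for (int pw = 1 << (31 - __builtin_clz(n)); pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] < rem) { pos += pw; rem -= t[pos]; }
    }
    return pos;  // 0-based
  }
};

double outlier_include_mdrmd(const arma::vec& z, bool negate) {
  arma::vec y = negate ? arma::vec(-z) : z;
  int n = y.n_elem;
  double inc = 0.01;
  double maxv = y.max();
  if (!(maxv > 0)) return 0.0;
  int nthresh = (int)(maxv / inc) + 1;
  // positions sorted by value descending: the exceedance set at each
  // threshold is a prefix of this ordering
  arma::uvec ord = arma::sort_index(y, "descend");
  PosBit bit(n);
  std::vector<double> frac(nthresh), medpos(nthresh);
  int inserted = 0, used = 0;
  for (int j = nthresh - 1; j >= 0; --j) {
    double thr = j * inc;
    while (inserted < n && y(ord(inserted)) >= thr) {
      bit.add((int)ord(inserted));
      inserted++;
    }
    int m = inserted;
    if (m == 0) { frac[j] = 0; medpos[j] = arma::datum::nan; continue; }
    double med;
    if (m % 2 == 1) med = bit.kth(m / 2 + 1) + 1.0;
    else med = 0.5 * ((bit.kth(m / 2) + 1.0) + (bit.kth(m / 2 + 1) + 1.0));
    frac[j] = 100.0 * m / n;
    medpos[j] = med / (n / 2.0) - 1.0;
    used = std::max(used, j + 1);
  }
  if (used == 0) return 0.0;
  // keep thresholds where at least 2% of samples are above
  int mj = 0;
  for (int j = 0; j < used; ++j) if (frac[j] > 2.0) mj = j;
  std::vector<double> v;
  for (int j = 0; j <= mj; ++j)
    if (std::isfinite(medpos[j])) v.push_back(medpos[j]);
  if (v.empty()) return 0.0;
  std::sort(v.begin(), v.end());
  size_t m = v.size();
  return (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
}

// One-sided Welch spectrum: 8 rectangular segments, 50% overlap (unit fs).
arma::vec welch_rect(const arma::vec& z, arma::vec& omega) {
  int n = z.n_elem;
  int L = std::max(8, (int)std::floor(n / 4.5));
  int hop = L / 2;
  int nfft = 1;
  while (nfft < L) nfft <<= 1;
  int nf = nfft / 2 + 1;
  arma::vec S(nf, arma::fill::zeros);
  int nseg = 0;
  for (int start = 0; start + L <= n; start += hop) {
    arma::vec seg(nfft, arma::fill::zeros);
    seg.subvec(0, L - 1) = z.subvec(start, start + L - 1);
    arma::cx_vec F = arma::fft(seg);
    for (int k = 0; k < nf; ++k) {
      double a = std::norm(F(k));
      S(k) += a / (2.0 * PI_ * L);
    }
    nseg++;
  }
  if (nseg == 0) { S.fill(arma::datum::nan); }
  else S /= (double)nseg;
  omega.set_size(nf);
  for (int k = 0; k < nf; ++k) omega(k) = 2.0 * PI_ * k / nfft;
  return S;
}

double fluct_anal_prop_r1(const arma::vec& z, bool rsrange) {
  int n = z.n_elem;
  arma::vec x = arma::cumsum(z);
  // 50 log-spaced window sizes from 5 to n/2, deduplicated
  int ntau_req = 50;
  std::vector<int> taus;
  double lo = std::log(5.0), hi = std::log(n / 2.0);
  for (int i = 0; i < ntau_req; ++i) {
    int t = (int)std::round(std::exp(lo + (hi - lo) * i / (ntau_req - 1)));
    if (taus.empty() || t != taus.back()) taus.push_back(t);
  }
  int ntau = taus.size();
  if (ntau < 12) return arma::datum::nan;
  arma::vec logtt(ntau), logFF(ntau);
  for (int ti = 0; ti < ntau; ++ti) {
    int tau = taus[ti];
    int nwin = n / tau;
    double acc = 0.0;
    for (int w = 0; w < nwin; ++w) {
      // linear detrend within the window
      double sx = 0, sy = 0, sxx = 0, sxy = 0;
      for (int i = 0; i < tau; ++i) {
        double xi = i, yi = x(w * tau + i);
        sx += xi; sy += yi; sxx += xi * xi; sxy += xi * yi;
      }
      double denom = tau * sxx - sx * sx;
      double b = (tau * sxy - sx * sy) / denom;
      double a = (sy - b * sx) / tau;
      if (rsrange) {
        double rmin = arma::datum::inf, rmax = -arma::datum::inf;
        for (int i = 0; i < tau; ++i) {
          double r = x(w * tau + i) - (a + b * i);
          if (r < rmin) rmin = r;
          if (r > rmax) rmax = r;
        }
        double rng = rmax - rmin;
        acc += rng * rng;
      } else {
        double ss = 0.0;
        for (int i = 0; i < tau; ++i) {
          double r = x(w * tau + i) - (a + b * i);
          ss += r * r;
        }
        acc += ss / tau;
      }
    }
    double F = std::sqrt(acc / nwin);
    logtt(ti) = std::log((double)tau);
    logFF(ti) = std::log(std::max(F, 1e-12));
  }
  // two-regime linear fit in log-log; output the scale split proportion
  int minpts = 6;
  double best = arma::datum::inf;
  int besti = minpts;
  for (int i = minpts; i <= ntau - minpts; ++i) {
    auto sse = [&](int from, int to) {  // inclusive range linear-fit SSE
      int m = to - from + 1;
      double sx = 0, sy = 0, sxx = 0, sxy = 0;
      for (int j = from; j <= to; ++j) {
        sx += logtt(j); sy += logFF(j);
        sxx += logtt(j) * logtt(j); sxy += logtt(j) * logFF(j);
      }
      double denom = m * sxx - sx * sx;
      double b = denom != 0 ? (m * sxy - sx * sy) / denom : 0.0;
      double a = (sy - b * sx) / m;
      double s = 0.0;
      for (int j = from; j <= to; ++j) {
        double r = logFF(j) - (a + b * logtt(j));
        s += r * r;
      }
      return s;
    };
    double tot = sse(0, i - 1) + sse(i - 1, ntau - 1);
    if (tot < best) { best = tot; besti = i; }
  }
  return (double)besti / ntau;
}

}  // namespace

//' @keywords internal
// [[Rcpp::export]]
CharacterVector catch22_feature_names() {
  return CharacterVector::create(
      "DN_HistogramMode_5", "DN_HistogramMode_10",
      "SB_BinaryStats_mean_longstretch1",
      "DN_OutlierInclude_p_001_mdrmd", "DN_OutlierInclude_n_001_mdrmd",
      "CO_f1ecac", "CO_FirstMin_ac",
      "SP_Summaries_welch_rect_area_5_1", "SP_Summaries_welch_rect_centroid",
      "FC_LocalSimple_mean3_stderr", "CO_trev_1_num",
      "CO_HistogramAMI_even_2_5", "IN_AutoMutualInfoStats_40_gaussian_fmmi",
      "MD_hrv_classic_pnn40", "SB_BinaryStats_diff_longstretch0",
      "SB_MotifThree_quantile_hh", "FC_LocalSimple_mean1_tauresrat",
      "CO_Embed2_Dist_tau_d_expfit_meandiff",
      "SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1",
      "SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1",
      "SB_TransitionMatrix_3ac_sumdiagcov", "PD_PeriodicityWang_th0_01");
}

// [[Rcpp::export]]
NumericVector catch22_compute(NumericVector x) {
  int n = x.size();
  NumericVector out(22, NA_REAL);
  out.attr("names") = catch22_feature_names();
  if (n < 16) return out;
  arma::vec y(x.begin(), n, false);
  if (!y.is_finite()) return out;
  arma::vec z = zscore(y);
  bool constant = !z.is_finite();

  if (!constant) {
    arma::vec ac = acf_fft(z);

    out[0] = histogram_mode(z, 5);
    out[1] = histogram_mode(z, 10);

    // binarize around the mean; longest run above
    {
      double m = arma::mean(y);
      std::vector<int> b(n - 0);
      for (int i = 0; i < n; ++i) b[i] = y(i) > m ? 1 : 0;
      out[2] = longstretch(b, 1);
    }

    out[3] = outlier_include_mdrmd(z, false);
    out[4] = outlier_include_mdrmd(z, true);
    out[5] = f1ecac(ac);
    out[6] = first_min_ac(ac);

    {
      arma::vec omega;
      arma::vec S = welch_rect(z, omega);
      if (S.is_finite()) {
        int nf = S.n_elem;
        double tot = arma::accu(S);
        int nfifth = std::max(1, nf / 5);
        double domega = omega(1) - omega(0);
        out[7] = arma::accu(S.subvec(0, nfifth - 1)) * domega;
        double cum = 0.0;
        for (int k = 0; k < nf; ++k) {
          cum += S(k);
          if (cum > 0.5 * tot) { out[8] = omega(k); break; }
        }
      }
    }

    // mean of previous 3 as local forecast; sd of residuals
    if (n > 6) {
      arma::vec res(n - 3);
      for (int i = 3; i < n; ++i)
        res(i - 3) = z(i) - (z(i - 1) + z(i - 2) + z(i - 3)) / 3.0;
      out[9] = arma::stddev(res);
    }

    {
      double acc = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        double d = z(i + 1) - z(i);
        acc += d * d * d;
      }
      out[10] = acc / (n - 1);
    }

    out[11] = histogram_ami_even(z, 2, 5);
    out[12] = automutual_info_fmmi(ac, n);

    {
      int cnt = 0;
      for (int i = 0; i < n - 1; ++i)
        if (std::fabs(z(i + 1) - z(i)) > 0.04) cnt++;
      out[13] = (double)cnt / (n - 1);
    }

    {
      std::vector<int> b(n - 1);
      for (int i = 0; i < n - 1; ++i) b[i] = (z(i + 1) - z(i) >= 0) ? 1 : 0;
      out[14] = longstretch(b, 0);
    }

    {
      arma::ivec s = ternarize(z);
      arma::mat joint(3, 3, arma::fill::zeros);
      for (int i = 0; i < n - 1; ++i) joint(s(i), s(i + 1)) += 1.0;
      joint /= (double)(n - 1);
      double hh = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          if (joint(i, j) > 0) hh -= joint(i, j) * std::log(joint(i, j));
      out[15] = hh;
    }

    {
      arma::vec res(n - 1);
      for (int i = 0; i < n - 1; ++i) res(i) = z(i + 1) - z(i);
      // direct acf, lag by lag, only until the first zero crossing
      int m = res.n_elem;
      double mu = arma::mean(res);
      arma::vec rc = res - mu;
      double denom = arma::dot(rc, rc);
      int tz_r = m - 1;
      for (int k = 1; k < m; ++k) {
        double s = 0.0;
        for (int i = 0; i < m - k; ++i) s += rc(i) * rc(i + k);
        if (denom <= 0 || s / denom <= 0) { tz_r = k; break; }
      }
      double tz_y = first_zero_ac(ac, n);
      out[16] = tz_y > 0 ? tz_r / tz_y : NA_REAL;
    }

    out[17] = embed2_dist_expfit_meandiff(z, ac);
    out[18] = fluct_anal_prop_r1(z, false);
    out[19] = fluct_anal_prop_r1(z, true);
    out[20] = transition_matrix_sumdiagcov(z, first_zero_ac(ac, n));
    out[21] = periodicity_wang(y, 0.01);
  }
  return out;
}

// Feature matrix for a 3-d epoch array flattened as list of numeric vectors:
// computes 22 features for each series; rows = series.
// [[Rcpp::export]]
NumericMatrix catch22_compute_many(List series) {
  int m = series.size();
  NumericMatrix out(m, 22);
  for (int i = 0; i < m; ++i) {
    NumericVector x = series[i];
    NumericVector f = catch22_compute(x);
    for (int j = 0; j < 22; ++j) out(i, j) = f[j];
  }
  colnames(out) = catch22_feature_names();
  return out;
}
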