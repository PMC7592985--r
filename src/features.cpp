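// Sliding-window texture feature extractors (2-D, per axial slice).
// Border policy everywhere: edge replication.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// type-7 quantile on a sorted vector
static double quantile7(const std::vector<double> &x, double p) {
  const int n = (int)x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter_2d(NumericMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      buf.clear();
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          buf.push_back(img(clampi(r + dr, nr), clampi(c + dc, nc)));
      std::sort(buf.begin(), buf.end());
      const size_t m = buf.size();
      out(r, c) = (m % 2 == 1) ? buf[m / 2]
                               : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
    }
  }
  return out;
}

// 15 first-order statistics over a window x window in-slice neighbourhood.
// Order: mean, p25, p75, variance, sd, median, iqr, mode, min, max, range,
// skewness, kurtosis, entropy, energy.
// Conventions: variance/sd use the sample (n-1) denominator; skewness =
// m3/m2^1.5 and kurtosis = m4/m2^2 from population moments, defined 0 when
// m2 = 0; mode, entropy (bits) and energy use a `nbins` equal-width
// histogram over the window's range (mode = lowest-centre bin on ties;
// constant window: entropy 0, energy 1, mode = the constant).
// [[Rcpp::export]]
List cpp_first_order_2d(NumericMatrix img, LogicalMatrix mask, int window,
                        int nbins) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  const int nstat = 15;
  List out(nstat);
  std::vector<NumericMatrix> maps;
  for (int k = 0; k < nstat; ++k) {
    NumericMatrix m(nr, nc);
    std::fill(m.begin(), m.end(), NA_REAL);
    maps.push_back(m);
  }
  std::vector<double> buf((size_t)window * window);
  std::vector<int> hist(nbins);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int n = 0;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          buf[n++] = img(clampi(r + dr, nr), clampi(c + dc, nc));
      std::vector<double> v(buf.begin(), buf.begin() + n);
      std::sort(v.begin(), v.end());
      const double mn = v.front(), mx = v.back();
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i];
      const double mean = s / n;
      double m2 = 0, m3 = 0, m4 = 0;
      for (int i = 0; i < n; ++i) {
        const double d = v[i] - mean;
        m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
      }
      m2 /= n; m3 /= n; m4 /= n;
      const double var = (n > 1) ? (m2 * n) / (n - 1) : 0.0;
      const double skew = (m2 > 0) ? m3 / std::pow(m2, 1.5) : 0.0;
      const double kurt = (m2 > 0) ? m4 / (m2 * m2) : 0.0;
      const double q25 = quantile7(v, 0.25), q75 = quantile7(v, 0.75);
      const double med = quantile7(v, 0.5);
      // histogram-based mode / entropy / energy
      double mode, entropy = 0.0, energy;
      if (mx > mn) {
        std::fill(hist.begin(), hist.end(), 0);
        const double w = (mx - mn) / nbins;
        for (int i = 0; i < n; ++i) {
          int b = (int)((v[i] - mn) / w);
          if (b >= nbins) b = nbins - 1;
          hist[b]++;
        }
        int best = 0;
        energy = 0.0;
        for (int b = 0; b < nbins; ++b) {
          if (hist[b] > hist[best]) best = b;
          if (hist[b] > 0) {
            const double p = (double)hist[b] / n;
            energy += p * p;
            entropy -= p * std::log2(p);
          }
        }
        mode = mn + (best + 0.5) * w;
      } else {
        mode = mn; entropy = 0.0; energy = 1.0;
      }
      maps[0](r, c) = mean;
      maps[1](r, c) = q25;
      maps[2](r, c) = q75;
      maps[3](r, c) = var;
      maps[4](r, c) = std::sqrt(var);
      maps[5](r, c) = med;
      maps[6](r, c) = q75 - q25;
      maps[7](r, c) = mode;
      maps[8](r, c) = mn;
      maps[9](r, c) = mx;
      maps[10](r, c) = mx - mn;
      maps[11](r, c) = skew;
      maps[12](r, c) = kurt;
      maps[13](r, c) = entropy;
      maps[14](r, c) = energy;
    }
  }
  for (int k = 0; k < nstat; ++k) out[k] = maps[k];
  out.attr("names") = CharacterVector::create(
      "mean", "p25", "p75", "variance", "sd", "median", "iqr", "mode", "min",
      "max", "range", "skewness", "kurtosis", "entropy", "energy");
  return out;
}

// Compute the 19 GLCM statistics from a symmetric count matrix.
// `stats` must have length 19. Order:
// contrast, inertia, energy, entropy, correlation, mcc, homogeneity,
// inverse, dissimilarity, cluster_shade, sum_average, sum_variance,
// sum_entropy, sum_of_squares, difference_variance, difference_entropy,
// maximum_probability, glcm_variance, glcm_sd.
static void glcm_stats(const arma::mat &counts, double *stats) {
  const int L = (int)counts.n_rows;
  const double N = arma::accu(counts);
  for (int k = 0; k < 19; ++k) stats[k] = 0.0;
  if (N <= 0) return;
  arma::mat P = counts / N;
  arma::vec px = arma::sum(P, 1);  // == py by symmetry
  double mu_x = 0.0;
  for (int i = 0; i < L; ++i) mu_x += i * px(i);
  double var_x = 0.0;
  for (int i = 0; i < L; ++i) var_x += (i - mu_x) * (i - mu_x) * px(i);
  const double sd_x = std::sqrt(var_x);

  double contrast = 0, energy = 0, entropy = 0, corr_num = 0, homog = 0,
         invdiff = 0, dissim = 0, shade = 0, maxp = 0, f4 = 0;
  std::vector<double> psum(2 * L - 1, 0.0), pdiff(L, 0.0);
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      const double p = P(i, j);
      if (p <= 0) continue;
      const int d = i - j;
      contrast += (double)d * d * p;
      energy += p * p;
      entropy -= p * std::log2(p);
      corr_num += (i - mu_x) * (j - mu_x) * p;
      homog += p / (1.0 + std::abs((double)d));
      invdiff += p / (1.0 + (double)d * d);
      dissim += std::abs((double)d) * p;
      const double sh = (i + j - 2 * mu_x);
      shade += sh * sh * sh * p;
      if (p > maxp) maxp = p;
      f4 += (i - mu_x) * (i - mu_x) * p;
      psum[i + j] += p;
      pdiff[std::abs(d)] += p;
    }
  }
  double sum_avg = 0.0;
  for (size_t k = 0; k < psum.size(); ++k) sum_avg += k * psum[k];
  double sum_var = 0.0, sum_ent = 0.0;
  for (size_t k = 0; k < psum.size(); ++k) {
    if (psum[k] > 0) {
      sum_var += (k - sum_avg) * (k - sum_avg) * psum[k];
      sum_ent -= psum[k] * std::log2(psum[k]);
    }
  }
  double mu_d = 0.0;
  for (int k = 0; k < L; ++k) mu_d += k * pdiff[k];
  double diff_var = 0.0, diff_ent = 0.0;
  for (int k = 0; k < L; ++k) {
    if (pdiff[k] > 0) {
      diff_var += (k - mu_d) * (k - mu_d) * pdiff[k];
      diff_ent -= pdiff[k] * std::log2(pdiff[k]);
    }
  }
  const double correlation = (sd_x > 0) ? corr_num / (sd_x * sd_x) : 0.0;

  // maximal correlation coefficient: sqrt of 2nd-largest eigenvalue of Q
  double mcc = 0.0;
  if (sd_x > 0) {
    std::vector<int> keep;
    for (int i = 0; i < L; ++i) if (px(i) > 0) keep.push_back(i);
    const int m = (int)keep.size();
    if (m >= 2) {
      arma::mat Q(m, m, arma::fill::zeros);
      for (int a = 0; a < m; ++a)
        for (int b = 0; b < m; ++b) {
          double q = 0.0;
          for (int k = 0; k < m; ++k)
            q += P(keep[a], keep[k]) * P(keep[b], keep[k]) /
                 (px(keep[a]) * px(keep[k]));
          Q(a, b) = q;
        }
      arma::cx_vec ev;
      if (arma::eig_gen(ev, Q)) {
        arma::vec re = arma::sort(arma::real(ev), "descend");
        double second = re(1);
        if (second < 0) second = 0;
        if (second > 1) second = 1;
        mcc = std::sqrt(second);
      }
    }
  }
  stats[0] = contrast;
  stats[1] = contrast * N;       // inertia from raw counts
  stats[2] = energy;
  stats[3] = entropy;
  stats[4] = correlation;
  stats[5] = mcc;
  stats[6] = homog;
  stats[7] = invdiff;
  stats[8] = dissim;
  stats[9] = shade;
  stats[10] = sum_avg;
  stats[11] = sum_var;
  stats[12] = sum_ent;
  stats[13] = f4 * N;            // sum of squares from raw counts
  stats[14] = diff_var;
  stats[15] = diff_ent;
  stats[16] = maxp;
  stats[17] = f4;
  stats[18] = std::sqrt(f4);
}

// [[Rcpp::export]]
CharacterVector cpp_glcm_stat_names() {
  return CharacterVector::create(
      "contrast", "inertia", "energy", "entropy", "correlation", "mcc",
      "homogeneity", "inverse", "dissimilarity", "cluster_shade",
      "sum_average", "sum_variance", "sum_entropy", "sum_of_squares",
      "difference_variance", "difference_entropy", "maximum_probability",
      "glcm_variance", "glcm_sd");
}

// Per-voxel GLCM statistics over a window x window neighbourhood.
// The window is quantized to `levels` gray levels by equal-width binning
// over the window's own range (constant window -> single level). Pairs are
// accumulated symmetrically over the four unit offsets (0, 45, 90, 135
// degrees) at distance 1, pairs restricted to the window.
// [[Rcpp::export]]
List cpp_glcm_2d(NumericMatrix img, LogicalMatrix mask, int window,
                 int levels) {
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  const int nstat = 19;
  std::vector<NumericMatrix> maps;
  for (int k = 0; k < nstat; ++k) {
    NumericMatrix m(nr, nc);
    std::fill(m.begin(), m.end(), NA_REAL);
    maps.push_back(m);
  }
  arma::imat win(window, window);
  arma::mat counts(levels, levels);
  const int offs[4][2] = {{0, 1}, {-1, 1}, {-1, 0}, {-1, -1}};
  double stats[19];
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      double mn = R_PosInf, mx = R_NegInf;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc) {
          const double v = img(clampi(r + dr, nr), clampi(c + dc, nc));
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
      const double rng = mx - mn;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc) {
          const double v = img(clampi(r + dr, nr), clampi(c + dc, nc));
          int lev = 0;
          if (rng > 0) {
            lev = (int)((v - mn) / rng * levels);
            if (lev >= levels) lev = levels - 1;
          }
          win(dr + h, dc + h) = lev;
        }
      counts.zeros();
      for (int o = 0; o < 4; ++o) {
        const int dr = offs[o][0], dc = offs[o][1];
        for (int a = 0; a < window; ++a) {
          const int a2 = a + dr;
          if (a2 < 0 || a2 >= window) continue;
          for (int b = 0; b < window; ++b) {
            const int b2 = b + dc;
            if (b2 < 0 || b2 >= window) continue;
            counts(win(a, b), win(a2, b2)) += 1.0;
            counts(win(a2, b2), win(a, b)) += 1.0;
          }
        }
      }
      glcm_stats(counts, stats);
      for (int k = 0; k < nstat; ++k) maps[k](r, c) = stats[k];
    }
  }
  List out(nstat);
  for (int k = 0; k < nstat; ++k) out[k] = maps[k];
  out.attr("names") = cpp_glcm_stat_names();
  return out;
}
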