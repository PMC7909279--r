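#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Per-term floor on the site log-pmf so a read-error rate of 0 on
// inconsistent counts yields a large negative value rather than -Inf.
static const double LOG_FLOOR = -745.0;

// log Binomial(a | n, pi) with pi = q(1-e) + (1-q)e folded in by the caller;
// lch = lchoose(n, a) precomputed per site. Zero-depth sites contribute 0.
static inline double site_logpmf(int a, int n, double lch, double q,
                                 double e) {
  if (n == 0) return 0.0;
  double pi = q * (1.0 - e) + (1.0 - q) * e;
  if (pi < 1e-300) pi = 1e-300;
  if (pi > 1.0 - 1e-16) pi = 1.0 - 1e-16;
  double v = lch + a * std::log(pi) + (n - a) * std::log1p(-pi);
  return (v < LOG_FLOOR) ? LOG_FLOOR : v;
}

static void softmax(const std::vector<double> &t, std::vector<double> &w) {
  double mx = *std::max_element(t.begin(), t.end());
  double s = 0.0;
  for (size_t k = 0; k < t.size(); ++k) {
    w[k] = std::exp(t[k] - mx);
    s += w[k];
  }
  for (size_t k = 0; k < t.size(); ++k) w[k] /= s;
}

static NumericVector make_lchoose(const IntegerVector &alt,
                                  const IntegerVector &n) {
  int M = alt.size();
  NumericVector lch(M);
  for (int j = 0; j < M; ++j)
    lch[j] = (n[j] > 0) ? R::lchoose((double)n[j], (double)alt[j]) : 0.0;
  return lch;
}

static double mix_loglik(const IntegerVector &alt, const IntegerVector &n,
                         const NumericVector &lch,
                         const std::vector<double> &w, const IntegerMatrix &h,
                         double e) {
  int M = alt.size(), K = h.nrow();
  double ll = 0.0;
  for (int j = 0; j < M; ++j) {
    double q = 0.0;
    for (int k = 0; k < K; ++k) q += w[k] * h(k, j);
    ll += site_logpmf(alt[j], n[j], lch[j], q, e);
  }
  return ll;
}

// Joint Metropolis-Hastings random-walk update of all K titres.
// Returns true on acceptance; cur_ll is kept in sync.
static bool titre_mh(std::vector<double> &t, std::vector<double> &w,
                     double &cur_ll, const IntegerMatrix &h,
                     const IntegerVector &alt, const IntegerVector &n,
                     const NumericVector &lch, double e, double sigma_t,
                     double delta) {
  int K = (int)t.size();
  std::vector<double> tp(K), wp(K);
  for (int k = 0; k < K; ++k) tp[k] = t[k] + norm_rand() * delta;
  softmax(tp, wp);
  double llp = mix_loglik(alt, n, lch, wp, h, e);
  double dprior = 0.0;
  for (int k = 0; k < K; ++k)
    dprior += (t[k] * t[k] - tp[k] * tp[k]) / (2.0 * sigma_t * sigma_t);
  double lacc = (llp - cur_ll) + dprior;
  if (std::log(unif_rand()) < lacc) {
    t = tp;
    w = wp;
    cur_ll = llp;
    return true;
  }
  return false;
}

// Exact block-Gibbs draw of (donor z_k, haplotype h_k) for one strain,
// conditioning on the other strains, the proportions and the counts.
// Copying emission is (1-mu) on match with the donor allele, mu otherwise;
// recombination is zero so one donor serves the whole strain.
static int hap_gibbs(int k, const std::vector<double> &w, IntegerMatrix &h,
                     const IntegerVector &alt, const IntegerVector &n,
                     const NumericVector &lch, const IntegerMatrix &panel,
                     double mu, double e) {
  int M = alt.size(), K = h.nrow(), Np = panel.nrow();
  std::vector<double> ll0(M), ll1(M), s0(M), s1(M);
  double lmu = std::log(mu), l1mu = std::log1p(-mu);
  for (int j = 0; j < M; ++j) {
    double qo = 0.0;
    for (int i = 0; i < K; ++i)
      if (i != k) qo += w[i] * h(i, j);
    ll0[j] = site_logpmf(alt[j], n[j], lch[j], qo, e);
    ll1[j] = site_logpmf(alt[j], n[j], lch[j], qo + w[k], e);
    // log-sum-exp of the two emission-weighted site likelihoods,
    // once for a donor carrying 0 and once for a donor carrying 1
    double a0 = l1mu + ll0[j], b0 = lmu + ll1[j];
    s0[j] = (a0 > b0) ? a0 + std::log1p(std::exp(b0 - a0))
                      : b0 + std::log1p(std::exp(a0 - b0));
    double a1 = lmu + ll0[j], b1 = l1mu + ll1[j];
    s1[j] = (a1 > b1) ? a1 + std::log1p(std::exp(b1 - a1))
                      : b1 + std::log1p(std::exp(a1 - b1));
  }
  std::vector<double> lw(Np);
  double mx = -1e308;
  for (int p = 0; p < Np; ++p) {
    double s = 0.0;
    for (int j = 0; j < M; ++j) s += panel(p, j) ? s1[j] : s0[j];
    lw[p] = s;
    if (s > mx) mx = s;
  }
  double tot = 0.0;
  for (int p = 0; p < Np; ++p) {
    lw[p] = std::exp(lw[p] - mx);
    tot += lw[p];
  }
  double u = unif_rand() * tot, c = 0.0;
  int z = Np - 1;
  for (int p = 0; p < Np; ++p) {
    c += lw[p];
    if (u <= c) {
      z = p;
      break;
    }
  }
  for (int j = 0; j < M; ++j) {
    double le0 = (panel(z, j) == 0 ? l1mu : lmu) + ll0[j];
    double le1 = (panel(z, j) == 1 ? l1mu : lmu) + ll1[j];
    double p1 = 1.0 / (1.0 + std::exp(le0 - le1));
    h(k, j) = (unif_rand() < p1) ? 1 : 0;
  }
  return z;
}

// Site-wise allele-exchange Metropolis move between two strains.
// Single-strain Gibbs updates cannot repair a point-switched site pair
// (each strain's conditional is pinned by the other), so this joint move
// supplies the missing pathway; it targets the same posterior, with the
// copying-emission ratio taken at the strains' current donors.
static void site_swap_mh(int k1, int k2, const std::vector<double> &w,
                         IntegerMatrix &h, const IntegerVector &alt,
                         const IntegerVector &n, const NumericVector &lch,
                         const IntegerMatrix &panel, int z1, int z2,
                         double mu, double e) {
  int M = alt.size(), K = h.nrow();
  double lmu = std::log(mu), l1mu = std::log1p(-mu);
  for (int j = 0; j < M; ++j) {
    if (h(k1, j) == h(k2, j)) continue;
    double q = 0.0;
    for (int k = 0; k < K; ++k) q += w[k] * h(k, j);
    double qs = q + (w[k1] - w[k2]) * (h(k2, j) - h(k1, j));
    double cur = site_logpmf(alt[j], n[j], lch[j], q, e) +
                 (h(k1, j) == panel(z1, j) ? l1mu : lmu) +
                 (h(k2, j) == panel(z2, j) ? l1mu : lmu);
    double prop = site_logpmf(alt[j], n[j], lch[j], qs, e) +
                  (h(k2, j) == panel(z1, j) ? l1mu : lmu) +
                  (h(k1, j) == panel(z2, j) ? l1mu : lmu);
    if (std::log(unif_rand()) < prop - cur) std::swap(h(k1, j), h(k2, j));
  }
}

// [[Rcpp::export]]
double loglik_cpp(NumericVector w, IntegerMatrix h, IntegerVector alt,
                  IntegerVector n, double e) {
  NumericVector lch = make_lchoose(alt, n);
  std::vector<double> wv(w.begin(), w.end());
  return mix_loglik(alt, n, lch, wv, h, e);
}

// [[Rcpp::export]]
List titre_step_cpp(NumericVector t, IntegerMatrix h, IntegerVector alt,
                    IntegerVector n, double e, double sigma_t, double delta) {
  NumericVector lch = make_lchoose(alt, n);
  int K = t.size();
  std::vector<double> tv(t.begin(), t.end()), wv(K);
  softmax(tv, wv);
  double ll = mix_loglik(alt, n, lch, wv, h, e);
  bool acc = titre_mh(tv, wv, ll, h, alt, n, lch, e, sigma_t, delta);
  return List::create(_["t"] = NumericVector(tv.begin(), tv.end()),
                      _["w"] = NumericVector(wv.begin(), wv.end()),
                      _["log_lik"] = ll, _["accepted"] = acc);
}

// [[Rcpp::export]]
List hap_step_cpp(int k, NumericVector w, IntegerMatrix h, IntegerVector alt,
                  IntegerVector n, IntegerMatrix panel, double mu, double e) {
  NumericVector lch = make_lchoose(alt, n);
  std::vector<double> wv(w.begin(), w.end());
  IntegerMatrix hc = clone(h);
  int z = hap_gibbs(k - 1, wv, hc, alt, n, lch, panel, mu, e);
  return List::create(_["z"] = z + 1, _["h"] = hc);
}

// Full sampler: each sweep is one joint titre MH update followed by a
// block-Gibbs haplotype update of every strain in random order.
// Post-burn-in accumulation sorts strains by current proportion (label
// alignment); near-equal K=2 proportions are oriented against the running
// modal haplotypes by minimal Hamming distance.  Haplotype draws are
// recorded in raw chain order when keep_draws is set (small M only).
// [[Rcpp::export]]
List mcmc_deconvolve_cpp(IntegerVector alt, IntegerVector n,
                         IntegerMatrix panel, int K, int n_steps,
                         double burn_frac, double e, double mu, double sigma_t,
                         double delta, double align_tol, bool keep_draws) {
  int M = alt.size(), Np = panel.nrow();
  if (panel.ncol() != M) stop("panel and counts are on different site sets");
  if (keep_draws && M > 40) stop("keep_draws requires M <= 40");
  NumericVector lch = make_lchoose(alt, n);

  std::vector<double> t(K, 0.0), w(K);
  softmax(t, w);
  IntegerMatrix h(K, M);
  for (int k = 0; k < K; ++k) {
    int z0 = (int)std::floor(unif_rand() * Np);
    if (z0 >= Np) z0 = Np - 1;
    for (int j = 0; j < M; ++j) h(k, j) = panel(z0, j);
  }
  double cur_ll = mix_loglik(alt, n, lch, w, h, e);

  int n_burn = (int)std::floor(n_steps * burn_frac);
  int n_keep = n_steps - n_burn;
  NumericVector trace(n_steps);
  NumericMatrix prop_samples(n_keep > 0 ? n_keep : 0, K);
  NumericMatrix allele_sum(K, M);
  NumericMatrix hap_codes(keep_draws && n_keep > 0 ? n_keep : 0,
                          keep_draws ? K : 0);
  IntegerVector z_last(K, NA_INTEGER);
  int n_acc = 0, kept = 0;
  std::vector<int> order(K);

  for (int step = 0; step < n_steps; ++step) {
    if (titre_mh(t, w, cur_ll, h, alt, n, lch, e, sigma_t, delta)) ++n_acc;
    // The titre mean only enters the prior (softmax is shift-invariant),
    // so it is Gibbs-drawn exactly: t_bar ~ N(0, sigma_t^2 / K).  Without
    // this the mean random-walks to equilibrium over ~(sigma_t/delta)^2
    // sweeps and leaves a slow transient in the log-posterior trace.
    {
      double mbar = 0.0;
      for (int k = 0; k < K; ++k) mbar += t[k];
      mbar /= K;
      double mnew = norm_rand() * sigma_t / std::sqrt((double)K);
      for (int k = 0; k < K; ++k) t[k] += mnew - mbar;
    }
    for (int k = 0; k < K; ++k) order[k] = k;
    for (int k = K - 1; k > 0; --k) {  // Fisher-Yates
      int jj = (int)std::floor(unif_rand() * (k + 1));
      if (jj > k) jj = k;
      std::swap(order[k], order[jj]);
    }
    for (int k = 0; k < K; ++k)
      z_last[order[k]] =
          hap_gibbs(order[k], w, h, alt, n, lch, panel, mu, e) + 1;
    if (K >= 2) {
      int k1 = 0, k2 = 1;
      if (K > 2) {  // random strain pair
        k1 = (int)std::floor(unif_rand() * K);
        k2 = (int)std::floor(unif_rand() * (K - 1));
        if (k2 >= k1) ++k2;
      }
      site_swap_mh(k1, k2, w, h, alt, n, lch, panel, z_last[k1] - 1,
                   z_last[k2] - 1, mu, e);
    }
    cur_ll = mix_loglik(alt, n, lch, w, h, e);
    double lprior = 0.0;
    for (int k = 0; k < K; ++k)
      lprior += -0.5 * t[k] * t[k] / (sigma_t * sigma_t) -
                std::log(sigma_t) - 0.9189385332046727;
    trace[step] = cur_ll + lprior;

    if (step >= n_burn) {
      std::vector<int> ord(K);
      for (int k = 0; k < K; ++k) ord[k] = k;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return w[a] > w[b]; });
      if (K == 2 && std::fabs(w[ord[0]] - w[ord[1]]) < align_tol &&
          kept > 0) {
        int d_id = 0, d_sw = 0;
        for (int j = 0; j < M; ++j) {
          int m0 = allele_sum(0, j) * 2 > kept ? 1 : 0;
          int m1 = allele_sum(1, j) * 2 > kept ? 1 : 0;
          d_id += (h(ord[0], j) != m0) + (h(ord[1], j) != m1);
          d_sw += (h(ord[1], j) != m0) + (h(ord[0], j) != m1);
        }
        if (d_sw < d_id) std::swap(ord[0], ord[1]);
      }
      for (int k = 0; k < K; ++k) {
        prop_samples(kept, k) = w[ord[k]];
        for (int j = 0; j < M; ++j) allele_sum(k, j) += h(ord[k], j);
      }
      if (keep_draws) {
        for (int k = 0; k < K; ++k) {
          double code = 0.0, b = 1.0;
          for (int j = 0; j < M; ++j) {
            code += h(k, j) * b;
            b *= 2.0;
          }
          hap_codes(kept, k) = code;
        }
      }
      ++kept;
    }
  }

  return List::create(
      _["trace"] = trace, _["prop_samples"] = prop_samples,
      _["allele_sum"] = allele_sum, _["n_keep"] = kept,
      _["accept_rate"] = (double)n_acc / n_steps,
      _["hap_codes"] = keep_draws ? (SEXP)hap_codes : R_NilValue,
      _["z_last"] = z_last);
}
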