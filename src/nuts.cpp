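// No-U-Turn sampler for the non-centred hierarchical (zero-inflated)
// Poisson scale-mark model.
//
// Unconstrained parameter vector layout:
//   [0]                alpha                  (species-level intercept)
//   [1]                z_sigma_alpha          (half-Cauchy via Normal-CDF map)
//   [2 .. 2+P)         beta                   (species-level slopes)
//   [2+P .. 2+P+K)     z_sigma_beta           (random-slope scales)
//   [.. +I)            delta_alpha            (standardized intercept offsets)
//   [.. +I*K)          delta_beta             (standardized slope offsets,
//                                              factor-major blocks of I)
//   [last, zip only]   logit pi               (zero-inflation weight)
//
// The likelihood row predictor is
//   eta_j = alpha + delta_alpha[i_j]*sigma_alpha
//         + sum_f X[j,f]*beta_f
//         + sum_{k in rsf} X[j,rsf_k]*delta_beta[i_j,k]*sigma_beta_k
// with marks ~ Poisson(exp(eta)) or ZIP(pi, exp(eta)).
//
// Sampler: recursive slice-variant NUTS with Stan-style warmup (dual
// averaging of the step size toward a target acceptance statistic, and
// windowed estimation of a diagonal inverse mass matrix). All randomness
// comes from R's RNG so that set.seed() in R makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Half-Cauchy(scale) scale parameters are sampled through a standard-normal
// coordinate z: sigma = scale / tan((pi/2) * Q(z)) with Q the upper-tail
// normal probability. The implied prior on sigma is exactly
// HalfCauchy(scale) while the unconstrained coordinate keeps light Gaussian
// tails (no slow log-scale random walk near sigma = 0).
inline double sigma_from_z(double z, double scale) {
  double Q = 0.5 * std::erfc(z * M_SQRT1_2);
  return scale / std::tan(M_PI_2 * Q);
}
inline double dsigma_dz(double z, double scale) {
  double Q = 0.5 * std::erfc(z * M_SQRT1_2);
  double s = std::sin(M_PI_2 * Q);
  double phi = std::exp(-0.5 * z * z) / std::sqrt(2.0 * M_PI);
  return scale * M_PI_2 * phi / (s * s);
}

struct Model {
  arma::mat X;          // n x P design
  arma::vec y;          // counts
  arma::uvec ind;       // 0-based individual index per row
  int n_ind;
  arma::uvec rsf;       // 0-based columns of X carrying individual slopes
  bool zip;
  double sd_int, sd_slope, shrink_scale, pi_a, pi_b;
  double lgamma_sum;    // sum lgamma(y+1), likelihood constant

  int P() const { return X.n_cols; }
  int K() const { return rsf.n_elem; }
  int dim() const { return 2 + P() + K() + n_ind + n_ind * K() + (zip ? 1 : 0); }

  // Workspace reused across gradient evaluations (single-threaded sampler).
  mutable arma::vec ws_eta, ws_r, ws_S, ws_T;

  // log posterior density (up to a constant) and its gradient
  double logp_grad(const arma::vec& th_, arma::vec& g_) const {
    const int P_ = P(), K_ = K(), I = n_ind, n = X.n_rows;
    const double* th = th_.memptr();
    if ((int)g_.n_elem != (int)th_.n_elem) g_.set_size(th_.n_elem);
    double* g = g_.memptr();
    const double alpha = th[0];
    const double z_a = th[1];
    const double sig_a = sigma_from_z(z_a, shrink_scale);
    const double* beta = th + 2;
    const double* z_b = th + 2 + P_;
    const double* dalpha = th + 2 + P_ + K_;
    const int off_da = 2 + P_ + K_;
    const int off_db = off_da + I;
    const int* ip = ind_raw.data();
    double pi = 0.0, t_pi = 0.0;
    if (zip) { t_pi = th[th_.n_elem - 1]; pi = 1.0 / (1.0 + std::exp(-t_pi)); }
    double sig_b[64];
    for (int k = 0; k < K_; ++k) sig_b[k] = sigma_from_z(z_b[k], shrink_scale);
    if (!std::isfinite(sig_a)) return -std::numeric_limits<double>::infinity();
    for (int k = 0; k < K_; ++k)
      if (!std::isfinite(sig_b[k])) return -std::numeric_limits<double>::infinity();

    // linear predictor (column-major passes over the design)
    ws_eta.set_size(n);
    double* eta = ws_eta.memptr();
    for (int j = 0; j < n; ++j) eta[j] = alpha + sig_a * dalpha[ip[j]];
    for (int f = 0; f < P_; ++f) {
      const double b = beta[f];
      if (b == 0.0) continue;
      const double* xc = X.colptr(f);
      for (int j = 0; j < n; ++j) eta[j] += xc[j] * b;
    }
    for (int k = 0; k < K_; ++k) {
      const double* xc = X.colptr(rsf(k));
      const double sk = sig_b[k];
      const double* db = th + off_db + (std::size_t)k * I;
      for (int j = 0; j < n; ++j) eta[j] += xc[j] * sk * db[ip[j]];
    }

    // likelihood + residual r = d loglik / d eta
    double lp = 0.0;
    ws_r.set_size(n);
    double* r = ws_r.memptr();
    const double* yp = y.memptr();
    double g_tpi = 0.0;
    const double log1mpi = zip ? std::log1p(-pi) : 0.0;
    for (int j = 0; j < n; ++j) {
      const double e = eta[j];
      if (!(e < 60.0)) return -std::numeric_limits<double>::infinity();
      const double lam = std::exp(e);
      if (!zip) {
        lp += yp[j] * e - lam;
        r[j] = yp[j] - lam;
      } else if (yp[j] > 0.0) {
        lp += log1mpi + yp[j] * e - lam;
        r[j] = yp[j] - lam;
        g_tpi += -pi;  // d log(1-pi)/dt = -pi
      } else {
        const double em = std::exp(-lam);
        const double denom = pi + (1.0 - pi) * em;
        lp += std::log(denom);
        r[j] = -(1.0 - pi) * em * lam / denom;
        // d/dpi log denom = (1 - em)/denom; times dpi/dt = pi(1-pi)
        g_tpi += (1.0 - em) / denom * pi * (1.0 - pi);
      }
    }
    lp -= lgamma_sum;
    if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();

    // gradients from the likelihood
    double sum_r = 0.0;
    for (int j = 0; j < n; ++j) sum_r += r[j];
    g[0] = sum_r;
    for (int f = 0; f < P_; ++f) {
      const double* xc = X.colptr(f);
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += xc[j] * r[j];
      g[2 + f] = acc;
    }
    ws_S.zeros(I);
    double* S = ws_S.memptr();                     // sum of r by individual
    for (int j = 0; j < n; ++j) S[ip[j]] += r[j];
    double g_dsiga = 0.0;  // d loglik / d sigma_alpha
    for (int i = 0; i < I; ++i) {
      g[off_da + i] = sig_a * S[i];
      g_dsiga += dalpha[i] * S[i];
    }
    g[1] = g_dsiga * dsigma_dz(z_a, shrink_scale);
    ws_T.set_size(I);
    double* T = ws_T.memptr();
    for (int k = 0; k < K_; ++k) {
      const double* xc = X.colptr(rsf(k));
      for (int i = 0; i < I; ++i) T[i] = 0.0;     // sum of x*r by individual
      for (int j = 0; j < n; ++j) T[ip[j]] += xc[j] * r[j];
      const double sk = sig_b[k];
      const double* db = th + off_db + (std::size_t)k * I;
      double* gdb = g + off_db + (std::size_t)k * I;
      double g_dsig = 0.0;
      for (int i = 0; i < I; ++i) {
        gdb[i] = sk * T[i];
        g_dsig += db[i] * T[i];
      }
      g[2 + P_ + k] = g_dsig * dsigma_dz(z_b[k], shrink_scale);
    }

    // priors
    lp += -0.5 * alpha * alpha / (sd_int * sd_int);
    g[0] += -alpha / (sd_int * sd_int);
    for (int f = 0; f < P_; ++f) {
      lp += -0.5 * beta[f] * beta[f] / (sd_slope * sd_slope);
      g[2 + f] += -beta[f] / (sd_slope * sd_slope);
    }
    // half-Cauchy(shrink_scale) on the sigmas, carried by the
    // standard-normal sampling coordinate z (prior + Jacobian fold into a
    // plain Normal(0, 1) density on z)
    lp += -0.5 * z_a * z_a;
    g[1] += -z_a;
    for (int k = 0; k < K_; ++k) {
      lp += -0.5 * z_b[k] * z_b[k];
      g[2 + P_ + k] += -z_b[k];
    }
    // standardized offsets ~ Normal(0, 1)
    for (int i = 0; i < I; ++i) {
      lp += -0.5 * dalpha[i] * dalpha[i];
      g[off_da + i] += -dalpha[i];
    }
    for (std::size_t m = off_db; m < off_db + (std::size_t)I * K_; ++m) {
      lp += -0.5 * th[m] * th[m];
      g[m] += -th[m];
    }
    if (zip) {
      // Beta(a, b) prior plus logit Jacobian: lp += a*log(pi) + b*log(1-pi)
      lp += pi_a * std::log(pi) + pi_b * std::log1p(-pi);
      g_tpi += pi_a * (1.0 - pi) - pi_b * pi;
      g[th_.n_elem - 1] = g_tpi;
    }
    if (!std::isfinite(lp)) return -std::numeric_limits<double>::infinity();
    return lp;
  }

  std::vector<int> ind_raw;
};

inline double rnormR() { return norm_rand(); }
inline double runifR() { return unif_rand(); }
inline double rexpR() { return exp_rand(); }

struct Hamiltonian {
  const Model* model;
  arma::vec inv_mass;   // diagonal of M^{-1} (posterior variances)

  double kinetic(const arma::vec& p) const {
    return 0.5 * arma::dot(p % p, inv_mass);
  }
  arma::vec sample_momentum(int dim) const {
    arma::vec p(dim);
    for (int i = 0; i < dim; ++i) p(i) = rnormR() / std::sqrt(inv_mass(i));
    return p;
  }
  // one leapfrog step; returns log posterior at the new position
  double leapfrog(arma::vec& th, arma::vec& p, arma::vec& grad,
                  double eps) const {
    p += 0.5 * eps * grad;
    th += eps * (inv_mass % p);
    double lp = model->logp_grad(th, grad);
    if (std::isfinite(lp)) p += 0.5 * eps * grad;
    return lp;
  }
};

struct TreeState {
  arma::vec th_minus, p_minus, g_minus;
  arma::vec th_plus, p_plus, g_plus;
  arma::vec th_prop;      // proposal drawn from the multinomial tree weights
  double log_w;           // log sum of exp(H0 - H) over the subtree
  bool ok;                // no U-turn, no divergence
  bool divergent;
  double sum_accept;      // accumulates min(1, exp(H0 - H)) for adaptation
  int n_leapfrog;
};

inline double log_sum_exp(double a, double b) {
  if (a == -std::numeric_limits<double>::infinity()) return b;
  if (b == -std::numeric_limits<double>::infinity()) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

const double DELTA_MAX = 1000.0;

bool no_uturn(const arma::vec& th_plus, const arma::vec& th_minus,
              const arma::vec& p_plus, const arma::vec& p_minus,
              const arma::vec& inv_mass) {
  arma::vec dth = th_plus - th_minus;
  return arma::dot(dth, inv_mass % p_minus) >= 0 &&
         arma::dot(dth, inv_mass % p_plus) >= 0;
}

// Recursive doubling (multinomial NUTS: subtree proposals are drawn with
// probability proportional to their Boltzmann weights exp(H0 - H)).
void build_tree(const Hamiltonian& ham, arma::vec th, arma::vec p,
                arma::vec grad, int dir, int depth,
                double eps, double H0, TreeState& out) {
  if (depth == 0) {
    double lp_new = ham.leapfrog(th, p, grad, dir * eps);
    out.n_leapfrog = 1;
    double H = std::isfinite(lp_new)
                 ? -lp_new + ham.kinetic(p)
                 : std::numeric_limits<double>::infinity();
    bool diverged = !std::isfinite(H) || H - H0 > DELTA_MAX;
    out.log_w = diverged ? -std::numeric_limits<double>::infinity() : H0 - H;
    out.divergent = diverged;
    out.ok = !diverged;
    out.th_minus = th; out.p_minus = p; out.g_minus = grad;
    out.th_plus = th; out.p_plus = p; out.g_plus = grad;
    out.th_prop = th;
    double de = H0 - H;
    out.sum_accept = std::isfinite(H) ? std::min(1.0, std::exp(de)) : 0.0;
    return;
  }
  TreeState first;
  build_tree(ham, th, p, grad, dir, depth - 1, eps, H0, first);
  out = first;
  if (!first.ok) return;
  TreeState second;
  if (dir == -1) {
    build_tree(ham, first.th_minus, first.p_minus, first.g_minus,
               dir, depth - 1, eps, H0, second);
    out.th_minus = second.th_minus; out.p_minus = second.p_minus;
    out.g_minus = second.g_minus;
  } else {
    build_tree(ham, first.th_plus, first.p_plus, first.g_plus,
               dir, depth - 1, eps, H0, second);
    out.th_plus = second.th_plus; out.p_plus = second.p_plus;
    out.g_plus = second.g_plus;
  }
  out.n_leapfrog += second.n_leapfrog;
  out.sum_accept += second.sum_accept;
  out.divergent = first.divergent || second.divergent;
  double log_w_tot = log_sum_exp(first.log_w, second.log_w);
  // uniform progressive sampling within a subtree
  if (second.ok && second.log_w > -std::numeric_limits<double>::infinity() &&
      runifR() < std::exp(second.log_w - log_w_tot)) {
    out.th_prop = second.th_prop;
  }
  out.log_w = log_w_tot;
  out.ok = second.ok &&
    no_uturn(out.th_plus, out.th_minus, out.p_plus, out.p_minus,
             ham.inv_mass);
}

double find_initial_stepsize(const Hamiltonian& ham, const arma::vec& th0) {
  const int dim = th0.n_elem;
  double eps = 1.0;
  arma::vec grad(dim);
  double lp0 = ham.model->logp_grad(th0, grad);
  arma::vec p = ham.sample_momentum(dim);
  double H0 = -lp0 + ham.kinetic(p);
  arma::vec th = th0, pp = p, g = grad;
  double lp = ham.leapfrog(th, pp, g, eps);
  double H = std::isfinite(lp) ? -lp + ham.kinetic(pp)
                               : std::numeric_limits<double>::infinity();
  double dH = H0 - H;
  double direction = (std::isfinite(dH) && dH > std::log(0.5)) ? 1.0 : -1.0;
  for (int iter = 0; iter < 60; ++iter) {
    th = th0; pp = p; g = grad;
    lp = ham.leapfrog(th, pp, g, eps);
    H = std::isfinite(lp) ? -lp + ham.kinetic(pp)
                          : std::numeric_limits<double>::infinity();
    dH = H0 - H;
    if (direction > 0 && !(std::isfinite(dH) && dH > std::log(0.5))) break;
    if (direction < 0 && !(!std::isfinite(dH) || dH < std::log(0.5))) break;
    eps *= (direction > 0) ? 2.0 : 0.5;
    if (eps > 1e7 || eps < 1e-10) break;
  }
  return eps;
}

struct Welford {
  arma::vec mean, m2;
  double n = 0;
  void init(int dim) { mean.zeros(dim); m2.zeros(dim); n = 0; }
  void add(const arma::vec& x) {
    n += 1;
    arma::vec d = x - mean;
    mean += d / n;
    m2 += d % (x - mean);
  }
  arma::vec variance() const { return m2 / std::max(1.0, n - 1.0); }
};

// Ancillarity-sufficiency interweaving move for the shared location
// parameters. NUTS samples the non-centred coordinates, where a shared
// mean and its standardized offsets form a long ridge (alpha up, all
// deltas down leaves the likelihood unchanged). Holding the centred
// individual effects alpha_i = alpha + delta_i * sigma fixed (the
// likelihood depends on the state only through them), the full
// conditional of the shared mean is conjugate Normal:
//   prec = 1/prior_sd^2 + I/sigma^2,
//   mean = (sum_i alpha_i / sigma^2) / prec,
// and the offsets are recovered deterministically. One such Gibbs update
// per shared location per iteration decorrelates the ridge directions at
// negligible cost; the same move applies to every random-slope mean, and
// to the coefficient of any between-individual covariate (x constant
// within a specimen, e.g. sex), which rides the same ridge through the
// intercept offsets of the individuals it is active for:
// holding t_i = alpha_i + x_i * beta fixed,
//   prec = 1/prior_sd^2 + sum_i x_i^2 / sigma_alpha^2,
//   mean = sum_i x_i (t_i - alpha) / sigma_alpha^2 / prec.
// 1-D slice sampler (stepping out + shrinkage) for the scale-parameter
// interweave below; logf must be unnormalized log density.
template <class F>
double slice_sample_1d(double x0, const F& logf, double w = 1.0,
                       int max_steps = 30) {
  const double f0 = logf(x0);
  if (!std::isfinite(f0)) return x0;
  const double y = f0 - rexpR();
  double L = x0 - w * runifR();
  double R = L + w;
  for (int s = 0; s < max_steps && logf(L) > y; ++s) L -= w;
  for (int s = 0; s < max_steps && logf(R) > y; ++s) R += w;
  for (int s = 0; s < 100; ++s) {
    const double x1 = L + runifR() * (R - L);
    if (logf(x1) > y) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// Scale-parameter interweave: holding the centred deviations
// c_i = delta_i * sigma fixed (hence alpha_i fixed and the likelihood
// unchanged), the conditional of the sampling coordinate z is
//   log f(z) = log phi(z) - I log sigma(z) - (sum c_i^2) / (2 sigma(z)^2),
// the sigma^{-I} term being the Jacobian of delta_i = c_i / sigma. A
// slice-sampling update in z then refreshes sigma across its ridge with
// the offsets.
void interweave_scale(const Model& model, double* z, double* delta, int I) {
  const double sig0 = sigma_from_z(*z, model.shrink_scale);
  if (!(std::isfinite(sig0) && sig0 > 0) || I == 0) return;
  double ss = 0.0;
  for (int i = 0; i < I; ++i) {
    const double c = delta[i] * sig0;
    ss += c * c;
  }
  const double scale = model.shrink_scale;
  auto logf = [&](double zz) {
    const double s = sigma_from_z(zz, scale);
    if (!(std::isfinite(s) && s > 0)) {
      return -std::numeric_limits<double>::infinity();
    }
    return -0.5 * zz * zz - I * std::log(s) - ss / (2.0 * s * s);
  };
  const double z1 = slice_sample_1d(*z, logf);
  const double sig1 = sigma_from_z(z1, scale);
  if (!(std::isfinite(sig1) && sig1 > 0)) return;
  const double ratio = sig0 / sig1;
  for (int i = 0; i < I; ++i) delta[i] *= ratio;
  *z = z1;
}

void interweave_locations(const Model& model, const arma::mat& between_x,
                          const arma::uvec& between_cols, arma::vec& th) {
  const int P = model.P(), K = model.K(), I = model.n_ind;
  const int off_da = 2 + P + K;
  const int off_db = off_da + I;
  {
    const double sig = sigma_from_z(th(1), model.shrink_scale);
    if (std::isfinite(sig) && sig > 0) {
      const double alpha = th(0);
      double sum_ai = 0.0;
      for (int i = 0; i < I; ++i) sum_ai += alpha + th(off_da + i) * sig;
      const double prec = 1.0 / (model.sd_int * model.sd_int) +
                          (double)I / (sig * sig);
      const double mean = (sum_ai / (sig * sig)) / prec;
      const double alpha_new = mean + rnormR() / std::sqrt(prec);
      if (std::isfinite(alpha_new)) {
        const double shift = (alpha - alpha_new) / sig;
        for (int i = 0; i < I; ++i) th(off_da + i) += shift;
        th(0) = alpha_new;
      }
    }
  }
  for (int k = 0; k < K; ++k) {
    const double sig = sigma_from_z(th(2 + P + k), model.shrink_scale);
    if (!(std::isfinite(sig) && sig > 0)) continue;
    const int jb = 2 + model.rsf(k);
    const double beta = th(jb);
    double* db = th.memptr() + off_db + (std::size_t)k * I;
    double sum_bi = 0.0;
    for (int i = 0; i < I; ++i) sum_bi += beta + db[i] * sig;
    const double prec = 1.0 / (model.sd_slope * model.sd_slope) +
                        (double)I / (sig * sig);
    const double mean = (sum_bi / (sig * sig)) / prec;
    const double beta_new = mean + rnormR() / std::sqrt(prec);
    if (!std::isfinite(beta_new)) continue;
    const double shift = (beta - beta_new) / sig;
    for (int i = 0; i < I; ++i) db[i] += shift;
    th(jb) = beta_new;
  }
  const double sig_a = sigma_from_z(th(1), model.shrink_scale);
  if (std::isfinite(sig_a) && sig_a > 0) {
    for (arma::uword b = 0; b < between_cols.n_elem; ++b) {
      const int jb = 2 + ((int)between_cols(b) - 1);
      const double beta = th(jb);
      const double s2 = sig_a * sig_a;
      double sxx = 0.0, sxt = 0.0;
      for (int i = 0; i < I; ++i) {
        const double x = between_x(i, b);
        sxx += x * x;
        sxt += x * (th(off_da + i) * sig_a + x * beta);  // x_i (t_i - alpha)
      }
      const double prec = 1.0 / (model.sd_slope * model.sd_slope) + sxx / s2;
      const double mean = (sxt / s2) / prec;
      const double beta_new = mean + rnormR() / std::sqrt(prec);
      if (!std::isfinite(beta_new)) continue;
      for (int i = 0; i < I; ++i) {
        th(off_da + i) += between_x(i, b) * (beta - beta_new) / sig_a;
      }
      th(jb) = beta_new;
    }
  }
  interweave_scale(model, th.memptr() + 1, th.memptr() + off_da, I);
  for (int k = 0; k < K; ++k) {
    interweave_scale(model, th.memptr() + 2 + P + k,
                     th.memptr() + off_db + (std::size_t)k * I, I);
  }
}

}  // namespace

// [[Rcpp::export]]
List nuts_chain(const arma::mat& X, const arma::vec& y,
                const arma::uvec& specimen_index, int n_ind,
                const arma::uvec& rsf_cols, bool zip,
                double prior_intercept_sd, double prior_slope_sd,
                double prior_shrinkage_scale, double pi_a, double pi_b,
                const arma::vec& init, int tune, int draws,
                double target_accept, int max_treedepth,
                const arma::mat& between_x, const arma::uvec& between_cols) {
  Model model;
  model.X = X; model.y = y;
  model.ind = specimen_index - 1;  // R is 1-based
  model.n_ind = n_ind;
  model.rsf = rsf_cols.n_elem ? rsf_cols - 1 : rsf_cols;
  model.zip = zip;
  model.sd_int = prior_intercept_sd; model.sd_slope = prior_slope_sd;
  model.shrink_scale = prior_shrinkage_scale;
  model.pi_a = pi_a; model.pi_b = pi_b;
  model.lgamma_sum = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) model.lgamma_sum += std::lgamma(y(j) + 1.0);
  model.ind_raw.resize(model.ind.n_elem);
  for (arma::uword j = 0; j < model.ind.n_elem; ++j) model.ind_raw[j] = (int)model.ind(j);
  if (model.K() > 64) stop("too many random-slope factors");

  const int dim = model.dim();
  if ((int)init.n_elem != dim) stop("init length does not match parameter dimension");

  Hamiltonian ham;
  ham.model = &model;
  ham.inv_mass.ones(dim);

  arma::vec th = init, grad(dim);
  double lp = model.logp_grad(th, grad);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initialization");

  // dual averaging state
  double eps = find_initial_stepsize(ham, th);
  double mu = std::log(10.0 * eps);
  double log_eps_bar = 0.0, h_bar = 0.0;
  const double da_gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;
  auto da_restart = [&](double eps_now) {
    mu = std::log(10.0 * eps_now);
    log_eps_bar = std::log(eps_now);
    h_bar = 0.0; da_count = 0;
  };
  da_restart(eps);

  // Stan-style adaptation windows for the diagonal mass matrix
  const bool adapt_mass = tune >= 200;
  const int init_buffer = 75, term_buffer = 50;
  int window = 25;
  int next_window_end = adapt_mass ? init_buffer + window : -1;
  Welford wf; wf.init(dim);

  arma::mat out_draws(draws, dim);
  arma::vec out_energy(draws), out_accept(draws);
  arma::ivec out_div(draws), out_depth(draws), out_leap(draws);

  const int total = tune + draws;
  for (int iter = 0; iter < total; ++iter) {
    const bool warmup = iter < tune;
    arma::vec p = ham.sample_momentum(dim);
    lp = model.logp_grad(th, grad);
    double H0 = -lp + ham.kinetic(p);

    TreeState traj;
    traj.th_minus = th; traj.p_minus = p; traj.g_minus = grad;
    traj.th_plus = th; traj.p_plus = p; traj.g_plus = grad;
    traj.th_prop = th;
    traj.log_w = 0.0; traj.ok = true; traj.divergent = false;
    traj.sum_accept = 0.0; traj.n_leapfrog = 0;

    int depth = 0;
    bool divergent = false;
    double sum_accept = 0.0; int n_leap = 0;
    while (traj.ok && depth < max_treedepth) {
      int dir = runifR() < 0.5 ? -1 : 1;
      TreeState sub;
      if (dir == -1) {
        build_tree(ham, traj.th_minus, traj.p_minus, traj.g_minus,
                   dir, depth, eps, H0, sub);
        traj.th_minus = sub.th_minus; traj.p_minus = sub.p_minus;
        traj.g_minus = sub.g_minus;
      } else {
        build_tree(ham, traj.th_plus, traj.p_plus, traj.g_plus,
                   dir, depth, eps, H0, sub);
        traj.th_plus = sub.th_plus; traj.p_plus = sub.p_plus;
        traj.g_plus = sub.g_plus;
      }
      sum_accept += sub.sum_accept; n_leap += sub.n_leapfrog;
      divergent = divergent || sub.divergent;
      // biased progressive sampling: favour the fresh subtree
      if (sub.ok && sub.log_w > -std::numeric_limits<double>::infinity() &&
          runifR() < std::exp(std::min(0.0, sub.log_w - traj.log_w))) {
        traj.th_prop = sub.th_prop;
      }
      traj.log_w = log_sum_exp(traj.log_w, sub.log_w);
      traj.ok = sub.ok &&
        no_uturn(traj.th_plus, traj.th_minus, traj.p_plus, traj.p_minus,
                 ham.inv_mass);
      ++depth;
    }
    th = traj.th_prop;
    if (model.n_ind > 0) {
      interweave_locations(model, between_x, between_cols, th);
    }

    double accept_stat = n_leap > 0 ? sum_accept / n_leap : 0.0;

    if (warmup) {
      // dual averaging toward the target acceptance statistic
      ++da_count;
      double frac = 1.0 / (da_count + t0);
      h_bar = (1.0 - frac) * h_bar + frac * (target_accept - accept_stat);
      double log_eps = mu - std::sqrt((double)da_count) / da_gamma * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);

      if (adapt_mass && iter >= init_buffer && iter < tune - term_buffer) {
        wf.add(th);
        if (iter + 1 == next_window_end) {
          arma::vec v = wf.variance();
          double nn = wf.n;
          // Stan's regularization toward unit variance
          ham.inv_mass = (nn / (nn + 5.0)) * v +
                         1e-3 * (5.0 / (nn + 5.0)) * arma::ones(dim);
          wf.init(dim);
          window *= 2;
          int end = next_window_end + window;
          if (end + 2 * window > tune - term_buffer) end = tune - term_buffer;
          next_window_end = end;
          eps = std::exp(log_eps_bar);
          da_restart(eps);
        }
      }
      if (iter == tune - 1) eps = std::exp(log_eps_bar);
    } else {
      int t = iter - tune;
      out_draws.row(t) = th.t();
      out_energy(t) = H0;
      out_div(t) = divergent ? 1 : 0;
      out_depth(t) = depth;
      out_leap(t) = n_leap;
      out_accept(t) = accept_stat;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = out_draws, _["energy"] = out_energy,
    _["divergent"] = out_div, _["treedepth"] = out_depth,
    _["n_leapfrog"] = out_leap, _["accept_stat"] = out_accept,
    _["step_size"] = eps, _["inv_mass"] = ham.inv_mass);
}

// Log posterior and gradient for testing against numerical differentiation.
// [[Rcpp::export]]
List model_logp_grad(const arma::mat& X, const arma::vec& y,
                     const arma::uvec& specimen_index, int n_ind,
                     const arma::uvec& rsf_cols, bool zip,
                     double prior_intercept_sd, double prior_slope_sd,
                     double prior_shrinkage_scale, double pi_a, double pi_b,
                     const arma::vec& theta) {
  Model model;
  model.X = X; model.y = y;
  model.ind = specimen_index - 1;
  model.n_ind = n_ind;
  model.rsf = rsf_cols.n_elem ? rsf_cols - 1 : rsf_cols;
  model.zip = zip;
  model.sd_int = prior_intercept_sd; model.sd_slope = prior_slope_sd;
  model.shrink_scale = prior_shrinkage_scale;
  model.pi_a = pi_a; model.pi_b = pi_b;
  model.lgamma_sum = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) model.lgamma_sum += std::lgamma(y(j) + 1.0);
  model.ind_raw.resize(model.ind.n_elem);
  for (arma::uword j = 0; j < model.ind.n_elem; ++j) model.ind_raw[j] = (int)model.ind(j);
  if (model.K() > 64) stop("too many random-slope factors");
  arma::vec g(model.dim());
  double lp = model.logp_grad(theta, g);
  return List::create(_["logp"] = lp, _["grad"] = g);
}
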