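// Log posterior (with analytic gradient) of the hierarchical dyadic beta
// regression, and a No-U-Turn sampler (multinomial NUTS, diagonal metric,
// dual-averaging step-size adaptation) used to fit it.
//
// Unconstrained parameter vector layout (S sites, B basins, K Strahler
// levels; scales sampled on the log scale with Jacobian):
//   [0]                    alpha_baseline
//   [1 .. S]               z_site (non-centered site intercepts)
//   [S+1]                  log sigma_site
//   [S+2 .. S+B+1]         alpha_basin
//   [S+B+2 .. S+B+K+1]     z_strahler (non-centered)
//   [S+B+K+2]              log sigma_strahler
//   [.. +B]                z_beta_distance
//   [.. +B]                z_beta_flow
//   [.. +B]                z_beta_precip
//   [.. +3]                mu_distance, mu_flow, mu_precipitation
//   [.. +3]                log sigma_distance, log sigma_flow, log sigma_precip
//   [last]                 log kappa

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// fast digamma: shift-up recurrence then asymptotic series (|rel err| ~1e-13
// for x > 0; the sampler only ever evaluates strictly positive arguments)
static inline double fast_digamma(double x) {
  double r = 0.0;
  while (x < 8.0) { r -= 1.0 / x; x += 1.0; }
  const double ix = 1.0 / x, ix2 = ix * ix;
  return r + std::log(x) - 0.5 * ix -
         ix2 * (1.0 / 12.0 - ix2 * (1.0 / 120.0 - ix2 * (1.0 / 252.0 -
         ix2 * (1.0 / 240.0))));
}

// fast log-gamma via Stirling's series after shifting the argument up
static inline double fast_lgamma(double x) {
  const double HALF_LOG_2PI_ = 0.9189385332046727;
  double r = 0.0;
  while (x < 10.0) { r -= std::log(x); x += 1.0; }
  const double ix = 1.0 / x, ix2 = ix * ix;
  return r + (x - 0.5) * std::log(x) - x + HALF_LOG_2PI_ +
         ix * (1.0 / 12.0 - ix2 * (1.0 / 360.0 - ix2 * (1.0 / 1260.0 -
         ix2 * (1.0 / 1680.0))));
}

struct Target {
  int npar;
  virtual void lp_grad(const std::vector<double>& th, double& lp,
                       std::vector<double>& grad) const = 0;
  virtual ~Target() {}
};

// ---------------------------------------------------------------------------
// model target
// ---------------------------------------------------------------------------

struct DdcsTarget : Target {
  int N, S, B, K;
  std::vector<int> s1, s2, basin, str;   // 0-based indices
  std::vector<double> xd, fl, xp, ly, l1y, lyr;

  // index helpers
  int i_a0() const { return 0; }
  int i_zs() const { return 1; }
  int i_ts() const { return S + 1; }
  int i_ac() const { return S + 2; }
  int i_zo() const { return S + B + 2; }
  int i_to() const { return S + B + K + 2; }
  int i_z1() const { return S + B + K + 3; }
  int i_z2() const { return S + 2 * B + K + 3; }
  int i_z3() const { return S + 3 * B + K + 3; }
  int i_mu() const { return S + 4 * B + K + 3; }
  int i_tb() const { return S + 4 * B + K + 6; }
  int i_lam() const { return S + 4 * B + K + 9; }

  void init_from_list(const List& data) {
    IntegerVector s1r = data["site1"], s2r = data["site2"],
                  br = data["basin"], sr = data["strahler_level"];
    NumericVector xdr = data["x_distance"], flr = data["flow"],
                  xpr = data["x_precip"], yr = data["y"];
    S = as<int>(data["n_sites"]);
    B = as<int>(data["n_basins"]);
    K = as<int>(data["n_strahler"]);
    N = s1r.size();
    s1.resize(N); s2.resize(N); basin.resize(N); str.resize(N);
    xd.resize(N); fl.resize(N); xp.resize(N);
    ly.resize(N); l1y.resize(N); lyr.resize(N);
    for (int i = 0; i < N; ++i) {
      s1[i] = s1r[i] - 1; s2[i] = s2r[i] - 1;
      basin[i] = br[i] - 1; str[i] = sr[i] - 1;
      if (s1[i] < 0 || s1[i] >= S || s2[i] < 0 || s2[i] >= S ||
          basin[i] < 0 || basin[i] >= B || str[i] < 0 || str[i] >= K)
        stop("design index out of range");
      xd[i] = xdr[i]; fl[i] = flr[i]; xp[i] = xpr[i];
      double y = yr[i];
      if (!(y > 0.0 && y < 1.0))
        stop("similarities must lie strictly in (0, 1)");
      ly[i] = std::log(y); l1y[i] = std::log1p(-y); lyr[i] = ly[i] - l1y[i];
    }
    npar = S + 4 * B + K + 10;
  }

  void lp_grad(const std::vector<double>& th, double& lp,
               std::vector<double>& grad) const {
    const double HALF_LOG_2PI = 0.9189385332046727;
    std::fill(grad.begin(), grad.end(), 0.0);
    lp = R_NegInf;

    // reject absurd log-scale values before exp() can overflow
    if (std::fabs(th[i_ts()]) > 40 || std::fabs(th[i_to()]) > 40 ||
        std::fabs(th[i_lam()]) > 40 || std::fabs(th[i_tb()]) > 40 ||
        std::fabs(th[i_tb() + 1]) > 40 || std::fabs(th[i_tb() + 2]) > 40)
      return;

    const double a0 = th[i_a0()];
    const double sig_s = std::exp(th[i_ts()]);
    const double sig_o = std::exp(th[i_to()]);
    const double mu_d = th[i_mu()], mu_f = th[i_mu() + 1], mu_p = th[i_mu() + 2];
    const double sb1 = std::exp(th[i_tb()]), sb2 = std::exp(th[i_tb() + 1]),
                 sb3 = std::exp(th[i_tb() + 2]);
    const double kappa = std::exp(th[i_lam()]);

    std::vector<double> a_s(S), a_o(K), b1(B), b2(B), b3(B);
    for (int s = 0; s < S; ++s) a_s[s] = sig_s * th[i_zs() + s];
    for (int o = 0; o < K; ++o) a_o[o] = sig_o * th[i_zo() + o];
    for (int c = 0; c < B; ++c) {
      b1[c] = mu_d + sb1 * th[i_z1() + c];
      b2[c] = mu_f + sb2 * th[i_z2() + c];
      b3[c] = mu_p + sb3 * th[i_z3() + c];
    }

    // likelihood
    double ll = 0.0, gk_sum = 0.0;
    std::vector<double> g_as(S, 0.0), g_ac(B, 0.0), g_ao(K, 0.0),
        g_b1(B, 0.0), g_b2(B, 0.0), g_b3(B, 0.0);
    double g_a0 = 0.0;
    const double lgk = fast_lgamma(kappa), dgk = fast_digamma(kappa);
    for (int i = 0; i < N; ++i) {
      const int c = basin[i];
      const double eta = a0 + a_s[s1[i]] + a_s[s2[i]] + g_safe(a_o, str[i]) +
          th[i_ac() + c] + b1[c] * xd[i] + b2[c] * fl[i] + b3[c] * xp[i];
      const double m = 1.0 / (1.0 + std::exp(-eta));
      const double p = m * kappa, q = kappa - p;
      if (!(p > 0.0) || !(q > 0.0)) return;     // logistic under/overflow
      const double dgp = fast_digamma(p), dgq = fast_digamma(q);
      ll += lgk - fast_lgamma(p) - fast_lgamma(q) +
            (p - 1.0) * ly[i] + (q - 1.0) * l1y[i];
      const double ge = kappa * m * (1.0 - m) * (lyr[i] - dgp + dgq);
      g_a0 += ge;
      g_as[s1[i]] += ge;
      g_as[s2[i]] += ge;
      g_ac[c] += ge;
      g_ao[str[i]] += ge;
      g_b1[c] += ge * xd[i];
      g_b2[c] += ge * fl[i];
      g_b3[c] += ge * xp[i];
      gk_sum += dgk - m * dgp - (1.0 - m) * dgq + m * ly[i] + (1.0 - m) * l1y[i];
    }
    if (!std::isfinite(ll)) return;

    // priors (Normal(0, 0.3) for baseline, basin intercepts, hypermeans;
    // standard normal for the non-centered z's; Exponential for scales and
    // half-Normal(0, 50) for kappa, both with log-scale Jacobians)
    double pr = 0.0;
    const double v03 = 0.09;
    pr += -0.5 * a0 * a0 / v03 - HALF_LOG_2PI - std::log(0.3);
    for (int s = 0; s < S; ++s) {
      const double z = th[i_zs() + s];
      pr += -0.5 * z * z - HALF_LOG_2PI;
    }
    for (int o = 0; o < K; ++o) {
      const double z = th[i_zo() + o];
      pr += -0.5 * z * z - HALF_LOG_2PI;
    }
    for (int c = 0; c < B; ++c) {
      const double ac = th[i_ac() + c];
      pr += -0.5 * ac * ac / v03 - HALF_LOG_2PI - std::log(0.3);
      const double z1v = th[i_z1() + c], z2v = th[i_z2() + c], z3v = th[i_z3() + c];
      pr += -0.5 * (z1v * z1v + z2v * z2v + z3v * z3v) - 3.0 * HALF_LOG_2PI;
    }
    for (int j = 0; j < 3; ++j) {
      const double mu = th[i_mu() + j];
      pr += -0.5 * mu * mu / v03 - HALF_LOG_2PI - std::log(0.3);
    }
    pr += -sig_s + th[i_ts()];                       // Exp(1), Jacobian
    pr += std::log(2.0) - 2.0 * sig_o + th[i_to()];  // Exp(2), Jacobian
    pr += 3.0 * std::log(2.0) - 2.0 * (sb1 + sb2 + sb3) +
          th[i_tb()] + th[i_tb() + 1] + th[i_tb() + 2];
    pr += std::log(2.0) - 0.5 * kappa * kappa / 2500.0 - HALF_LOG_2PI -
          std::log(50.0) + th[i_lam()];              // half-Normal(0,50)

    lp = ll + pr;
    if (!std::isfinite(lp)) { lp = R_NegInf; return; }

    // assemble gradient (chain rule through the non-centered scales)
    grad[i_a0()] = g_a0 - a0 / v03;
    double zs_dot = 0.0;
    for (int s = 0; s < S; ++s) {
      const double z = th[i_zs() + s];
      grad[i_zs() + s] = sig_s * g_as[s] - z;
      zs_dot += z * g_as[s];
    }
    grad[i_ts()] = sig_s * zs_dot - sig_s + 1.0;
    for (int c = 0; c < B; ++c)
      grad[i_ac() + c] = g_ac[c] - th[i_ac() + c] / v03;
    double zo_dot = 0.0;
    for (int o = 0; o < K; ++o) {
      const double z = th[i_zo() + o];
      grad[i_zo() + o] = sig_o * g_ao[o] - z;
      zo_dot += z * g_ao[o];
    }
    grad[i_to()] = sig_o * zo_dot - 2.0 * sig_o + 1.0;
    double z1_dot = 0.0, z2_dot = 0.0, z3_dot = 0.0,
           g_mu1 = 0.0, g_mu2 = 0.0, g_mu3 = 0.0;
    for (int c = 0; c < B; ++c) {
      grad[i_z1() + c] = sb1 * g_b1[c] - th[i_z1() + c];
      grad[i_z2() + c] = sb2 * g_b2[c] - th[i_z2() + c];
      grad[i_z3() + c] = sb3 * g_b3[c] - th[i_z3() + c];
      z1_dot += th[i_z1() + c] * g_b1[c];
      z2_dot += th[i_z2() + c] * g_b2[c];
      z3_dot += th[i_z3() + c] * g_b3[c];
      g_mu1 += g_b1[c]; g_mu2 += g_b2[c]; g_mu3 += g_b3[c];
    }
    grad[i_mu()]     = g_mu1 - mu_d / v03;
    grad[i_mu() + 1] = g_mu2 - mu_f / v03;
    grad[i_mu() + 2] = g_mu3 - mu_p / v03;
    grad[i_tb()]     = sb1 * z1_dot - 2.0 * sb1 + 1.0;
    grad[i_tb() + 1] = sb2 * z2_dot - 2.0 * sb2 + 1.0;
    grad[i_tb() + 2] = sb3 * z3_dot - 2.0 * sb3 + 1.0;
    grad[i_lam()] = kappa * gk_sum - kappa * kappa / 2500.0 + 1.0;
    for (int j = 0; j < npar; ++j)
      if (!std::isfinite(grad[j])) { lp = R_NegInf; return; }
  }

  static double g_safe(const std::vector<double>& v, int i) { return v[i]; }
};

// diagonal Gaussian target, used to exercise the sampler on a known
// distribution in unit tests
struct GaussTarget : Target {
  std::vector<double> sd;
  void lp_grad(const std::vector<double>& th, double& lp,
               std::vector<double>& grad) const {
    lp = 0.0;
    for (int j = 0; j < npar; ++j) {
      const double v = sd[j] * sd[j];
      lp += -0.5 * th[j] * th[j] / v;
      grad[j] = -th[j] / v;
    }
  }
};

// ---------------------------------------------------------------------------
// NUTS (multinomial sampling across the trajectory, diagonal metric,
// dual-averaging step size, Stan-style windowed metric adaptation)
// ---------------------------------------------------------------------------

struct PhasePoint {
  std::vector<double> th, r, grad;
  double lp;
};

struct TreeState {
  PhasePoint minus, plus, prop;
  double log_w, s_acc;
  int n_acc, nl;
  bool div, turn;
};

class Nuts {
public:
  const Target& tgt;
  int d;
  std::vector<double> inv_metric;
  double eps, H0;
  int max_td;
  long n_grad;

  Nuts(const Target& t, int max_treedepth)
      : tgt(t), d(t.npar), inv_metric(t.npar, 1.0), eps(1.0),
        max_td(max_treedepth), n_grad(0) {}

  double hamiltonian(const PhasePoint& z) const {
    if (!std::isfinite(z.lp)) return R_NegInf;
    double kin = 0.0;
    for (int j = 0; j < d; ++j) kin += z.r[j] * z.r[j] * inv_metric[j];
    return z.lp - 0.5 * kin;
  }

  void leapfrog(PhasePoint& z, double dir) {
    const double e = dir * eps;
    for (int j = 0; j < d; ++j) z.r[j] += 0.5 * e * z.grad[j];
    for (int j = 0; j < d; ++j) z.th[j] += e * inv_metric[j] * z.r[j];
    tgt.lp_grad(z.th, z.lp, z.grad);
    ++n_grad;
    for (int j = 0; j < d; ++j) z.r[j] += 0.5 * e * z.grad[j];
  }

  bool uturn(const PhasePoint& zm, const PhasePoint& zp) const {
    double dm = 0.0, dp = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dth = zp.th[j] - zm.th[j];
      dm += dth * inv_metric[j] * zm.r[j];
      dp += dth * inv_metric[j] * zp.r[j];
    }
    return dm < 0.0 || dp < 0.0;
  }

  void build_tree(const PhasePoint& z, int depth, double dir, TreeState& out) {
    if (depth == 0) {
      PhasePoint znew = z;
      leapfrog(znew, dir);
      double dH = hamiltonian(znew) - H0;
      if (!std::isfinite(dH)) dH = R_NegInf;
      out.minus = znew; out.plus = znew; out.prop = znew;
      out.log_w = dH;
      out.s_acc = std::isfinite(dH) ? std::min(1.0, std::exp(std::min(dH, 0.0))) : 0.0;
      out.n_acc = 1; out.nl = 1;
      out.div = dH < -1000.0;
      out.turn = false;
      return;
    }
    TreeState t1, t2;
    build_tree(z, depth - 1, dir, t1);
    if (t1.div || t1.turn) { out = t1; return; }
    build_tree(dir > 0 ? t1.plus : t1.minus, depth - 1, dir, t2);
    out = t2;
    if (dir > 0) out.minus = t1.minus; else out.plus = t1.plus;
    const double lw = logsumexp(t1.log_w, t2.log_w);
    if (!(t2.div || t2.turn)) {
      if (unif_rand() < std::exp(t2.log_w - lw)) out.prop = t2.prop;
      else out.prop = t1.prop;
    } else out.prop = t1.prop;
    out.log_w = lw;
    out.s_acc = t1.s_acc + t2.s_acc;
    out.n_acc = t1.n_acc + t2.n_acc;
    out.nl = t1.nl + t2.nl;
    out.div = t1.div || t2.div;
    out.turn = t1.turn || t2.turn || uturn(out.minus, out.plus);
  }

  // one transition; returns accept-stat, updates z in place
  double transition(PhasePoint& z, bool& divergent, int& depth_out, int& nl_out) {
    PhasePoint cur = z;
    for (int j = 0; j < d; ++j) cur.r[j] = norm_rand() / std::sqrt(inv_metric[j]);
    H0 = hamiltonian(cur);
    PhasePoint prop = cur;
    TreeState tree;
    tree.minus = cur; tree.plus = cur;
    double log_w_tot = 0.0, s_acc = 0.0;
    int n_acc = 0, nl = 0, depth = 0;
    divergent = false;
    while (true) {
      const double dir = unif_rand() < 0.5 ? -1.0 : 1.0;
      TreeState sub;
      build_tree(dir > 0 ? tree.plus : tree.minus, depth, dir, sub);
      if (dir > 0) tree.plus = sub.plus; else tree.minus = sub.minus;
      s_acc += sub.s_acc; n_acc += sub.n_acc; nl += sub.nl;
      if (sub.div) { divergent = true; break; }
      if (sub.turn) break;
      if (unif_rand() < std::exp(sub.log_w - logsumexp(log_w_tot, sub.log_w)))
        prop = sub.prop;
      log_w_tot = logsumexp(log_w_tot, sub.log_w);
      ++depth;
      if (uturn(tree.minus, tree.plus)) break;
      if (depth >= max_td) break;
    }
    z = prop;
    depth_out = depth;
    nl_out = nl;
    return n_acc > 0 ? s_acc / n_acc : 0.0;
  }

  double find_eps(const PhasePoint& z0) {
    eps = 1.0;
    PhasePoint z = z0;
    for (int j = 0; j < d; ++j) z.r[j] = norm_rand() / std::sqrt(inv_metric[j]);
    const double H_init = hamiltonian(z);
    double a = 0.0;
    {
      PhasePoint zt = z;
      leapfrog(zt, 1.0);
      const double H1 = hamiltonian(zt);
      a = (std::isfinite(H1) && H1 - H_init > std::log(0.5)) ? 1.0 : -1.0;
    }
    for (int it = 0; it < 50; ++it) {
      const double eps2 = eps * std::pow(2.0, a);
      const double saved = eps;
      eps = eps2;
      PhasePoint zt = z;
      leapfrog(zt, 1.0);
      const double H1 = hamiltonian(zt);
      const bool ok = std::isfinite(H1) && a * (H1 - H_init) > a * std::log(0.5);
      if (!ok) { eps = saved; break; }
    }
    return eps;
  }

  static double logsumexp(double a, double b) {
    const double m = std::max(a, b);
    if (!std::isfinite(m)) return m;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
  }
};

static List nuts_run(const Target& tgt, NumericVector init, int n_warmup,
                     int n_sampling, int max_treedepth, double delta,
                     int init_buffer, int term_buffer, int base_window) {
  const int d = tgt.npar;
  if (init.size() != d) stop("init has wrong length");
  Nuts nuts(tgt, max_treedepth);

  PhasePoint z;
  z.th.assign(init.begin(), init.end());
  z.r.assign(d, 0.0);
  z.grad.assign(d, 0.0);
  tgt.lp_grad(z.th, z.lp, z.grad);
  if (!std::isfinite(z.lp)) stop("initial point has non-finite log posterior");

  // dual averaging
  const double gamma_da = 0.05, t0 = 10.0, kap = 0.75;
  double eps0 = nuts.find_eps(z);
  double mu_da = std::log(10.0 * eps0);
  double log_eps_bar = std::log(eps0), Hbar = 0.0;
  int da_n = 0;
  nuts.eps = eps0;

  // metric adaptation windows
  std::vector<int> win_end;
  if (n_warmup >= init_buffer + term_buffer + base_window) {
    int e = init_buffer + base_window, w = base_window;
    while (true) {
      const int nxt = e + 2 * w;
      if (nxt + term_buffer > n_warmup) {
        win_end.push_back(n_warmup - term_buffer);
        break;
      }
      win_end.push_back(e);
      w *= 2; e = nxt;
    }
  }
  const int last_win = win_end.empty() ? 0 : win_end.back();

  long wf_n = 0;
  std::vector<double> wf_m(d, 0.0), wf_s(d, 0.0);

  NumericMatrix draws(n_sampling, d);
  LogicalVector div(n_sampling), sat(n_sampling);
  NumericVector acc(n_sampling);
  IntegerVector nlv(n_sampling), depthv(n_sampling);
  int div_warmup = 0;

  for (int it = 1; it <= n_warmup + n_sampling; ++it) {
    bool divergent; int depth, nl;
    const double astat = nuts.transition(z, divergent, depth, nl);
    if (it <= n_warmup) {
      if (divergent) ++div_warmup;
      ++da_n;
      const double w1 = 1.0 / (da_n + t0);
      Hbar = (1.0 - w1) * Hbar + w1 * (delta - astat);
      const double log_eps = mu_da - std::sqrt((double) da_n) / gamma_da * Hbar;
      const double w2 = std::pow((double) da_n, -kap);
      log_eps_bar = w2 * log_eps + (1.0 - w2) * log_eps_bar;
      nuts.eps = std::exp(log_eps);

      if (!win_end.empty() && it > init_buffer && it <= last_win) {
        ++wf_n;
        for (int j = 0; j < d; ++j) {
          const double dlt = z.th[j] - wf_m[j];
          wf_m[j] += dlt / wf_n;
          wf_s[j] += dlt * (z.th[j] - wf_m[j]);
        }
        if (std::find(win_end.begin(), win_end.end(), it) != win_end.end()) {
          if (wf_n > 1) {
            for (int j = 0; j < d; ++j) {
              const double v = wf_s[j] / (wf_n - 1);
              nuts.inv_metric[j] =
                  v * wf_n / (wf_n + 5.0) + 1e-3 * 5.0 / (wf_n + 5.0);
            }
          }
          wf_n = 0;
          std::fill(wf_m.begin(), wf_m.end(), 0.0);
          std::fill(wf_s.begin(), wf_s.end(), 0.0);
          const double e = nuts.find_eps(z);
          nuts.eps = e;
          mu_da = std::log(10.0 * e);
          log_eps_bar = std::log(e);
          Hbar = 0.0; da_n = 0;
        }
      }
      if (it == n_warmup) nuts.eps = std::exp(log_eps_bar);
    } else {
      const int i = it - n_warmup - 1;
      for (int j = 0; j < d; ++j) draws(i, j) = z.th[j];
      div[i] = divergent;
      sat[i] = depth >= max_treedepth;
      acc[i] = astat;
      nlv[i] = nl;
      depthv[i] = depth;
    }
  }

  return List::create(
      _["draws"] = draws, _["divergent"] = div, _["treedepth_saturated"] = sat,
      _["accept_stat"] = acc, _["n_leapfrog"] = nlv, _["treedepth"] = depthv,
      _["step_size"] = nuts.eps, _["inv_metric"] = wrap(nuts.inv_metric),
      _["divergent_warmup"] = div_warmup, _["n_grad"] = (double) nuts.n_grad);
}

// [[Rcpp::export]]
List ddcs_lp_grad_cpp(NumericVector theta, List data) {
  DdcsTarget tgt;
  tgt.init_from_list(data);
  if (theta.size() != tgt.npar) stop("theta has wrong length");
  std::vector<double> th(theta.begin(), theta.end()), grad(tgt.npar, 0.0);
  double lp;
  tgt.lp_grad(th, lp, grad);
  return List::create(_["lp"] = lp, _["grad"] = wrap(grad));
}

// [[Rcpp::export]]
List nuts_ddcs_cpp(List data, NumericVector init, int n_warmup, int n_sampling,
                   int max_treedepth, double delta, int init_buffer,
                   int term_buffer, int base_window) {
  DdcsTarget tgt;
  tgt.init_from_list(data);
  return nuts_run(tgt, init, n_warmup, n_sampling, max_treedepth, delta,
                  init_buffer, term_buffer, base_window);
}

// [[Rcpp::export]]
List nuts_gauss_cpp(NumericVector sds, NumericVector init, int n_warmup,
                    int n_sampling, int max_treedepth, double delta,
                    int init_buffer, int term_buffer, int base_window) {
  GaussTarget tgt;
  tgt.npar = sds.size();
  tgt.sd.assign(sds.begin(), sds.end());
  return nuts_run(tgt, init, n_warmup, n_sampling, max_treedepth, delta,
                  init_buffer, term_buffer, base_window);
}

// [[Rcpp::export]]
int ddcs_npar_cpp(List data) {
  DdcsTarget tgt;
  tgt.init_from_list(data);
  return tgt.npar;
}
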