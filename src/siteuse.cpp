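#include <Rcpp.h>
using namespace Rcpp;

// Two-state (occupied / unoccupied) daily occupancy hidden Markov machinery.
// Latent state u_d in {0,1} per day; emissions are the visits of that day:
// y_j ~ Bernoulli(u_d * p_j). A day without visits is uninformative; a day
// with any detection is incompatible with u_d = 0.

static inline double inv_logit(double x) {
  return x >= 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

// fold per-visit Bernoulli terms into per-day emission factors:
// e1[d] = prod_j p_j^y (1-p_j)^(1-y); det[d] = 1 if any detection on day d
static void day_emissions(const int* day, const int* y, const double* p, int nv,
                          int D, std::vector<double>& e1, std::vector<int>& det) {
  std::fill(e1.begin(), e1.begin() + D, 1.0);
  std::fill(det.begin(), det.begin() + D, 0);
  for (int v = 0; v < nv; ++v) {
    const int d = day[v] - 1;
    e1[d] *= y[v] ? p[v] : (1.0 - p[v]);
    if (y[v]) det[d] = 1;
  }
}

// scaled forward recursion; returns log marginal likelihood and optionally the
// filtered P(u_d = 1 | y_{1:d}) needed by the backward sampler
static double forward_pass(const std::vector<double>& e1, const std::vector<int>& det,
                           double psi1, const double* phi, const double* gam,
                           int D, double* a1out) {
  double ll = 0.0;
  double a1 = psi1 * e1[0];
  double a0 = (1.0 - psi1) * (det[0] ? 0.0 : 1.0);
  double s = a0 + a1;
  if (!(s > 0.0) || !R_finite(s)) return R_NegInf;
  ll += std::log(s); a1 /= s; a0 /= s;
  if (a1out) a1out[0] = a1;
  for (int d = 1; d < D; ++d) {
    const double ph = phi[d - 1], ga = gam[d - 1];
    double n1 = (a1 * ph + a0 * ga) * e1[d];
    double n0 = (a1 * (1.0 - ph) + a0 * (1.0 - ga)) * (det[d] ? 0.0 : 1.0);
    s = n0 + n1;
    if (!(s > 0.0) || !R_finite(s)) return R_NegInf;
    ll += std::log(s); a1 = n1 / s; a0 = n0 / s;
    if (a1out) a1out[d] = a1;
  }
  return ll;
}

// backward sampling of one trajectory given the filtered marginals
static void backward_draw(const double* a1, const double* phi, const double* gam,
                          int D, int* u) {
  u[D - 1] = (unif_rand() < a1[D - 1]) ? 1 : 0;
  for (int d = D - 2; d >= 0; --d) {
    const int un = u[d + 1];
    const double t1 = un ? phi[d] : (1.0 - phi[d]);   // from u_d = 1
    const double t0 = un ? gam[d] : (1.0 - gam[d]);   // from u_d = 0
    const double w1 = a1[d] * t1, w0 = (1.0 - a1[d]) * t0;
    const double pr1 = (w1 + w0) > 0.0 ? w1 / (w1 + w0) : 0.0;
    u[d] = (unif_rand() < pr1) ? 1 : 0;
  }
}

// [[Rcpp::export]]
double fw_loglik_cpp(IntegerVector day, IntegerVector y, NumericVector p,
                     double psi1, NumericVector phi, NumericVector gamma, int D) {
  std::vector<double> e1(D);
  std::vector<int> det(D);
  day_emissions(day.begin(), y.begin(), p.begin(), day.size(), D, e1, det);
  return forward_pass(e1, det, psi1, phi.begin(), gamma.begin(), D, nullptr);
}

// [[Rcpp::export]]
IntegerMatrix ffbs_cpp(IntegerVector day, IntegerVector y, NumericVector p,
                       double psi1, NumericVector phi, NumericVector gamma,
                       int D, int n) {
  std::vector<double> e1(D);
  std::vector<int> det(D);
  day_emissions(day.begin(), y.begin(), p.begin(), day.size(), D, e1, det);
  std::vector<double> a1(D);
  double ll = forward_pass(e1, det, psi1, phi.begin(), gamma.begin(), D, a1.data());
  if (ll == R_NegInf)
    stop("detection history has zero probability under the supplied parameters");
  IntegerMatrix out(n, D);
  std::vector<int> u(D);
  for (int i = 0; i < n; ++i) {
    backward_draw(a1.data(), phi.begin(), gamma.begin(), D, u.data());
    for (int d = 0; d < D; ++d) out(i, d) = u[d];
  }
  return out;
}

// total presence days and longest run of consecutive presence days per row
// [[Rcpp::export]]
IntegerMatrix run_stats_cpp(IntegerMatrix u) {
  const int n = u.nrow(), D = u.ncol();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0, cur = 0;
    for (int d = 0; d < D; ++d) {
      if (u(i, d)) { ++tot; ++cur; if (cur > best) best = cur; }
      else cur = 0;
    }
    out(i, 0) = tot;
    out(i, 1) = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-species MCMC: componentwise adaptive random-walk Metropolis on the
// marginal posterior (latent trajectories integrated out by the forward
// algorithm), with FFBS trajectory draws for the target year at each kept
// iteration. Parameter vector layout (all unconstrained):
//   0 logit(pmax)  1 logit(psi1)  2 mu_alpha  3 eta2 (2nd season half, log
//   lambda)  4 delta (PLL slope)  5-7 b0,b1,b2 (persistence, logit)
//   8-10 c0,c1,c2 (colonization, logit)  11 log sigma_alpha
//   12 log sigma_phi_site  13 log sigma_phi_year  14 log sigma_gam_site
//   15 log sigma_gam_year  16..16+S-1 site alpha raw (non-centered)
//   +S site phi raw, +2S site gam raw, 16+3S..+T-1 year phi raw, +T year gam raw
// ---------------------------------------------------------------------------

struct Block {
  int site, year;            // 0-based
  std::vector<int> day, sll, y, half;
  double pll;
};

struct Model {
  std::vector<Block> blocks;
  int D, S, T;
  std::vector<double> z, z2;
  double coef_sd, sd_scale, pmax_a, pmax_b, psi1_a, psi1_b;

  int P() const { return 16 + 3 * S + 2 * T; }

  void block_fields(const std::vector<double>& th, const Block& b,
                    std::vector<double>& e1, std::vector<int>& det,
                    std::vector<double>& phi, std::vector<double>& gam,
                    double& psi1) const {
    const double pmax = inv_logit(th[0]);
    psi1 = inv_logit(th[1]);
    const double sa = std::exp(th[11]);
    const double sps = std::exp(th[12]), spy = std::exp(th[13]);
    const double sgs = std::exp(th[14]), sgy = std::exp(th[15]);
    const int i = b.site, t = b.year;
    const double alpha = th[2] + sa * th[16 + i];
    const double rephi = sps * th[16 + S + i] + spy * th[16 + 3 * S + t];
    const double regam = sgs * th[16 + 2 * S + i] + sgy * th[16 + 3 * S + T + t];
    std::fill(e1.begin(), e1.begin() + D, 1.0);
    std::fill(det.begin(), det.begin() + D, 0);
    const double lam0 = std::exp(alpha + th[4] * b.pll);
    const double lam1 = lam0 * std::exp(th[3]);
    const int nv = (int) b.day.size();
    for (int v = 0; v < nv; ++v) {
      const double lam = b.half[v] ? lam1 : lam0;
      const double pv = pmax * (1.0 - std::exp(-lam * b.sll[v]));
      const int d = b.day[v] - 1;
      e1[d] *= b.y[v] ? pv : (1.0 - pv);
      if (b.y[v]) det[d] = 1;
    }
    for (int d = 0; d < D - 1; ++d) {
      phi[d] = inv_logit(th[5] + th[6] * z[d] + th[7] * z2[d] + rephi);
      gam[d] = inv_logit(th[8] + th[9] * z[d] + th[10] * z2[d] + regam);
    }
  }

  double block_ll(const std::vector<double>& th, const Block& b,
                  std::vector<double>& e1, std::vector<int>& det,
                  std::vector<double>& phi, std::vector<double>& gam) const {
    double psi1;
    block_fields(th, b, e1, det, phi, gam, psi1);
    return forward_pass(e1, det, psi1, phi.data(), gam.data(), D, nullptr);
  }

  // componentwise log prior (includes change-of-variable Jacobians)
  double lprior(int j, double x) const {
    if (j == 0 || j == 1) {
      const double a = (j == 0) ? pmax_a : psi1_a;
      const double bb = (j == 0) ? pmax_b : psi1_b;
      // Beta(a, b) on inv_logit(x) with Jacobian p(1-p)
      const double lp = -std::log1p(std::exp(-x));
      const double l1mp = -std::log1p(std::exp(x));
      return a * lp + bb * l1mp;
    }
    if (j >= 2 && j <= 10) return -0.5 * x * x / (coef_sd * coef_sd);
    if (j >= 11 && j <= 15) {
      const double sig = std::exp(x);   // half-normal(sd_scale) + Jacobian
      return -0.5 * sig * sig / (sd_scale * sd_scale) + x;
    }
    return -0.5 * x * x;                // non-centered effects ~ N(0,1)
  }
};

// [[Rcpp::export]]
List siteuse_mcmc_cpp(List blocks_r, int D, int S, int T, NumericVector z,
                      List priors, int n_warmup, int n_samples, int thin,
                      NumericVector init, int target_year, double step_init) {
  Model M;
  M.D = D; M.S = S; M.T = T;
  M.z.assign(z.begin(), z.end());
  M.z2.resize(M.z.size());
  for (size_t i = 0; i < M.z.size(); ++i) M.z2[i] = M.z[i] * M.z[i];
  M.coef_sd  = as<double>(priors["coef_sd"]);
  M.sd_scale = as<double>(priors["sd_scale"]);
  M.pmax_a   = as<double>(priors["pmax_a"]);
  M.pmax_b   = as<double>(priors["pmax_b"]);
  M.psi1_a   = as<double>(priors["psi1_a"]);
  M.psi1_b   = as<double>(priors["psi1_b"]);

  const int nb = blocks_r.size();
  M.blocks.resize(nb);
  for (int b = 0; b < nb; ++b) {
    List bl = blocks_r[b];
    Block& B = M.blocks[b];
    B.site = as<int>(bl["site"]) - 1;
    B.year = as<int>(bl["year"]) - 1;
    IntegerVector dd = bl["day"], ss = bl["sll"], yy = bl["y"], hh = bl["half"];
    B.day.assign(dd.begin(), dd.end());
    B.sll.assign(ss.begin(), ss.end());
    B.y.assign(yy.begin(), yy.end());
    B.half.assign(hh.begin(), hh.end());
    B.pll = as<double>(bl["pll"]);
  }

  const int P = M.P();
  if (init.size() != P) stop("init has length %d, expected %d", init.size(), P);
  std::vector<double> th(init.begin(), init.end());

  // which blocks each parameter touches
  std::vector<std::vector<int>> aff(P);
  std::vector<int> all(nb);
  for (int b = 0; b < nb; ++b) all[b] = b;
  for (int j = 0; j < 16; ++j) aff[j] = all;
  for (int b = 0; b < nb; ++b) {
    const int i = M.blocks[b].site, t = M.blocks[b].year;
    aff[16 + i].push_back(b);
    aff[16 + S + i].push_back(b);
    aff[16 + 2 * S + i].push_back(b);
    aff[16 + 3 * S + t].push_back(b);
    aff[16 + 3 * S + T + t].push_back(b);
  }

  std::vector<double> e1(D), phi(std::max(D - 1, 1)), gam(std::max(D - 1, 1)), a1(D);
  std::vector<int> det(D), utmp(D);

  std::vector<double> llc(nb), llnew(nb);
  for (int b = 0; b < nb; ++b) {
    llc[b] = M.block_ll(th, M.blocks[b], e1, det, phi, gam);
    if (llc[b] == R_NegInf)
      stop("failed to initialize in-support: block %d has zero likelihood", b + 1);
  }

  std::vector<double> lstep(P, std::log(step_init));
  std::vector<double> acc(P, 0.0), tries(P, 0.0);

  const int n_keep = n_samples / thin;
  NumericMatrix out_par(n_keep, P);
  std::vector<int> tblocks;
  for (int b = 0; b < nb; ++b)
    if (M.blocks[b].year == target_year - 1) tblocks.push_back(b);
  const int nt = (int) tblocks.size();
  IntegerVector out_traj(static_cast<R_xlen_t>(n_keep) * nt * D);
  IntegerVector traj_sites(nt);
  for (int k = 0; k < nt; ++k) traj_sites[k] = M.blocks[tblocks[k]].site + 1;

  const int total = n_warmup + n_samples;
  int keep = 0;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < P; ++j) {
      const double cur = th[j];
      th[j] = cur + std::exp(lstep[j]) * norm_rand();
      double lacc = M.lprior(j, th[j]) - M.lprior(j, cur);
      bool bad = false;
      for (size_t k = 0; k < aff[j].size(); ++k) {
        const int b = aff[j][k];
        llnew[b] = M.block_ll(th, M.blocks[b], e1, det, phi, gam);
        if (llnew[b] == R_NegInf) { bad = true; break; }
        lacc += llnew[b] - llc[b];
      }
      const bool accept = !bad && R_finite(lacc) &&
        (lacc >= 0.0 || std::log(unif_rand()) < lacc);
      if (accept) {
        for (size_t k = 0; k < aff[j].size(); ++k) llc[aff[j][k]] = llnew[aff[j][k]];
        acc[j] += 1.0;
      } else {
        th[j] = cur;
      }
      tries[j] += 1.0;
      if (it < n_warmup) {
        const double g = std::min(0.25, 1.0 / std::sqrt((double) it + 1.0));
        lstep[j] += g * ((accept ? 1.0 : 0.0) - 0.44);
      }
    }
    if (it >= n_warmup && ((it - n_warmup) % thin == 0)) {
      for (int j = 0; j < P; ++j) out_par(keep, j) = th[j];
      for (int k = 0; k < nt; ++k) {
        const Block& B = M.blocks[tblocks[k]];
        double psi1;
        M.block_fields(th, B, e1, det, phi, gam, psi1);
        double ll = forward_pass(e1, det, psi1, phi.data(), gam.data(), D, a1.data());
        if (ll == R_NegInf) stop("trajectory draw failed for site %d", B.site + 1);
        backward_draw(a1.data(), phi.data(), gam.data(), D, utmp.data());
        // layout: [keep, site-slot, day] with draw index fastest
        for (int d = 0; d < D; ++d)
          out_traj[keep + static_cast<R_xlen_t>(n_keep) * (k + static_cast<R_xlen_t>(nt) * d)] = utmp[d];
      }
      ++keep;
    }
  }

  NumericVector arate(P);
  for (int j = 0; j < P; ++j) arate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;
  return List::create(_["par"] = out_par, _["traj"] = out_traj,
                      _["traj_sites"] = traj_sites, _["n_keep"] = n_keep,
                      _["accept_rate"] = arate);
}
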