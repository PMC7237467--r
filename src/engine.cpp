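// Simulation core: tile coding, von Mises beliefs, the four decision models,
// and the batch/trial game loop. All randomness goes through R's global RNG
// (unif_rand / norm_rand), so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ----------------------------------------------------------------------------
// circular helpers
// ----------------------------------------------------------------------------

static inline double wrap2pi(double x) {
  double t = x / (2.0 * M_PI);
  double w = (t - std::floor(t)) * 2.0 * M_PI;
  if (w >= 2.0 * M_PI || w < 0.0) w = 0.0;  // guard rounding at the seam
  return w;
}

static inline double circDist(double a, double b) {
  double d = std::fabs(wrap2pi(a) - wrap2pi(b));
  return d > M_PI ? 2.0 * M_PI - d : d;
}

// log I0(x): exact (scaled Bessel) below the switch point, asymptotic
// e^x / sqrt(2 pi x) above. Relative error at the switch < 1e-3.
static const double BESSEL_SWITCH = 50.0;

static inline double logI0(double x) {
  if (x < BESSEL_SWITCH) return std::log(Rf_bessel_i(x, 0.0, 2.0)) + x;
  return x - 0.5 * std::log(2.0 * M_PI * x);
}

// Best-Fisher (1979) rejection sampler for the von Mises distribution.
static double rvm1(double mu, double kappa) {
  if (kappa < 1e-8) return wrap2pi(2.0 * M_PI * unif_rand());
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double u1 = unif_rand();
    double z = std::cos(M_PI * u1);
    double f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double u3 = unif_rand();
      double th = (u3 < 0.5 ? -1.0 : 1.0) * std::acos(f);
      return wrap2pi(mu + th);
    }
  }
}

// ----------------------------------------------------------------------------
// tile coding: m tilings of n tiles over [0, 2pi)
// ----------------------------------------------------------------------------

// 0-based flat indices (tiling-major) of the m active tiles for angle phi
static void tileActive(double phi, int n, int m, std::vector<int>& idx) {
  double x = wrap2pi(phi) / (2.0 * M_PI);
  idx.resize(m);
  for (int j = 1; j <= m; ++j) {
    double u = x * n - (double)j / m;
    int ii = (int)std::floor(u);
    int i0 = ((ii % n) + n) % n;
    idx[j - 1] = (j - 1) * n + i0;
  }
}

// circular mean of the centers of the active tiles
static double tilePhibar(double phi, int n, int m) {
  double x = wrap2pi(phi) / (2.0 * M_PI);
  double ss = 0.0, cc = 0.0;
  for (int j = 1; j <= m; ++j) {
    double u = x * n - (double)j / m;
    int ii = (int)std::floor(u);
    int i0 = ((ii % n) + n) % n;
    double cen = 2.0 * M_PI * ((i0 + (double)j / m + 0.5) / n);
    ss += std::sin(cen);
    cc += std::cos(cen);
  }
  return wrap2pi(std::atan2(ss, cc));
}

// ----------------------------------------------------------------------------
// von Mises belief over the hidden displacement direction
// ----------------------------------------------------------------------------

struct KappaGrid {
  std::vector<double> k, dk;
  KappaGrid() {}
  KappaGrid(int nk, double kmin, double kmax) {
    k.resize(nk);
    dk.resize(nk);
    double l0 = std::log(kmin), l1 = std::log(kmax);
    for (int g = 0; g < nk; ++g)
      k[g] = std::exp(l0 + (l1 - l0) * g / (nk - 1));
    for (int g = 0; g < nk; ++g) {
      double lo = (g == 0) ? k[0] : 0.5 * (k[g - 1] + k[g]);
      double hi = (g == nk - 1) ? k[nk - 1] : 0.5 * (k[g] + k[g + 1]);
      dk[g] = hi - lo;
    }
  }
};

struct Belief {
  double R0, Phi, c;
  std::vector<double> kcum;  // cumulative kappa-marginal weights
  std::vector<double> kw;    // normalized kappa-marginal weights

  void reset(int nk) {
    R0 = 0.0;
    Phi = NA_REAL;
    c = 0.0;
    kw.assign(nk, 0.0);
    kcum.assign(nk, 0.0);
  }

  // vector-add unit vectors of new observation angles to the resultant
  void update(const double* ang, int kcount) {
    double ss = 0.0, cc = 0.0;
    if (R0 > 0.0 && R_finite(Phi)) {
      ss = R0 * std::sin(Phi);
      cc = R0 * std::cos(Phi);
    }
    for (int j = 0; j < kcount; ++j) {
      ss += std::sin(ang[j]);
      cc += std::cos(ang[j]);
    }
    R0 = std::sqrt(ss * ss + cc * cc);
    Phi = (R0 > 1e-12) ? wrap2pi(std::atan2(ss, cc)) : NA_REAL;
    c += kcount;
  }

  // marginal over the kappa grid: w_g  prop.  dk_g I0(R0 k_g) / I0(k_g)^c
  void computeKW(const KappaGrid& G) {
    int nk = (int)G.k.size();
    kw.resize(nk);
    kcum.resize(nk);
    double mx = -1e300;
    for (int g = 0; g < nk; ++g) {
      double lw = std::log(G.dk[g]) + logI0(R0 * G.k[g]) - c * logI0(G.k[g]);
      kw[g] = lw;
      if (lw > mx) mx = lw;
    }
    double s = 0.0;
    for (int g = 0; g < nk; ++g) {
      kw[g] = std::exp(kw[g] - mx);
      s += kw[g];
    }
    double cum = 0.0;
    for (int g = 0; g < nk; ++g) {
      kw[g] /= s;
      cum += kw[g];
      kcum[g] = cum;
    }
  }

  int sampleKappaIdx() const {
    double u = unif_rand();
    int nk = (int)kcum.size();
    for (int g = 0; g < nk; ++g)
      if (u <= kcum[g]) return g;
    return nk - 1;
  }
};

// posterior marginal over nu on an even midpoint grid, numerically normalized
static void nuProfile(const Belief& B, const KappaGrid& G,
                      std::vector<double>& prof) {
  int nnu = (int)prof.size();
  double dnu = 2.0 * M_PI / nnu;
  double Phi = R_finite(B.Phi) ? B.Phi : 0.0;
  std::fill(prof.begin(), prof.end(), 0.0);
  int nk = (int)G.k.size();
  for (int g = 0; g < nk; ++g) {
    if (B.kw[g] < 1e-14) continue;
    double k = B.R0 * G.k[g];
    double lI = logI0(k);
    for (int i = 0; i < nnu; ++i) {
      double nu = (i + 0.5) * dnu;
      prof[i] += B.kw[g] * std::exp(k * std::cos(nu - Phi) - lI) / (2.0 * M_PI);
    }
  }
  double s = 0.0;
  for (int i = 0; i < nnu; ++i) s += prof[i] * dnu;
  for (int i = 0; i < nnu; ++i) prof[i] /= s;
}

// expected utility of acting: int p(nu) p(phi|f) (pi/2 - d_C(phi, nu))
static double bayesActFromProfile(const std::vector<double>& prof,
                                  double phibar, double halfwidth, int nphi) {
  int nnu = (int)prof.size();
  double dnu = 2.0 * M_PI / nnu;
  double g = 0.0;
  for (int i = 0; i < nnu; ++i) {
    double nu = (i + 0.5) * dnu;
    double acc = 0.0;
    for (int q = 0; q < nphi; ++q) {
      double phi = phibar + halfwidth * (2.0 * (q + 0.5) / nphi - 1.0);
      acc += M_PI / 2.0 - circDist(phi, nu);
    }
    g += prof[i] * dnu * (acc / nphi);
  }
  return g;
}

static double thompsonDraw(const Belief& B, const KappaGrid& G, double phibar,
                           double halfwidth) {
  int gidx = B.sampleKappaIdx();
  double kap = B.R0 * G.k[gidx];
  double Phi = R_finite(B.Phi) ? B.Phi : 0.0;
  double nu = rvm1(Phi, kap);
  double phi = phibar + halfwidth * (2.0 * unif_rand() - 1.0);
  return M_PI / 2.0 - circDist(phi, nu);
}

// ----------------------------------------------------------------------------
// SARSA(lambda) with replacing traces and the perceptron rule
// ----------------------------------------------------------------------------

// replace -> learn -> decay, on the stacked (a=0 | a=1) weight vector
static void sarsaApply(std::vector<double>& w, std::vector<double>& z,
                       const std::vector<int>& idx_t, int a_t, double r,
                       const std::vector<int>& idx_t1, int a_t1, bool terminal,
                       double alpha, double gamma, double lam, int nm) {
  int off_t = a_t ? nm : 0;
  for (size_t u = 0; u < idx_t.size(); ++u) {
    int p = off_t + idx_t[u];
    if (z[p] < 1.0) z[p] = 1.0;
  }
  double q_t = 0.0;
  for (size_t u = 0; u < idx_t.size(); ++u) q_t += w[off_t + idx_t[u]];
  double q_t1 = 0.0;
  if (!terminal) {
    int off1 = a_t1 ? nm : 0;
    for (size_t u = 0; u < idx_t1.size(); ++u) q_t1 += w[off1 + idx_t1[u]];
  }
  double ad = alpha * (r - q_t + gamma * q_t1);
  double gl = gamma * lam;
  for (size_t p = 0; p < w.size(); ++p) {
    if (z[p] != 0.0) {
      w[p] += ad * z[p];
      z[p] *= gl;
    }
  }
}

// punitive perceptron update; no-op when training signal T = 1
static void perceptronApply(std::vector<double>& w, double& b,
                            const std::vector<int>& idx, int T, double alpha,
                            bool asPrinted) {
  if (T == 1) return;
  double fac = alpha * (T - 1.0);
  if (asPrinted) {
    for (size_t p = 0; p < w.size(); ++p) w[p] += fac * w[p];
    b += fac * b;
  } else {
    for (size_t u = 0; u < idx.size(); ++u) w[idx[u]] += fac;
    b += fac;
  }
}

// ----------------------------------------------------------------------------
// trial geometry
// ----------------------------------------------------------------------------

static inline bool inBrim(double x, double y, double W, double H, double brim) {
  return x < brim * W || x > (1.0 - brim) * W || y < brim * H ||
         y > (1.0 - brim) * H;
}

static void sampleGeometry(double W, double H, double dist, double brim,
                           double& sx, double& sy, double& tx, double& ty) {
  for (int att = 0; att < 100000; ++att) {
    sx = W * unif_rand();
    sy = H * unif_rand();
    double th = 2.0 * M_PI * unif_rand();
    tx = sx + dist * std::cos(th);
    ty = sy + dist * std::sin(th);
    if (!inBrim(sx, sy, W, H, brim) && !inBrim(tx, ty, W, H, brim)) return;
  }
  stop("trial geometry rejection sampling did not terminate; check config");
}

// ----------------------------------------------------------------------------
// exported operation-level kernels
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".ng_encode_idx")]]
IntegerVector ng_encode_idx(double phi, int n, int m) {
  std::vector<int> idx;
  tileActive(phi, n, m, idx);
  IntegerVector out(m);
  for (int j = 0; j < m; ++j) out[j] = idx[j] + 1;  // 1-based for R
  return out;
}

// [[Rcpp::export(name = ".ng_phibar")]]
double ng_phibar(double phi, int n, int m) { return tilePhibar(phi, n, m); }

// [[Rcpp::export(name = ".ng_log_i0")]]
NumericVector ng_log_i0(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = logI0(x[i]);
  return out;
}

// [[Rcpp::export(name = ".ng_rvonmises")]]
NumericVector ng_rvonmises(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu, kappa);
  return out;
}

// [[Rcpp::export(name = ".ng_kappa_grid")]]
List ng_kappa_grid(int nk, double kmin, double kmax) {
  KappaGrid G(nk, kmin, kmax);
  return List::create(_["kappa"] = wrap(G.k), _["width"] = wrap(G.dk));
}

// [[Rcpp::export(name = ".ng_belief_kappa_weights")]]
NumericVector ng_belief_kappa_weights(double R0, double c, int nk, double kmin,
                                      double kmax) {
  KappaGrid G(nk, kmin, kmax);
  Belief B;
  B.reset(nk);
  B.R0 = R0;
  B.c = c;
  B.Phi = 0.0;
  B.computeKW(G);
  return wrap(B.kw);
}

// [[Rcpp::export(name = ".ng_belief_nu_profile")]]
List ng_belief_nu_profile(double R0, double Phi, double c, int nnu, int nk,
                          double kmin, double kmax) {
  KappaGrid G(nk, kmin, kmax);
  Belief B;
  B.reset(nk);
  B.R0 = R0;
  B.Phi = Phi;
  B.c = c;
  B.computeKW(G);
  std::vector<double> prof(nnu);
  nuProfile(B, G, prof);
  NumericVector nu(nnu);
  for (int i = 0; i < nnu; ++i) nu[i] = (i + 0.5) * 2.0 * M_PI / nnu;
  return List::create(_["nu"] = nu, _["density"] = wrap(prof));
}

// [[Rcpp::export(name = ".ng_bayes_activation")]]
double ng_bayes_activation(double R0, double Phi, double c, double phibar,
                           int n, int m, int nnu, int nk, double kmin,
                           double kmax, int nphi) {
  KappaGrid G(nk, kmin, kmax);
  Belief B;
  B.reset(nk);
  B.R0 = R0;
  B.Phi = Phi;
  B.c = c;
  B.computeKW(G);
  std::vector<double> prof(nnu);
  nuProfile(B, G, prof);
  double halfwidth = M_PI / (double)(n * m);
  return bayesActFromProfile(prof, phibar, halfwidth, nphi);
}

// [[Rcpp::export(name = ".ng_thompson_activation")]]
double ng_thompson_activation(double R0, double Phi, double c, double phibar,
                              int n, int m, int nk, double kmin, double kmax) {
  KappaGrid G(nk, kmin, kmax);
  Belief B;
  B.reset(nk);
  B.R0 = R0;
  B.Phi = Phi;
  B.c = c;
  B.computeKW(G);
  double halfwidth = M_PI / (double)(n * m);
  return thompsonDraw(B, G, phibar, halfwidth);
}

// [[Rcpp::export(name = ".ng_sarsa_update")]]
List ng_sarsa_update(NumericVector w, NumericVector z, IntegerVector idx_t,
                     int a_t, double r, IntegerVector idx_t1, int a_t1,
                     bool terminal, double alpha, double gamma, double lam,
                     int nm) {
  std::vector<double> wv(w.begin(), w.end());
  std::vector<double> zv(z.begin(), z.end());
  std::vector<int> i0(idx_t.size()), i1(idx_t1.size());
  for (R_xlen_t u = 0; u < idx_t.size(); ++u) i0[u] = idx_t[u] - 1;
  for (R_xlen_t u = 0; u < idx_t1.size(); ++u) i1[u] = idx_t1[u] - 1;
  sarsaApply(wv, zv, i0, a_t, r, i1, a_t1, terminal, alpha, gamma, lam, nm);
  return List::create(_["w"] = wrap(wv), _["z"] = wrap(zv));
}

// [[Rcpp::export(name = ".ng_perceptron_update")]]
List ng_perceptron_update(NumericVector w, double b, IntegerVector idx, int T,
                          double alpha, bool as_printed) {
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> i0(idx.size());
  for (R_xlen_t u = 0; u < idx.size(); ++u) i0[u] = idx[u] - 1;
  perceptronApply(wv, b, i0, T, alpha, as_printed);
  return List::create(_["w"] = wrap(wv), _["b"] = b);
}

// Event synchronization (adaptive coincidence window of half the minimum
// surrounding inter-spike interval; missing boundary intervals count as +Inf).
// [[Rcpp::export(name = ".ng_event_sync")]]
double ng_event_sync(NumericVector ti, NumericVector tj) {
  int mi = ti.size(), mj = tj.size();
  if (mi < 1 || mj < 1) stop("event synchronization needs non-empty trains");
  double total = 0.0;
  for (int k = 0; k < mi; ++k) {
    double ip = (k > 0) ? ti[k] - ti[k - 1] : R_PosInf;
    double in = (k < mi - 1) ? ti[k + 1] - ti[k] : R_PosInf;
    for (int l = 0; l < mj; ++l) {
      double jp = (l > 0) ? tj[l] - tj[l - 1] : R_PosInf;
      double jn = (l < mj - 1) ? tj[l + 1] - tj[l] : R_PosInf;
      double tau = 0.5 * std::min(std::min(ip, in), std::min(jp, jn));
      double diff = ti[k] - tj[l];
      if (diff == 0.0)
        total += 1.0;  // J_{k,l} + J_{l,k} = 1/2 + 1/2
      else if (std::fabs(diff) <= tau)
        total += 1.0;  // one direction contributes 1
    }
  }
  return total / std::sqrt((double)mi * (double)mj);
}

// [[Rcpp::export(name = ".ng_sample_geometry")]]
NumericVector ng_sample_geometry(double W, double H, double dist, double brim) {
  double sx, sy, tx, ty;
  sampleGeometry(W, H, dist, brim, sx, sy, tx, ty);
  return NumericVector::create(sx, sy, tx, ty);
}

// ----------------------------------------------------------------------------
// the game loop: one batch of trials with persistent unit learning state
// ----------------------------------------------------------------------------

enum ModelId { SCRIPTED = 0, BAYES = 1, THOMPSON = 2, RL = 3, ANN = 4 };

// [[Rcpp::export(name = ".ng_run_batch")]]
List ng_run_batch(int model, List cfg, List par, NumericVector mu) {
  const double W = cfg["screen_width"], H = cfg["screen_height"];
  const double step = cfg["step_length"], dist = cfg["target_distance"];
  const double brim = cfg["brim_fraction"], radius = cfg["target_radius"];
  const int np = cfg["n_players"];
  const int ntrials = cfg["trials_per_batch"];
  const int maxSteps = cfg["max_steps_per_trial"];

  const double beta1 = par["beta1"], beta2 = par["beta2"], beta3 = par["beta3"];
  const double gain = par["gain"], q = par["q"], epsBase = par["epsilon_base"];
  const int n = par["n_tiles"], m = par["n_tilings"];
  const int nm = n * m;
  const int nnu = par["nu_grid"], nk = par["kappa_grid_size"];
  const double kmin = par["kappa_min"], kmax = par["kappa_max"];
  const int nphi = par["phi_quadrature"];
  const double alpha = par["alpha"], gamma = par["gamma"], lam = par["lambda"];
  const bool asPrinted = par["as_printed"];

  if ((int)mu.size() != np) stop("mu must have n_players entries");

  KappaGrid G;
  std::vector<Belief> beliefs;
  std::vector<std::vector<double> > profiles;  // Bayes nu-profiles
  std::vector<std::vector<double> > rlw, rlz;
  std::vector<std::vector<double> > annw;
  std::vector<double> annb;
  if (model == BAYES || model == THOMPSON) {
    G = KappaGrid(nk, kmin, kmax);
    beliefs.resize(np);
    for (int i = 0; i < np; ++i) {
      beliefs[i].reset(nk);
      beliefs[i].computeKW(G);
    }
    if (model == BAYES) {
      profiles.assign(np, std::vector<double>(nnu));
      for (int i = 0; i < np; ++i) nuProfile(beliefs[i], G, profiles[i]);
    }
  } else if (model == RL) {
    rlw.assign(np, std::vector<double>(2 * nm, 0.0));
    rlz.assign(np, std::vector<double>(2 * nm, 0.0));
  } else if (model == ANN) {
    annw.assign(np, std::vector<double>(nm, 0.0));
    annb.assign(np, 0.0);
  }

  std::vector<double> spikes(np, 0.0);  // spike counts (drive epsilon decay)
  const double halfwidth = M_PI / (double)nm;

  // growing per-step records
  std::vector<int> recA;
  std::vector<double> recX, recY, recXn, recYn;
  std::vector<int> recTrial;
  // per-trial records
  std::vector<double> trStartX, trStartY, trTargX, trTargY;
  std::vector<int> trSteps, trReached;

  // SARSA pending transition per unit
  std::vector<int> pend(np, 0);
  std::vector<std::vector<int> > pendIdx(np);
  std::vector<double> pendR(np, 0.0);

  std::vector<int> a(np, 0);
  std::vector<std::vector<int> > idxNow(np);
  std::vector<double> phibarNow(np, 0.0);
  std::vector<int> scratchIdx;

  for (int trial = 0; trial < ntrials; ++trial) {
    double sx, sy, tx, ty;
    sampleGeometry(W, H, dist, brim, sx, sy, tx, ty);
    trStartX.push_back(sx);
    trStartY.push_back(sy);
    trTargX.push_back(tx);
    trTargY.push_back(ty);

    // episodic traces and no cross-trial bootstrap
    if (model == RL) {
      for (int i = 0; i < np; ++i) {
        std::fill(rlz[i].begin(), rlz[i].end(), 0.0);
        pend[i] = 0;
      }
    }

    double x = sx, y = sy;
    int nstep = 0;
    bool reached = false;

    while (nstep < maxSteps) {
      double d0 = std::hypot(tx - x, ty - y);
      if (d0 <= radius) {
        reached = true;
        break;
      }
      double psi = wrap2pi(std::atan2(ty - y, tx - x));

      // --- decisions ---
      for (int i = 0; i < np; ++i) {
        if (model == SCRIPTED) {
          a[i] = (circDist(psi, mu[i]) < M_PI / 2.0) ? 1 : 0;
          continue;
        }
        double phi = wrap2pi(psi + norm_rand() * std::sqrt(beta3));
        double g = 0.0;
        if (model == BAYES) {
          phibarNow[i] = tilePhibar(phi, n, m);
          g = bayesActFromProfile(profiles[i], phibarNow[i], halfwidth, nphi);
        } else if (model == THOMPSON) {
          phibarNow[i] = tilePhibar(phi, n, m);
          g = thompsonDraw(beliefs[i], G, phibarNow[i], halfwidth);
        } else if (model == RL) {
          tileActive(phi, n, m, idxNow[i]);
          double q1 = 0.0, q0 = 0.0;
          for (size_t u = 0; u < idxNow[i].size(); ++u) {
            q0 += rlw[i][idxNow[i][u]];
            q1 += rlw[i][nm + idxNow[i][u]];
          }
          g = q1 - q0;
        } else {  // ANN
          tileActive(phi, n, m, idxNow[i]);
          g = annb[i];
          for (size_t u = 0; u < idxNow[i].size(); ++u)
            g += annw[i][idxNow[i][u]];
        }
        double eps = std::pow(epsBase, spikes[i]);
        if (eps < beta2) eps = beta2;
        double sig = std::atan(gain * g) / M_PI + 0.5;
        double p = (1.0 - q) * (0.5 * eps + (1.0 - eps) * sig);
        a[i] = (unif_rand() < p) ? 1 : 0;
      }

      // --- pending SARSA updates use the state/action just chosen ---
      if (model == RL) {
        for (int i = 0; i < np; ++i) {
          if (pend[i]) {
            if (beta1 >= 1.0 || unif_rand() < beta1)
              sarsaApply(rlw[i], rlz[i], pendIdx[i], 1, pendR[i], idxNow[i],
                         a[i], false, alpha, gamma, lam, nm);
            pend[i] = 0;
          }
        }
      }

      // --- group displacement ---
      double dx = 0.0, dy = 0.0;
      int nact = 0;
      for (int i = 0; i < np; ++i) {
        if (a[i]) {
          dx += step * std::cos(mu[i]);
          dy += step * std::sin(mu[i]);
          ++nact;
        }
      }
      double xn = x + dx, yn = y + dy;
      double d1 = std::hypot(tx - xn, ty - yn);
      double rsign = (d0 > d1) ? 1.0 : ((d0 < d1) ? -1.0 : 0.0);

      // --- record ---
      for (int i = 0; i < np; ++i) recA.push_back(a[i]);
      recX.push_back(x);
      recY.push_back(y);
      recXn.push_back(xn);
      recYn.push_back(yn);
      recTrial.push_back(trial + 1);

      // --- learning ---
      if (model == BAYES || model == THOMPSON) {
        double dlen = std::hypot(dx, dy);
        if (dlen > 1e-12) {
          double ang = wrap2pi(std::atan2(dy, dx));
          for (int i = 0; i < np; ++i) {
            if (a[i] && (beta1 >= 1.0 || unif_rand() < beta1)) {
              beliefs[i].update(&ang, 1);
              beliefs[i].computeKW(G);
              if (model == BAYES) nuProfile(beliefs[i], G, profiles[i]);
            }
          }
        }
      } else if (model == RL) {
        for (int i = 0; i < np; ++i) {
          if (a[i]) {
            pend[i] = 1;
            pendIdx[i] = idxNow[i];
            pendR[i] = rsign;
          }
        }
      } else if (model == ANN) {
        int T = (rsign > 0.0) ? 1 : 0;
        for (int i = 0; i < np; ++i) {
          if (a[i] && (beta1 >= 1.0 || unif_rand() < beta1))
            perceptronApply(annw[i], annb[i], idxNow[i], T, alpha, asPrinted);
        }
      }

      for (int i = 0; i < np; ++i) spikes[i] += a[i];
      x = xn;
      y = yn;
      ++nstep;
      if (std::hypot(tx - x, ty - y) <= radius) {
        reached = true;
        break;
      }
    }

    // terminal flush of pending transitions (no bootstrap)
    if (model == RL) {
      for (int i = 0; i < np; ++i) {
        if (pend[i]) {
          if (beta1 >= 1.0 || unif_rand() < beta1)
            sarsaApply(rlw[i], rlz[i], pendIdx[i], 1, pendR[i], pendIdx[i], 0,
                       true, alpha, gamma, lam, nm);
          pend[i] = 0;
        }
      }
    }

    trSteps.push_back(nstep);
    trReached.push_back(reached ? 1 : 0);
  }

  int N = (int)recTrial.size();
  IntegerMatrix A(N, np);
  for (int t = 0; t < N; ++t)
    for (int i = 0; i < np; ++i) A(t, i) = recA[(size_t)t * np + i];
  NumericMatrix S(N, 2), Sn(N, 2);
  for (int t = 0; t < N; ++t) {
    S(t, 0) = recX[t];
    S(t, 1) = recY[t];
    Sn(t, 0) = recXn[t];
    Sn(t, 1) = recYn[t];
  }

  List units(np);
  for (int i = 0; i < np; ++i) {
    if (model == BAYES || model == THOMPSON) {
      units[i] = List::create(_["R0"] = beliefs[i].R0, _["Phi"] = beliefs[i].Phi,
                              _["c"] = beliefs[i].c);
    } else if (model == RL) {
      units[i] = List::create(_["w"] = wrap(rlw[i]), _["z"] = wrap(rlz[i]));
    } else if (model == ANN) {
      units[i] = List::create(_["w"] = wrap(annw[i]), _["b"] = annb[i]);
    } else {
      units[i] = List::create(_["scripted"] = true);
    }
  }

  return List::create(
      _["actions"] = A, _["pos"] = S, _["pos_next"] = Sn,
      _["trial"] = wrap(recTrial),
      _["trials"] = DataFrame::create(
          _["start_x"] = wrap(trStartX), _["start_y"] = wrap(trStartY),
          _["target_x"] = wrap(trTargX), _["target_y"] = wrap(trTargY),
          _["steps"] = wrap(trSteps), _["reached"] = wrap(trReached)),
      _["spikes"] = wrap(spikes), _["units"] = units);
}
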