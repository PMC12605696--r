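// Piecewise-analytic one-compartment engine and Laplace marginal likelihood.
//
// The structural model is a one-compartment disposition with first-order
// absorption (gut depot) and first-order elimination; clearance is piecewise
// constant across occasions.  Between events the system is linear with
// constant coefficients, so the state (A_gut, A_central) is propagated
// exactly segment by segment; segments break at dose times, infusion ends,
// occasion boundaries and requested output times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TEQ = 1e-9;  // time comparison tolerance (h)

// Exact propagation of (Ag, Ac) over dt with constant ka, ke and zero-order
// input rate R into the central compartment.
static inline void propagate(double &Ag, double &Ac, double dt,
                             double ka, double ke, double R) {
  if (dt <= 0.0) return;
  double eg = std::exp(-ka * dt);
  if (ke > 1e-12) {
    double ec = std::exp(-ke * dt);
    double absorb;
    if (std::fabs(ka - ke) > 1e-8 * ka)
      absorb = Ag * ka / (ka - ke) * (ec - eg);
    else
      absorb = Ag * ka * dt * ec;  // ka -> ke limit
    Ac = Ac * ec + absorb + R / ke * (1.0 - ec);
  } else {
    Ac = Ac + Ag * (1.0 - eg) + R * dt;  // no elimination
  }
  Ag *= eg;
}

// Concentration at obs_t for one individual.  CL_occ holds clearance per
// occasion; occ_b (sorted, length n_occ - 1) are the boundary times: the
// k-th occasion is active on (occ_b[k-2], occ_b[k-1]] (1-based), i.e. an
// observation falling exactly on a boundary still belongs to the ending
// occasion (pre-switch), matching the TDM-interval occasion definition.
// Outputs at a time where a dose is also scheduled are evaluated pre-dose.
static arma::vec profile_eval(double V, const arma::vec &CL_occ,
                              const arma::vec &occ_b, double ka, double F,
                              const arma::vec &d_time, const arma::vec &d_amt,
                              const arma::ivec &d_oral, const arma::vec &d_dur,
                              const arma::vec &obs_t) {
  const int nd = d_time.n_elem, nobs = obs_t.n_elem;
  arma::vec out(nobs, arma::fill::zeros);
  if (nobs == 0) return out;

  // breakpoints: dose starts, infusion ends, occasion bounds, output times
  std::vector<double> bp;
  bp.reserve(2 * nd + occ_b.n_elem + nobs);
  for (int i = 0; i < nd; ++i) {
    bp.push_back(d_time[i]);
    if (!d_oral[i]) bp.push_back(d_time[i] + d_dur[i]);
  }
  for (arma::uword i = 0; i < occ_b.n_elem; ++i) bp.push_back(occ_b[i]);
  for (int i = 0; i < nobs; ++i) bp.push_back(obs_t[i]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::fabs(a - b) < TEQ; }),
           bp.end());

  double t = 0.0, Ag = 0.0, Ac = 0.0;
  int iobs = 0;
  // outputs at (or before) t = 0: nothing in the system yet
  while (iobs < nobs && obs_t[iobs] <= TEQ) out[iobs++] = 0.0;
  // doses scheduled at t = 0 (oral bolus into depot)
  for (int i = 0; i < nd; ++i)
    if (d_oral[i] && std::fabs(d_time[i]) < TEQ) Ag += F * d_amt[i];

  for (size_t s = 0; s < bp.size(); ++s) {
    double t1 = bp[s];
    if (t1 <= t + TEQ) continue;
    // occasion active on the segment ending at t1: count bounds strictly < t1
    int occ = 0;
    for (arma::uword k = 0; k < occ_b.n_elem; ++k)
      if (occ_b[k] < t1 - TEQ) ++occ;
    if (occ >= (int)CL_occ.n_elem) occ = CL_occ.n_elem - 1;
    double ke = CL_occ[occ] / V;
    // infusion rate active over the whole segment
    double R = 0.0;
    for (int i = 0; i < nd; ++i)
      if (!d_oral[i] && d_time[i] <= t + TEQ && d_time[i] + d_dur[i] >= t1 - TEQ)
        R += d_amt[i] / d_dur[i];
    propagate(Ag, Ac, t1 - t, ka, ke, R);
    t = t1;
    while (iobs < nobs && obs_t[iobs] <= t + TEQ) out[iobs++] = Ac / V;
    if (iobs == nobs) break;
    for (int i = 0; i < nd; ++i)
      if (d_oral[i] && std::fabs(d_time[i] - t) < TEQ) Ag += F * d_amt[i];
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_profile(double V, const arma::vec &CL_occ, const arma::vec &occ_b,
                      double ka, double F, const arma::vec &d_time,
                      const arma::vec &d_amt, const arma::ivec &d_oral,
                      const arma::vec &d_dur, const arma::vec &obs_t) {
  return profile_eval(V, CL_occ, occ_b, ka, F, d_time, d_amt, d_oral, d_dur,
                      obs_t);
}

// Population simulation: one row per simulated individual (Vs[i], CL_mat row)
// under a shared regimen and shared occasion grid.
// [[Rcpp::export]]
arma::mat cpp_profile_multi(const arma::vec &Vs, const arma::mat &CL_mat,
                            const arma::vec &occ_b, double ka, double F,
                            const arma::vec &d_time, const arma::vec &d_amt,
                            const arma::ivec &d_oral, const arma::vec &d_dur,
                            const arma::vec &obs_t) {
  const arma::uword n = Vs.n_elem;
  arma::mat out(n, obs_t.n_elem);
  for (arma::uword i = 0; i < n; ++i)
    out.row(i) = profile_eval(Vs[i], CL_mat.row(i).t(), occ_b, ka, F, d_time,
                              d_amt, d_oral, d_dur, obs_t).t();
  return out;
}

// -2 log conditional likelihood under proportional residual error
// y = c * (1 + eps), eps ~ N(0, sigma^2).
static double cond_neg2ll(double V, const arma::vec &CL_occ,
                          const arma::vec &occ_b, double ka, double F,
                          double sigma, const arma::vec &d_time,
                          const arma::vec &d_amt, const arma::ivec &d_oral,
                          const arma::vec &d_dur, const arma::vec &obs_t,
                          const arma::vec &obs_y) {
  arma::vec c = profile_eval(V, CL_occ, occ_b, ka, F, d_time, d_amt, d_oral,
                             d_dur, obs_t);
  double ll = 0.0;
  for (arma::uword j = 0; j < c.n_elem; ++j) {
    if (!(c[j] > 1e-12) || !std::isfinite(c[j])) return 1e10;
    double sd = sigma * c[j];
    double r = (obs_y[j] - c[j]) / sd;
    ll += std::log(2.0 * M_PI * sd * sd) + r * r;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_cond_neg2ll(double V, const arma::vec &CL_occ, const arma::vec &occ_b,
                       double ka, double F, double sigma,
                       const arma::vec &d_time, const arma::vec &d_amt,
                       const arma::ivec &d_oral, const arma::vec &d_dur,
                       const arma::vec &obs_t, const arma::vec &obs_y) {
  return cond_neg2ll(V, CL_occ, occ_b, ka, F, sigma, d_time, d_amt, d_oral,
                     d_dur, obs_t, obs_y);
}

// ---- Laplace machinery ----------------------------------------------------

struct PatientData {
  arma::vec d_time, d_amt, d_dur, occ_b, obs_t, obs_y;
  arma::ivec d_oral;
  int n_occ;
  double Vtyp, CLtyp;
};

// Precompiled propagation plan for one patient: the segment structure
// (breakpoints, infusion rates, occasion indices, oral depot additions,
// observation attachment) depends only on the event schedule, not on the
// parameters, so it is built once per likelihood call and reused across
// every inner-objective evaluation.
struct Segment {
  double dt, R, ega, oral_amt;  // ega = exp(-ka*dt), oral_amt added post-segment
  int occ;
  std::vector<int> obs_idx;     // observations recorded at segment end (pre-dose)
};

struct Plan {
  std::vector<Segment> segs;
  std::vector<int> obs_at_zero;  // observations at t <= 0: concentration 0
  int n_obs;
};

static Plan build_plan(const PatientData &p, double ka) {
  Plan plan;
  plan.n_obs = p.obs_t.n_elem;
  const int nd = p.d_time.n_elem, nobs = p.obs_t.n_elem;
  std::vector<double> bp;
  bp.reserve(2 * nd + p.occ_b.n_elem + nobs);
  for (int i = 0; i < nd; ++i) {
    bp.push_back(p.d_time[i]);
    if (!p.d_oral[i]) bp.push_back(p.d_time[i] + p.d_dur[i]);
  }
  for (arma::uword i = 0; i < p.occ_b.n_elem; ++i) bp.push_back(p.occ_b[i]);
  for (int i = 0; i < nobs; ++i) bp.push_back(p.obs_t[i]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::fabs(a - b) < TEQ; }),
           bp.end());
  double t = 0.0;
  int iobs = 0;
  while (iobs < nobs && p.obs_t[iobs] <= TEQ) plan.obs_at_zero.push_back(iobs++);
  double oral0 = 0.0;
  for (int i = 0; i < nd; ++i)
    if (p.d_oral[i] && std::fabs(p.d_time[i]) < TEQ) oral0 += p.d_amt[i];
  if (oral0 > 0.0) {
    Segment s0; s0.dt = 0.0; s0.R = 0.0; s0.ega = 1.0; s0.occ = 0;
    s0.oral_amt = oral0;
    plan.segs.push_back(s0);
  }
  for (size_t k = 0; k < bp.size(); ++k) {
    double t1 = bp[k];
    if (t1 <= t + TEQ) continue;
    Segment s;
    s.dt = t1 - t;
    s.ega = std::exp(-ka * s.dt);
    int occ = 0;
    for (arma::uword j = 0; j < p.occ_b.n_elem; ++j)
      if (p.occ_b[j] < t1 - TEQ) ++occ;
    if (occ >= p.n_occ) occ = p.n_occ - 1;
    s.occ = occ;
    s.R = 0.0;
    for (int i = 0; i < nd; ++i)
      if (!p.d_oral[i] && p.d_time[i] <= t + TEQ &&
          p.d_time[i] + p.d_dur[i] >= t1 - TEQ)
        s.R += p.d_amt[i] / p.d_dur[i];
    t = t1;
    while (iobs < nobs && p.obs_t[iobs] <= t + TEQ) s.obs_idx.push_back(iobs++);
    s.oral_amt = 0.0;
    for (int i = 0; i < nd; ++i)
      if (p.d_oral[i] && std::fabs(p.d_time[i] - t) < TEQ)
        s.oral_amt += p.d_amt[i];
    plan.segs.push_back(s);
    if (iobs == nobs) break;
  }
  return plan;
}

// Fast conditional -2 log-likelihood using a precompiled plan.
static double plan_neg2ll(const Plan &plan, double V, const arma::vec &CL_occ,
                          double ka, double F, double sigma,
                          const arma::vec &obs_y) {
  if (!plan.obs_at_zero.empty()) return 1e10;  // observation with no drug
  double Ag = 0.0, Ac = 0.0, ll = 0.0;
  for (const Segment &s : plan.segs) {
    if (s.dt > 0.0) {
      double ke = CL_occ[s.occ] / V;
      double eg = s.ega;
      if (ke > 1e-12) {
        double ec = std::exp(-ke * s.dt);
        double absorb;
        if (std::fabs(ka - ke) > 1e-8 * ka)
          absorb = Ag * ka / (ka - ke) * (ec - eg);
        else
          absorb = Ag * ka * s.dt * ec;
        Ac = Ac * ec + absorb + s.R / ke * (1.0 - ec);
      } else {
        Ac = Ac + Ag * (1.0 - eg) + s.R * s.dt;
      }
      Ag *= eg;
    }
    for (int j : s.obs_idx) {
      double c = Ac / V;
      if (!(c > 1e-12) || !std::isfinite(c)) return 1e10;
      double sd = sigma * c;
      double r = (obs_y[j] - c) / sd;
      ll += std::log(2.0 * M_PI * sd * sd) + r * r;
    }
    if (s.oral_amt > 0.0) Ag += F * s.oral_amt;
  }
  return ll;
}

struct REStructure {
  bool useV, useCL, useK;
  int n_occ, d;
  arma::vec var;  // prior variances, length d
};

// Inner problem context: precompiled plan plus random-effect structure.
struct InnerCtx {
  const Plan *plan;
  const PatientData *p;
  const REStructure *s;
  double ka, F, sigma;
  mutable arma::vec CL_work;  // per-occasion clearance workspace
};

// Penalized -2 log joint: conditional -2LL plus Gaussian prior terms.
static double pen_obj(const arma::vec &b, const InnerCtx &c) {
  const REStructure &s = *c.s;
  const PatientData &p = *c.p;
  int idx = 0;
  double etaV = s.useV ? b[idx++] : 0.0;
  double etaCL = s.useCL ? b[idx++] : 0.0;
  for (int k = 0; k < p.n_occ; ++k) {
    double kap = s.useK ? b[idx + k] : 0.0;
    c.CL_work[k] = p.CLtyp * std::exp(etaCL + kap);
  }
  double V = p.Vtyp * std::exp(etaV);
  double f = plan_neg2ll(*c.plan, V, c.CL_work, c.ka, c.F, c.sigma, p.obs_y);
  for (int k = 0; k < s.d; ++k)
    f += b[k] * b[k] / s.var[k] + std::log(2.0 * M_PI * s.var[k]);
  return f;
}

static arma::vec num_grad(const arma::vec &b, const InnerCtx &c,
                          double h = 1e-4) {
  const int d = c.s->d;
  arma::vec g(d);
  arma::vec bb = b;
  for (int i = 0; i < d; ++i) {
    bb[i] = b[i] + h;
    double fp = pen_obj(bb, c);
    bb[i] = b[i] - h;
    double fm = pen_obj(bb, c);
    bb[i] = b[i];
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}

static arma::mat num_hess(const arma::vec &b, const InnerCtx &c,
                          double h = 1e-3) {
  const int d = c.s->d;
  arma::mat H(d, d);
  double f0 = pen_obj(b, c);
  arma::vec fpp(d);
  arma::vec bb = b;
  for (int i = 0; i < d; ++i) {
    bb[i] = b[i] + h; fpp[i] = pen_obj(bb, c);
    bb[i] = b[i] - h; double fm = pen_obj(bb, c);
    bb[i] = b[i];
    H(i, i) = (fpp[i] - 2.0 * f0 + fm) / (h * h);
  }
  for (int i = 0; i < d; ++i)
    for (int j = i + 1; j < d; ++j) {
      bb[i] = b[i] + h; bb[j] = b[j] + h;
      double fij = pen_obj(bb, c);
      bb[i] = b[i]; bb[j] = b[j];
      H(i, j) = H(j, i) = (fij - fpp[i] - fpp[j] + f0) / (h * h);
    }
  return H;
}

// Damped Newton minimization of the penalized objective.
static double inner_newton(arma::vec &b, const InnerCtx &c,
                           int max_iter = 60) {
  double f = pen_obj(b, c);
  if (f >= 1e9) { b.zeros(); f = pen_obj(b, c); }
  for (int it = 0; it < max_iter; ++it) {
    arma::vec g = num_grad(b, c);
    if (arma::norm(g, "inf") < 1e-6 * (1.0 + std::fabs(f))) break;
    arma::mat H = num_hess(b, c);
    arma::vec step;
    double lam = 0.0;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat Hl = H;
      if (lam > 0.0) Hl.diag() += lam;
      if (arma::solve(step, Hl, -g, arma::solve_opts::no_approx)) {
        if (arma::dot(step, g) < 0.0) break;  // descent direction
      }
      lam = (lam == 0.0) ? 1e-3 : lam * 10.0;
      step.reset();
    }
    if (step.n_elem == 0) step = -g;  // fall back to gradient descent
    double alpha = 1.0, fnew = 0.0;
    bool ok = false;
    for (int ls = 0; ls < 25; ++ls) {
      fnew = pen_obj(b + alpha * step, c);
      if (fnew < f - 1e-12) { ok = true; break; }
      alpha *= 0.5;
    }
    if (!ok) break;
    b += alpha * step;
    if (std::fabs(f - fnew) < 1e-9 * (1.0 + std::fabs(f))) { f = fnew; break; }
    f = fnew;
  }
  return f;
}

// Portable deterministic RNG (xorshift64*) with Box-Muller normals, so the
// importance-sampling nodes are bit-reproducible across platforms and
// identical between calls (common random numbers: the marginal-likelihood
// estimate is a smooth deterministic function of the parameters).
struct PortableRng {
  uint64_t s;
  explicit PortableRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t x = s * 0x2545F4914F6CDD1DULL;
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// Importance-sampled -2 log marginal likelihood for one patient, using a
// Gaussian proposal centered at the posterior mode with covariance
// scale^2 * (H/2)^-1 and antithetic common random numbers. Returns the
// Laplace value if the Hessian factorization fails.
static double is_ofv_patient(const arma::vec &bhat, const arma::mat &H,
                             double laplace_val, const InnerCtx &c,
                             int n_pairs, double scale, uint64_t seed) {
  const int d = bhat.n_elem;
  arma::mat R;
  if (!arma::chol(R, arma::symmatu(H) / 2.0)) return laplace_val;
  // b = bhat + scale * R^-1 z ; log q(b) = const - d log(scale)
  //   + log det R - z'z/2
  double logdetR = arma::sum(arma::log(R.diag()));
  PortableRng rng(seed);
  std::vector<double> logw;
  logw.reserve(2 * n_pairs);
  arma::vec z(d), step(d), b(d);
  for (int j = 0; j < n_pairs; ++j) {
    for (int k = 0; k < d; ++k) z[k] = rng.norm();
    step = scale * arma::solve(arma::trimatu(R), z);
    double lq_quad = -0.5 * arma::dot(z, z);
    for (int sgn = 0; sgn < 2; ++sgn) {
      if (sgn) b = bhat - step; else b = bhat + step;
      double f = pen_obj(b, c);
      double lq = -0.5 * d * std::log(2.0 * M_PI) - d * std::log(scale) +
                  logdetR + lq_quad;
      logw.push_back(-0.5 * f - lq);
    }
  }
  double mx = *std::max_element(logw.begin(), logw.end());
  double acc = 0.0;
  for (double w : logw) acc += std::exp(w - mx);
  return -2.0 * (mx + std::log(acc / logw.size()));
}

// Log-determinant of a (near-)positive-definite matrix, ridged if needed.
static double safe_logdet(const arma::mat &H) {
  arma::mat M = arma::symmatu(H);
  double ridge = 0.0;
  for (int tries = 0; tries < 12; ++tries) {
    arma::mat L;
    arma::mat Mr = M;
    if (ridge > 0.0) Mr.diag() += ridge;
    if (arma::chol(L, Mr)) return 2.0 * arma::sum(arma::log(L.diag()));
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
  }
  return 0.0;
}

// Stable patient key for per-patient random streams: estimation results are
// then invariant to the ordering of patients in the dataset.
static uint64_t pat_id(const List &pl) {
  if (pl.containsElementNamed("id"))
    return (uint64_t)std::llround(as<double>(pl["id"]));
  return 0;
}

static PatientData unpack_patient(const List &pl, double Vtyp, double CLtyp) {
  PatientData p;
  p.d_time = as<arma::vec>(pl["d_time"]);
  p.d_amt  = as<arma::vec>(pl["d_amt"]);
  p.d_oral = as<arma::ivec>(pl["d_oral"]);
  p.d_dur  = as<arma::vec>(pl["d_dur"]);
  p.occ_b  = as<arma::vec>(pl["occ_b"]);
  p.obs_t  = as<arma::vec>(pl["obs_t"]);
  p.obs_y  = as<arma::vec>(pl["obs_y"]);
  p.n_occ  = as<int>(pl["n_occ"]);
  p.Vtyp = Vtyp; p.CLtyp = CLtyp;
  return p;
}

static REStructure re_structure(double omegaV, double omegaCL, double gamma,
                                int n_occ) {
  REStructure s;
  s.useV = omegaV > 1e-8;
  s.useCL = omegaCL > 1e-8;
  s.useK = gamma > 1e-8;
  s.n_occ = n_occ;
  s.d = (s.useV ? 1 : 0) + (s.useCL ? 1 : 0) + (s.useK ? n_occ : 0);
  s.var.set_size(s.d);
  int idx = 0;
  if (s.useV) s.var[idx++] = omegaV * omegaV;
  if (s.useCL) s.var[idx++] = omegaCL * omegaCL;
  if (s.useK) for (int k = 0; k < n_occ; ++k) s.var[idx + k] = gamma * gamma;
  return s;
}

// -2 log marginal likelihood over the whole dataset. The mode of each
// patient's penalized objective is found by damped Newton; with n_is = 0
// the Laplace approximation is returned, otherwise the integral is
// estimated by antithetic importance sampling (2*n_is nodes per patient)
// from a Gaussian proposal at the mode — deterministic given is_seed.
// `patients` is a list of per-patient event lists (see unpack_patient);
// Vtyp/CLtyp carry the covariate-scaled typical values per patient.
// `warm` optionally holds per-patient starting modes from a previous call.
// [[Rcpp::export]]
List cpp_laplace_ofv(const List &patients, const arma::vec &Vtyp,
                     const arma::vec &CLtyp, double F, double ka,
                     double omegaV, double omegaCL, double gamma, double sigma,
                     Nullable<List> warm = R_NilValue, bool return_ebe = false,
                     int n_is = 0, double is_scale = 1.3, int is_seed = 1) {
  const int n = patients.size();
  double ofv = 0.0;
  List ebe(n);
  List warm_list;
  bool has_warm = warm.isNotNull();
  if (has_warm) warm_list = warm.get();
  for (int i = 0; i < n; ++i) {
    List pl = patients[i];
    PatientData p = unpack_patient(pl, Vtyp[i], CLtyp[i]);
    REStructure s = re_structure(omegaV, omegaCL, gamma, p.n_occ);
    Plan plan = build_plan(p, ka);
    InnerCtx ctx{&plan, &p, &s, ka, F, sigma, arma::vec(p.n_occ)};
    if (s.d == 0) {
      ofv += pen_obj(arma::vec(), ctx);
      if (return_ebe) ebe[i] = NumericVector(0);
      continue;
    }
    arma::vec b(s.d, arma::fill::zeros);
    if (has_warm) {
      arma::vec w = as<arma::vec>(warm_list[i]);
      if ((int)w.n_elem == s.d) b = w;
    }
    double fhat = inner_newton(b, ctx);
    arma::mat H = num_hess(b, ctx);
    double ld = safe_logdet(H) - s.d * std::log(2.0);
    double ofv_i = fhat - s.d * std::log(2.0 * M_PI) + ld;
    if (n_is > 0)
      ofv_i = is_ofv_patient(b, H, ofv_i, ctx, n_is, is_scale,
                             0x5DEECE66DULL * (pat_id(pl) + 1) +
                                 (uint64_t)is_seed);
    ofv += ofv_i;
    ebe[i] = wrap(b);
  }
  return List::create(_["ofv"] = ofv, _["ebe"] = ebe);
}

// ---- SAEM ------------------------------------------------------------------
//
// Stochastic approximation EM in individual log-parameter space:
//   phi_V,i  = oV_i  + xV_i'bV  + eta_V,i,   eta_V  ~ N(0, omega_V^2)
//   phi_CL,i = oCL_i + xCL_i'bCL + eta_CL,i, eta_CL ~ N(0, omega_CL^2)
//   log CL on occasion k adds kappa_ik ~ N(0, gamma^2)
// The E-step samples (phi_V, phi_CL, kappa) per patient by adaptive
// componentwise random-walk Metropolis; the M-step is closed form for the
// covariate coefficients and variance components (linear models in log
// space) and a 1-D Brent step for F, using the linearity of the profile in
// the oral dose amounts: c_j(F) = a_j + F * b_j.

struct SaemPatient {
  PatientData p;
  Plan plan;
  arma::vec xV, xCL;   // free regressors (may be empty)
  double oV, oCL;      // fixed offsets in the log-scale means
  arma::vec a, bF;     // iv-only and unit-F oral profile components at obs
  double phiV, phiCL;
  arma::vec kappa;
  arma::vec CL_work;
};

static double saem_neg2ll(SaemPatient &sp, double ka, double F, double sigma) {
  double V = std::exp(sp.phiV);
  for (int k = 0; k < sp.p.n_occ; ++k)
    sp.CL_work[k] = std::exp(sp.phiCL + (sp.kappa.n_elem ? sp.kappa[k] : 0.0));
  return plan_neg2ll(sp.plan, V, sp.CL_work, ka, F, sigma, sp.p.obs_y);
}

// [[Rcpp::export]]
List cpp_saem(const List &patients, const List &xV_list, const List &xCL_list,
              const arma::vec &oV, const arma::vec &oCL, double ka,
              const arma::vec &init,   // bV..., bCL..., omegaV, omegaCL, gamma, sigma, F
              int nV, int nCL,         // number of free regressors per block
              bool est_omegaV, bool est_omegaCL, bool est_gamma,
              bool est_sigma, bool est_F,
              int n_burn, int n_iter, int n_chains_mh, int seed) {
  const int n = patients.size();
  std::vector<SaemPatient> sp(n);
  int idx = 0;
  arma::vec bV(std::max(nV, 0)), bCL(std::max(nCL, 0));
  for (int k = 0; k < nV; ++k) bV[k] = init[idx++];
  for (int k = 0; k < nCL; ++k) bCL[k] = init[idx++];
  double omegaV = init[idx++], omegaCL = init[idx++];
  double gamma = init[idx++], sigma = init[idx++], F = init[idx++];
  const bool useK = est_gamma || gamma > 1e-8;

  int n_occ_tot = 0, n_obs_tot = 0;
  std::vector<uint64_t> pid(n);
  for (int i = 0; i < n; ++i) {
    List pl = patients[i];
    pid[i] = pat_id(pl);
    sp[i].p = unpack_patient(pl, 1.0, 1.0);
    sp[i].plan = build_plan(sp[i].p, ka);
    sp[i].xV = as<arma::vec>(xV_list[i]);
    sp[i].xCL = as<arma::vec>(xCL_list[i]);
    sp[i].oV = oV[i];
    sp[i].oCL = oCL[i];
    double muV = sp[i].oV + (nV ? arma::dot(sp[i].xV, bV) : 0.0);
    double muCL = sp[i].oCL + (nCL ? arma::dot(sp[i].xCL, bCL) : 0.0);
    sp[i].phiV = muV;
    sp[i].phiCL = muCL;
    sp[i].kappa = arma::vec(useK ? sp[i].p.n_occ : 0, arma::fill::zeros);
    sp[i].CL_work.set_size(sp[i].p.n_occ);
    n_occ_tot += sp[i].p.n_occ;
    n_obs_tot += sp[i].p.obs_y.n_elem;
  }

  // precomputed designs for the M-step regressions
  arma::mat XV(n, std::max(nV, 1)), XCL(n, std::max(nCL, 1));
  for (int i = 0; i < n; ++i) {
    if (nV) XV.row(i) = sp[i].xV.t();
    if (nCL) XCL.row(i) = sp[i].xCL.t();
  }
  arma::mat XtXV = nV ? XV.cols(0, nV - 1).t() * XV.cols(0, nV - 1)
                      : arma::mat(1, 1, arma::fill::eye);
  arma::mat XtXCL = nCL ? XCL.cols(0, nCL - 1).t() * XCL.cols(0, nCL - 1)
                        : arma::mat(1, 1, arma::fill::eye);

  double step_scale = 0.4;
  // SA-smoothed sufficient statistics
  arma::vec S_xyV(std::max(nV, 1), arma::fill::zeros);
  arma::vec S_xyCL(std::max(nCL, 1), arma::fill::zeros);
  double S_rV = 0.0, S_rCL = 0.0, S_k2 = 0.0, S_res = 0.0, S_F = F;
  bool stats_init = false;

  const int n_total = n_burn + n_iter;
  for (int it = 0; it < n_total; ++it) {
    double acc = 0.0, tries = 0.0;
    // ---- E-step: Metropolis within Gibbs per patient
    for (int i = 0; i < n; ++i) {
      // per-patient, per-iteration stream keyed by the patient id, so the
      // fit is invariant to patient ordering
      PortableRng rng(((uint64_t)seed * 2654435761ULL) ^
                      ((pid[i] + 1) * 0x9E3779B97F4A7C15ULL) ^
                      ((uint64_t)(it + 1) * 0xBF58476D1CE4E5B9ULL));
      double muV = sp[i].oV + (nV ? arma::dot(sp[i].xV, bV) : 0.0);
      double muCL = sp[i].oCL + (nCL ? arma::dot(sp[i].xCL, bCL) : 0.0);
      if (omegaV < 1e-8) sp[i].phiV = muV;    // pinned: no IIV on V
      if (omegaCL < 1e-8) sp[i].phiCL = muCL; // pinned: no IIV on CL
      double ll = saem_neg2ll(sp[i], ka, F, sigma);
      // one componentwise Metropolis move; dev terms are the Gaussian prior
      auto mh_move = [&](double &comp, double mu, double sdev) {
        double dev0 = comp - mu;
        double old = comp;
        comp = old + step_scale * sdev * rng.norm();
        double dev1 = comp - mu;
        double llP = saem_neg2ll(sp[i], ka, F, sigma);
        double dlog = -0.5 * (llP - ll) -
          0.5 * (dev1 * dev1 - dev0 * dev0) / (sdev * sdev);
        tries += 1.0;
        if (std::log(rng.unif()) < dlog) { ll = llP; acc += 1.0; }
        else comp = old;
      };
      for (int sweep = 0; sweep < n_chains_mh; ++sweep) {
        if (omegaV >= 1e-8) mh_move(sp[i].phiV, muV, omegaV);
        if (omegaCL >= 1e-8) mh_move(sp[i].phiCL, muCL, omegaCL);
        if (useK && gamma > 1e-10)
          for (arma::uword k = 0; k < sp[i].kappa.n_elem; ++k)
            mh_move(sp[i].kappa[k], 0.0, gamma);
      }
    }
    // adapt proposal scale toward ~40% acceptance during burn-in
    if (it < n_burn && tries > 0) {
      double rate = acc / tries;
      step_scale *= std::exp(0.5 * (rate - 0.4));
      step_scale = std::min(std::max(step_scale, 0.05), 2.0);
    }

    // ---- current-sample sufficient statistics
    arma::vec xyV(std::max(nV, 1), arma::fill::zeros);
    arma::vec xyCL(std::max(nCL, 1), arma::fill::zeros);
    double k2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double yV = sp[i].phiV - sp[i].oV;
      double yCL = sp[i].phiCL - sp[i].oCL;
      if (nV) xyV += sp[i].xV * yV;
      if (nCL) xyCL += sp[i].xCL * yCL;
      if (useK) k2 += arma::dot(sp[i].kappa, sp[i].kappa);
    }
    // residual stat and F update on the current samples
    double Fhat = F;
    {
      // per-obs iv (a) and unit-F oral (b) components, then Brent over F
      for (int i = 0; i < n; ++i) {
        double V = std::exp(sp[i].phiV);
        for (int k = 0; k < sp[i].p.n_occ; ++k)
          sp[i].CL_work[k] = std::exp(sp[i].phiCL +
                                      (useK ? sp[i].kappa[k] : 0.0));
        arma::vec c1 = profile_eval(V, sp[i].CL_work, sp[i].p.occ_b, ka, 0.0,
                                    sp[i].p.d_time, sp[i].p.d_amt,
                                    sp[i].p.d_oral, sp[i].p.d_dur,
                                    sp[i].p.obs_t);
        arma::vec c2 = profile_eval(V, sp[i].CL_work, sp[i].p.occ_b, ka, 1.0,
                                    sp[i].p.d_time, sp[i].p.d_amt,
                                    sp[i].p.d_oral, sp[i].p.d_dur,
                                    sp[i].p.obs_t);
        sp[i].a = c1;
        sp[i].bF = c2 - c1;
      }
      auto gF = [&](double f) {
        double tot = 0.0;
        for (int i = 0; i < n; ++i)
          for (arma::uword j = 0; j < sp[i].p.obs_y.n_elem; ++j) {
            double c = sp[i].a[j] + f * sp[i].bF[j];
            if (!(c > 1e-12)) return 1e10;
            double r = (sp[i].p.obs_y[j] - c) / c;
            tot += 2.0 * std::log(c) + r * r / (sigma * sigma);
          }
        return tot;
      };
      if (est_F) {
        // golden-section on (0.05, 1]
        double lo = 0.05, hi = 1.0;
        const double gr = 0.61803398875;
        double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
        double f1 = gF(x1), f2 = gF(x2);
        for (int g = 0; g < 40; ++g) {
          if (f1 < f2) { hi = x2; x2 = x1; f2 = f1;
            x1 = hi - gr * (hi - lo); f1 = gF(x1); }
          else { lo = x1; x1 = x2; f1 = f2;
            x2 = lo + gr * (hi - lo); f2 = gF(x2); }
        }
        Fhat = 0.5 * (lo + hi);
      }
      // residual sums at Fhat
      double res = 0.0;
      for (int i = 0; i < n; ++i)
        for (arma::uword j = 0; j < sp[i].p.obs_y.n_elem; ++j) {
          double c = sp[i].a[j] + Fhat * sp[i].bF[j];
          double r = (sp[i].p.obs_y[j] - c) / std::max(c, 1e-12);
          res += r * r;
        }
      // ---- SA smoothing
      double alpha = (it < n_burn) ? 1.0
                     : 1.0 / std::pow(it - n_burn + 1, 0.7);
      if (!stats_init) {
        S_xyV = xyV; S_xyCL = xyCL; S_k2 = k2; S_res = res; S_F = Fhat;
        stats_init = true;
      } else {
        S_xyV += alpha * (xyV - S_xyV);
        S_xyCL += alpha * (xyCL - S_xyCL);
        S_k2 += alpha * (k2 - S_k2);
        S_res += alpha * (res - S_res);
        S_F += alpha * (Fhat - S_F);
      }
      if (est_F) F = S_F;
      if (est_sigma) sigma = std::max(std::sqrt(S_res / n_obs_tot), 1e-4);
    }
    // ---- M-step: regression coefficients and variances
    if (nV) bV = arma::solve(XtXV, S_xyV);
    if (nCL) bCL = arma::solve(XtXCL, S_xyCL);
    if (est_omegaV || est_omegaCL) {
      // SA on the squared deviations uses current samples around updated means
      double rV = 0.0, rCL = 0.0;
      for (int i = 0; i < n; ++i) {
        double muV = sp[i].oV + (nV ? arma::dot(sp[i].xV, bV) : 0.0);
        double muCL = sp[i].oCL + (nCL ? arma::dot(sp[i].xCL, bCL) : 0.0);
        double dV = sp[i].phiV - muV, dCL = sp[i].phiCL - muCL;
        rV += dV * dV; rCL += dCL * dCL;
      }
      double alpha = (it < n_burn) ? 1.0
                     : 1.0 / std::pow(it - n_burn + 1, 0.7);
      if (it == 0) { S_rV = rV; S_rCL = rCL; }
      else { S_rV += alpha * (rV - S_rV); S_rCL += alpha * (rCL - S_rCL); }
      if (est_omegaV) omegaV = std::max(std::sqrt(S_rV / n), 1e-3);
      if (est_omegaCL) omegaCL = std::max(std::sqrt(S_rCL / n), 1e-3);
    }
    if (est_gamma && useK)
      gamma = std::max(std::sqrt(S_k2 / n_occ_tot), 1e-3);
  }

  arma::vec out(nV + nCL + 5);
  idx = 0;
  for (int k = 0; k < nV; ++k) out[idx++] = bV[k];
  for (int k = 0; k < nCL; ++k) out[idx++] = bCL[k];
  out[idx++] = omegaV; out[idx++] = omegaCL; out[idx++] = gamma;
  out[idx++] = sigma; out[idx++] = F;
  return List::create(_["par"] = out, _["step_scale"] = step_scale);
}

// Posterior mode (MAP) of the random effects for a single patient with the
// population parameters held fixed; returns the mode and its penalized -2
// log joint value.
// [[Rcpp::export]]
List cpp_map_individual(const List &patient, double Vtyp, double CLtyp,
                        double F, double ka, double omegaV, double omegaCL,
                        double gamma, double sigma) {
  PatientData p = unpack_patient(patient, Vtyp, CLtyp);
  REStructure s = re_structure(omegaV, omegaCL, gamma, p.n_occ);
  Plan plan = build_plan(p, ka);
  InnerCtx ctx{&plan, &p, &s, ka, F, sigma, arma::vec(p.n_occ)};
  arma::vec b(s.d, arma::fill::zeros);
  double f = (s.d > 0) ? inner_newton(b, ctx, 200) : pen_obj(b, ctx);
  return List::create(_["b"] = wrap(b), _["value"] = f,
                      _["useV"] = s.useV, _["useCL"] = s.useCL,
                      _["useK"] = s.useK);
}
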