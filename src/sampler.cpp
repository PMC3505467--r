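// Adaptive block-updating random-walk Metropolis-Hastings sampler for the
// two-layer censored-mixture model.  Per-spot sufficient statistics (counts,
// sums, sums of squares per group) make each spot-likelihood evaluation O(1)
// in the number of gels.  R's RNG is used throughout, so a set.seed() on the
// R side makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;
static const double MASS_FLOOR = 1e-300;

static inline double plogis_(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double dnorm_log(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * LOG2PI - std::log(s) - 0.5 * z * z;
}

// log of the normal mass on [d, nu], computed in the better tail
static inline double log_trunc_mass(double mu, double sigma, double d,
                                    double nu) {
  double a = (d - mu) / sigma, b = (nu - mu) / sigma, m;
  if (a > 0.0)
    m = R::pnorm(a, 0, 1, 0, 0) - R::pnorm(b, 0, 1, 0, 0);
  else
    m = R::pnorm(b, 0, 1, 1, 0) - R::pnorm(a, 0, 1, 1, 0);
  if (!(m > MASS_FLOOR)) m = MASS_FLOOR;
  return std::log(m);
}

static inline double mod_laplace_log(double x, double lam, double phi) {
  if (x < 0.0) return std::log1p(-phi) + std::log(lam) + lam * x;
  return std::log(phi) + std::log(lam) - lam * x;
}

// inverse-gamma(0.001, 0.001) prior on the variance, evaluated as a density
// in the sd (includes the 2*sigma Jacobian)
static inline double sd_prior_log(double s) {
  if (!(s > 0.0)) return R_NegInf;
  const double a = 0.001, b = 0.001;
  static const double c0 = a * std::log(b) - R::lgammafn(a);
  double v = s * s;
  return c0 - (a + 1.0) * std::log(v) - b / v + std::log(2.0 * s);
}

struct SpotStats {
  double n0, sum0, ss0, miss0;   // control gels: observed count, sum, sum sq, missing
  double n1, sum1, ss1, miss1;   // case gels
};

struct Sampler {
  int S;
  std::vector<SpotStats> st;
  double d, nu;

  // local state
  std::vector<double> mu, del, kap, tau;
  // primed globals + expansion multipliers
  double muGp, sigGp, aMu, psi, lamD, phiD, muKp, sigKp, aK, muTp, sigTp, aT;
  // naturals (derived)
  double muG, sigG, sigS, muK, sigK, muT, sigT;

  // caches
  std::vector<double> locLik;
  double LLsum, Smu, Sdel, Skap, Stau;

  void naturals() {
    muG = aMu * muGp; sigG = aMu * sigGp;
    muK = aK * muKp;  sigK = aK * sigKp;
    muT = aT * muTp;  sigT = aT * sigTp;
    sigS = psi * sigG;
  }

  double groupLL(double m, double rho, const double n, const double sum,
                 const double ss, const double miss, double sig) const {
    double res = 0.0;
    if (miss > 0.0) {
      double pc = R::pnorm((d - m) / sig, 0, 1, 1, 0);
      double mass = (1.0 - rho) + rho * pc;
      if (!(mass > MASS_FLOOR)) mass = MASS_FLOOR;
      res += miss * std::log(mass);
    }
    if (n > 0.0) {
      double logLam = log_trunc_mass(m, sig, d, nu);
      res += n * (std::log(rho) - std::log(sig) - 0.5 * LOG2PI - logLam) -
        (ss - 2.0 * m * sum + n * m * m) / (2.0 * sig * sig);
    }
    return res;
  }

  double locLikSpot(int s, double m, double dl, double k, double t,
                    double sig) const {
    const SpotStats &x = st[s];
    double p0 = plogis_(k), p1 = plogis_(k + t);
    return groupLL(m, p0, x.n0, x.sum0, x.ss0, x.miss0, sig) +
           groupLL(m + dl, p1, x.n1, x.sum1, x.ss1, x.miss1, sig);
  }

  double sumSmu(double mG, double sG) const {
    double r = 0.0;
    for (int s = 0; s < S; ++s) r += dnorm_log(mu[s], mG, sG);
    return r;
  }
  double sumSdel(double lam, double phi) const {
    double r = 0.0;
    for (int s = 0; s < S; ++s) r += mod_laplace_log(del[s], lam, phi);
    return r;
  }
  double sumSkap(double mK, double sK) const {
    double r = 0.0;
    for (int s = 0; s < S; ++s) r += dnorm_log(kap[s], mK, sK);
    return r;
  }
  double sumStau(double mT, double sT) const {
    double r = 0.0;
    for (int s = 0; s < S; ++s) r += dnorm_log(tau[s], mT, sT);
    return r;
  }

  double priorLog() const {
    if (psi < 0.001 || psi > 2.0) return R_NegInf;
    if (!(lamD > 0.0)) return R_NegInf;
    if (!(phiD > 0.0 && phiD < 1.0)) return R_NegInf;
    double r = dnorm_log(muG, -3.0, 5.0) + sd_prior_log(sigG) -
      std::log(2.0 - 0.001) - lamD +
      std::log(6.0) + std::log(phiD) + std::log1p(-phiD) +
      dnorm_log(muK, 0.0, 3.0) + sd_prior_log(sigK) +
      dnorm_log(muT, 0.0, 3.0) + sd_prior_log(sigT);
    return r;
  }

  void refreshCaches() {
    naturals();
    LLsum = 0.0;
    for (int s = 0; s < S; ++s) {
      locLik[s] = locLikSpot(s, mu[s], del[s], kap[s], tau[s], sigS);
      LLsum += locLik[s];
    }
    Smu = sumSmu(muG, sigG);
    Sdel = sumSdel(lamD, phiD);
    Skap = sumSkap(muK, sigK);
    Stau = sumStau(muT, sigT);
  }

  double fullLogPost() const {
    return LLsum + Smu + Sdel + Skap + Stau + priorLog();
  }
};

// --- proposal kernels (all consume R's RNG deterministically) --------------

static inline double prop_normal(double cur, double sd) {
  return cur + sd * R::norm_rand();
}

// lower-truncated normal proposal; adds log Z(cur) - log Z(cand) to corr
static inline double prop_tnorm_lower(double cur, double sd, double lower,
                                      double &corr) {
  double pa = R::pnorm(lower, cur, sd, 1, 0);
  double u = pa + R::unif_rand() * (1.0 - pa);
  if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
  if (u < 1e-300) u = 1e-300;
  double x = R::qnorm(u, cur, sd, 1, 0);
  if (x < lower) x = lower;
  double zc = 1.0 - pa;
  double zn = R::pnorm(lower, x, sd, 0, 0);  // upper tail at candidate
  if (zc < MASS_FLOOR) zc = MASS_FLOOR;
  if (zn < MASS_FLOOR) zn = MASS_FLOOR;
  corr += std::log(zc) - std::log(zn);
  return x;
}

// doubly-truncated normal proposal on [lower, upper]
static inline double prop_tnorm_both(double cur, double sd, double lower,
                                     double upper, double &corr) {
  double pa = R::pnorm(lower, cur, sd, 1, 0);
  double pb = R::pnorm(upper, cur, sd, 1, 0);
  double m = pb - pa;
  if (m < MASS_FLOOR) m = MASS_FLOOR;
  double u = pa + R::unif_rand() * (pb - pa);
  if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
  if (u < 1e-300) u = 1e-300;
  double x = R::qnorm(u, cur, sd, 1, 0);
  if (x < lower) x = lower;
  if (x > upper) x = upper;
  double mn = R::pnorm(upper, x, sd, 1, 0) - R::pnorm(lower, x, sd, 1, 0);
  if (mn < MASS_FLOOR) mn = MASS_FLOOR;
  corr += std::log(m) - std::log(mn);
  return x;
}

// logit-scale normal walk for a (0,1) parameter, with Jacobian correction
static inline double prop_logitnorm(double cur, double sd, double &corr) {
  double z = std::log(cur / (1.0 - cur)) + sd * R::norm_rand();
  double x = plogis_(z);
  if (x <= 0.0 || x >= 1.0) return x;  // rejected downstream via support
  corr += std::log(x) + std::log1p(-x) - std::log(cur) - std::log1p(-cur);
  return x;
}

static inline bool mh_decide(double delta) {
  double lu = std::log(R::unif_rand());
  return lu < delta;   // NaN / -Inf compare false => reject
}

// [[Rcpp::export(name = ".run_sampler_cpp")]]
List run_sampler_cpp(NumericMatrix values, IntegerVector groups, double d,
                     double nu, int iterations, int thin, double burninFrac,
                     List init, bool expand, double rhoOpt1, double rhoOpt2,
                     int tuneInterval, int tuneWindow, double sdInit) {
  const int S = values.nrow(), G = values.ncol();
  int nCase = 0;
  for (int g = 0; g < G; ++g) if (groups[g] == 1) ++nCase;
  Sampler M;
  M.S = S; M.d = d; M.nu = nu;
  M.st.resize(S);
  for (int s = 0; s < S; ++s) {
    SpotStats x = {0, 0, 0, 0, 0, 0, 0, 0};
    for (int g = 0; g < G; ++g) {
      double v = values(s, g);
      bool ctrl = groups[g] == 0;
      if (NumericMatrix::is_na(v) || v < d) {
        if (ctrl) x.miss0 += 1.0; else x.miss1 += 1.0;
      } else if (ctrl) {
        x.n0 += 1.0; x.sum0 += v; x.ss0 += v * v;
      } else {
        x.n1 += 1.0; x.sum1 += v; x.ss1 += v * v;
      }
    }
    M.st[s] = x;
  }

  auto loadInit = [&](List ini) {
    M.mu  = as<std::vector<double> >(ini["mu"]);
    M.del = as<std::vector<double> >(ini["delta"]);
    M.kap = as<std::vector<double> >(ini["kappa"]);
    M.tau = as<std::vector<double> >(ini["tau"]);
    M.muGp = as<double>(ini["muG"]);   M.sigGp = as<double>(ini["sigmaG"]);
    M.psi  = as<double>(ini["psi"]);
    M.lamD = as<double>(ini["lambdaDelta"]);
    M.phiD = as<double>(ini["phiDelta"]);
    M.muKp = as<double>(ini["muKappa"]); M.sigKp = as<double>(ini["sigmaKappa"]);
    M.muTp = as<double>(ini["muTau"]);   M.sigTp = as<double>(ini["sigmaTau"]);
    M.aMu = 1.0; M.aK = 1.0; M.aT = 1.0;
  };
  M.locLik.resize(S);
  loadInit(init);
  M.refreshCaches();
  if (!std::isfinite(M.fullLogPost())) {
    // fall back to a generic in-support state
    List safe = List::create(
      _["mu"] = NumericVector(S, -3.0), _["delta"] = NumericVector(S, 0.0),
      _["kappa"] = NumericVector(S, 0.0), _["tau"] = NumericVector(S, 0.0),
      _["muG"] = -3.0, _["sigmaG"] = 1.0, _["psi"] = 0.5,
      _["lambdaDelta"] = 1.0, _["phiDelta"] = 0.5,
      _["muKappa"] = 0.0, _["sigmaKappa"] = 1.0,
      _["muTau"] = 0.0, _["sigmaTau"] = 1.0);
    loadInit(safe);
    M.refreshCaches();
    if (!std::isfinite(M.fullLogPost()))
      stop("could not find a finite initial posterior state");
  }

  // tunable units: 8 global blocks + 2 shared local blocks
  const int NB = 10;
  // parameters per block: 0.44 target for 1-d, 0.234 for multi-d
  const double rhoOpt[NB] = {rhoOpt2, rhoOpt1, rhoOpt2, rhoOpt1, rhoOpt2,
                             rhoOpt1, rhoOpt2, rhoOpt1, rhoOpt2, rhoOpt2};
  std::vector<double> sd(NB, sdInit);
  const int nChunks = std::max(1, tuneWindow / tuneInterval);
  std::vector<std::vector<double> > chP(NB, std::vector<double>(nChunks, 0.0));
  std::vector<std::vector<double> > chA(NB, std::vector<double>(nChunks, 0.0));
  std::vector<double> curP(NB, 0.0), curA(NB, 0.0);
  std::vector<double> postP(NB, 0.0), postA(NB, 0.0);
  std::vector<double> tunedAcc(NB, NA_REAL);  // window acceptance at freeze
  int chunkIdx = 0;
  const int burnIters = (int)std::floor(burninFrac * (double)iterations);

  const int nRec = iterations / thin;
  const int nCol = 12 + 4 * S + 1;
  NumericMatrix samples(nRec, nCol);
  IntegerVector stateIdx(nRec);
  int row = 0;

  auto tally = [&](int id, bool acc, bool inBurn) {
    curP[id] += 1.0; if (acc) curA[id] += 1.0;
    if (!inBurn) { postP[id] += 1.0; if (acc) postA[id] += 1.0; }
  };

  for (int t = 1; t <= iterations; ++t) {
    const bool inBurn = t <= burnIters;

    // ---- block 0: (muG', sigG') ------------------------------------------
    // scale-aware pair proposal: log-normal walk on the primed sd and a
    // mean step proportional to the current primed sd, so the tuned step
    // tracks the block's own posterior scale as the chain (and the
    // expansion multiplier) drifts.  The Hastings correction is exact; the
    // natural-scale support bound sigma >= 0.01 matches the proposal
    // truncation used for the unexpanded scale parameters.
    {
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double c2 = M.sigGp * std::exp(sd[0] * z1);
      double c1 = M.muGp + sd[0] * M.sigGp * z2;
      double dm = c1 - M.muGp;
      double corr = 0.5 * (dm * dm) / (sd[0] * sd[0]) *
        (1.0 / (M.sigGp * M.sigGp) - 1.0 / (c2 * c2));
      double nMuG = M.aMu * c1, nSigG = M.aMu * c2, nSigS = M.psi * nSigG;
      bool acc = false;
      if (nSigG >= 0.01) {
        double candLL = 0.0;
        std::vector<double> tmp(S);
        for (int s = 0; s < S; ++s) {
          tmp[s] = M.locLikSpot(s, M.mu[s], M.del[s], M.kap[s], M.tau[s],
                                nSigS);
          candLL += tmp[s];
        }
        double candSmu = M.sumSmu(nMuG, nSigG);
        double dPr = dnorm_log(nMuG, -3.0, 5.0) + sd_prior_log(nSigG) -
                     dnorm_log(M.muG, -3.0, 5.0) - sd_prior_log(M.sigG);
        double delta = (candLL - M.LLsum) + (candSmu - M.Smu) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) {
          M.muGp = c1; M.sigGp = c2; M.naturals();
          M.locLik.swap(tmp); M.LLsum = candLL; M.Smu = candSmu;
        }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(0, acc, inBurn);
    }

    // ---- block 1: alpha_mu (expansion only) ------------------------------
    if (expand) {
      double corr = 0.0;
      // a step in alpha moves the naturals by (muGp, sigGp) * d(alpha);
      // normalizing by their norm keeps the tuned scale meaningful as the
      // chain drifts (both are fixed within this block)
      double s1 = sd[1] / std::sqrt(M.muGp * M.muGp + M.sigGp * M.sigGp);
      double cA = prop_tnorm_lower(M.aMu, s1, 0.01, corr);
      bool acc = false;
      if (cA <= 10.0) {
        double nMuG = cA * M.muGp, nSigG = cA * M.sigGp, nSigS = M.psi * nSigG;
        double candLL = 0.0;
        std::vector<double> tmp(S);
        for (int s = 0; s < S; ++s) {
          tmp[s] = M.locLikSpot(s, M.mu[s], M.del[s], M.kap[s], M.tau[s], nSigS);
          candLL += tmp[s];
        }
        double candSmu = M.sumSmu(nMuG, nSigG);
        double dPr = dnorm_log(nMuG, -3.0, 5.0) + sd_prior_log(nSigG) -
                     dnorm_log(M.muG, -3.0, 5.0) - sd_prior_log(M.sigG);
        double delta = (candLL - M.LLsum) + (candSmu - M.Smu) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) {
          M.aMu = cA; M.naturals();
          M.locLik.swap(tmp); M.LLsum = candLL; M.Smu = candSmu;
        }
      } else {
        (void)mh_decide(R_NegInf);   // keep the RNG stream aligned
      }
      tally(1, acc, inBurn);
    }

    // ---- block 2: (lambda_delta, phi_delta) ------------------------------
    {
      double corr = 0.0;
      double cL = prop_tnorm_lower(M.lamD, sd[2], 0.01, corr);
      double cF = prop_logitnorm(M.phiD, sd[2], corr);
      bool acc = false;
      if (cF > 0.0 && cF < 1.0) {
        double candSdel = M.sumSdel(cL, cF);
        double dPr = (-cL + std::log(cF) + std::log1p(-cF)) -
                     (-M.lamD + std::log(M.phiD) + std::log1p(-M.phiD));
        double delta = (candSdel - M.Sdel) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) { M.lamD = cL; M.phiD = cF; M.Sdel = candSdel; }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(2, acc, inBurn);
    }

    // ---- block 3: psi ----------------------------------------------------
    {
      double corr = 0.0;
      double cP = prop_tnorm_both(M.psi, sd[3] / M.sigG, 0.001, 2.0, corr);
      double nSigS = cP * M.sigG;
      double candLL = 0.0;
      std::vector<double> tmp(S);
      for (int s = 0; s < S; ++s) {
        tmp[s] = M.locLikSpot(s, M.mu[s], M.del[s], M.kap[s], M.tau[s], nSigS);
        candLL += tmp[s];
      }
      double delta = (candLL - M.LLsum) + corr;  // flat prior on [0.001, 2]
      bool acc = mh_decide(delta);
      if (acc) {
        M.psi = cP; M.sigS = nSigS;
        M.locLik.swap(tmp); M.LLsum = candLL;
      }
      tally(3, acc, inBurn);
    }

    // ---- block 4: (muK', sigK') ------------------------------------------
    {
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double c2 = M.sigKp * std::exp(sd[4] * z1);
      double c1 = M.muKp + sd[4] * M.sigKp * z2;
      double dm = c1 - M.muKp;
      double corr = 0.5 * (dm * dm) / (sd[4] * sd[4]) *
        (1.0 / (M.sigKp * M.sigKp) - 1.0 / (c2 * c2));
      double nMuK = M.aK * c1, nSigK = M.aK * c2;
      bool acc = false;
      if (nSigK >= 0.01) {
        double candSkap = M.sumSkap(nMuK, nSigK);
        double dPr = dnorm_log(nMuK, 0.0, 3.0) + sd_prior_log(nSigK) -
                     dnorm_log(M.muK, 0.0, 3.0) - sd_prior_log(M.sigK);
        double delta = (candSkap - M.Skap) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) { M.muKp = c1; M.sigKp = c2; M.naturals(); M.Skap = candSkap; }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(4, acc, inBurn);
    }

    // ---- block 5: alpha_kappa --------------------------------------------
    if (expand) {
      double corr = 0.0;
      double s5 = sd[5] / std::sqrt(M.muKp * M.muKp + M.sigKp * M.sigKp);
      double cA = prop_tnorm_lower(M.aK, s5, 0.01, corr);
      bool acc = false;
      if (cA <= 10.0) {
        double nMuK = cA * M.muKp, nSigK = cA * M.sigKp;
        double candSkap = M.sumSkap(nMuK, nSigK);
        double dPr = dnorm_log(nMuK, 0.0, 3.0) + sd_prior_log(nSigK) -
                     dnorm_log(M.muK, 0.0, 3.0) - sd_prior_log(M.sigK);
        double delta = (candSkap - M.Skap) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) { M.aK = cA; M.naturals(); M.Skap = candSkap; }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(5, acc, inBurn);
    }

    // ---- block 6: (muT', sigT') ------------------------------------------
    {
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double c2 = M.sigTp * std::exp(sd[6] * z1);
      double c1 = M.muTp + sd[6] * M.sigTp * z2;
      double dm = c1 - M.muTp;
      double corr = 0.5 * (dm * dm) / (sd[6] * sd[6]) *
        (1.0 / (M.sigTp * M.sigTp) - 1.0 / (c2 * c2));
      double nMuT = M.aT * c1, nSigT = M.aT * c2;
      bool acc = false;
      if (nSigT >= 0.01) {
        double candStau = M.sumStau(nMuT, nSigT);
        double dPr = dnorm_log(nMuT, 0.0, 3.0) + sd_prior_log(nSigT) -
                     dnorm_log(M.muT, 0.0, 3.0) - sd_prior_log(M.sigT);
        double delta = (candStau - M.Stau) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) { M.muTp = c1; M.sigTp = c2; M.naturals(); M.Stau = candStau; }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(6, acc, inBurn);
    }

    // ---- block 7: alpha_tau ----------------------------------------------
    if (expand) {
      double corr = 0.0;
      double s7 = sd[7] / std::sqrt(M.muTp * M.muTp + M.sigTp * M.sigTp);
      double cA = prop_tnorm_lower(M.aT, s7, 0.01, corr);
      bool acc = false;
      if (cA <= 10.0) {
        double nMuT = cA * M.muTp, nSigT = cA * M.sigTp;
        double candStau = M.sumStau(nMuT, nSigT);
        double dPr = dnorm_log(nMuT, 0.0, 3.0) + sd_prior_log(nSigT) -
                     dnorm_log(M.muT, 0.0, 3.0) - sd_prior_log(M.sigT);
        double delta = (candStau - M.Stau) + dPr + corr;
        acc = mh_decide(delta);
        if (acc) { M.aT = cA; M.naturals(); M.Stau = candStau; }
      } else {
        (void)mh_decide(R_NegInf);
      }
      tally(7, acc, inBurn);
    }

    // ---- local blocks, fixed spot order ----------------------------------
    // logit-scale steps track the per-spot posterior width: prior precision
    // 1/sigma^2 from the global layer plus a Bernoulli information floor of
    // ~0.15 per informative gel (kappa sees every gel, tau only case gels)
    const double scaleK = 1.0 / std::sqrt(0.15 * G + 1.0 / (M.sigK * M.sigK));
    const double scaleT = 1.0 / std::sqrt(0.15 * nCase +
                                          1.0 / (M.sigT * M.sigT));
    for (int s = 0; s < S; ++s) {
      // (mu_s, delta_s)
      {
        // intensity-scale locals step proportionally to the current spot sd
        double cM = prop_normal(M.mu[s], sd[8] * M.sigS);
        double cD = prop_normal(M.del[s], sd[8] * M.sigS);
        double candL = M.locLikSpot(s, cM, cD, M.kap[s], M.tau[s], M.sigS);
        double dG = dnorm_log(cM, M.muG, M.sigG) -
                    dnorm_log(M.mu[s], M.muG, M.sigG) +
                    mod_laplace_log(cD, M.lamD, M.phiD) -
                    mod_laplace_log(M.del[s], M.lamD, M.phiD);
        double delta = (candL - M.locLik[s]) + dG;
        bool acc = mh_decide(delta);
        if (acc) {
          M.LLsum += candL - M.locLik[s];
          M.Smu += dnorm_log(cM, M.muG, M.sigG) -
                   dnorm_log(M.mu[s], M.muG, M.sigG);
          M.Sdel += mod_laplace_log(cD, M.lamD, M.phiD) -
                    mod_laplace_log(M.del[s], M.lamD, M.phiD);
          M.mu[s] = cM; M.del[s] = cD; M.locLik[s] = candL;
        }
        tally(8, acc, inBurn);
      }
      // (kappa_s, tau_s)
      {
        double cK = prop_normal(M.kap[s], sd[9] * scaleK);
        double cT = prop_normal(M.tau[s], sd[9] * scaleT);
        double candL = M.locLikSpot(s, M.mu[s], M.del[s], cK, cT, M.sigS);
        double dG = dnorm_log(cK, M.muK, M.sigK) -
                    dnorm_log(M.kap[s], M.muK, M.sigK) +
                    dnorm_log(cT, M.muT, M.sigT) -
                    dnorm_log(M.tau[s], M.muT, M.sigT);
        double delta = (candL - M.locLik[s]) + dG;
        bool acc = mh_decide(delta);
        if (acc) {
          M.LLsum += candL - M.locLik[s];
          M.Skap += dnorm_log(cK, M.muK, M.sigK) -
                    dnorm_log(M.kap[s], M.muK, M.sigK);
          M.Stau += dnorm_log(cT, M.muT, M.sigT) -
                    dnorm_log(M.tau[s], M.muT, M.sigT);
          M.kap[s] = cK; M.tau[s] = cT; M.locLik[s] = candL;
        }
        tally(9, acc, inBurn);
      }
    }

    // ---- proposal-sd adaptation (burn-in only) ---------------------------
    if (t % tuneInterval == 0) {
      for (int b = 0; b < NB; ++b) {
        chP[b][chunkIdx] = curP[b]; chA[b][chunkIdx] = curA[b];
        curP[b] = 0.0; curA[b] = 0.0;
      }
      chunkIdx = (chunkIdx + 1) % nChunks;
      if (inBurn) {
        for (int b = 0; b < NB; ++b) {
          double wp = 0.0, wa = 0.0;
          for (int c = 0; c < nChunks; ++c) { wp += chP[b][c]; wa += chA[b][c]; }
          if (wp <= 0.0) continue;
          double rho = wa / wp;
          tunedAcc[b] = rho;
          double lo = 1.0 / wp, hi = 1.0 - 1.0 / wp;
          if (rho < lo) rho = lo;
          if (rho > hi) rho = hi;
          sd[b] *= R::qnorm(rhoOpt[b] / 2.0, 0, 1, 1, 0) /
                   R::qnorm(rho / 2.0, 0, 1, 1, 0);
          if (sd[b] < 1e-8) sd[b] = 1e-8;
          if (sd[b] > 1e8) sd[b] = 1e8;
        }
      }
    }

    // ---- periodic exact refresh to kill accumulated float drift ----------
    if (t % 10000 == 0) M.refreshCaches();

    // ---- record ----------------------------------------------------------
    if (t % thin == 0) {
      M.refreshCaches();
      int j = 0;
      samples(row, j++) = M.muG;  samples(row, j++) = M.sigG;
      samples(row, j++) = M.psi;  samples(row, j++) = M.lamD;
      samples(row, j++) = M.phiD; samples(row, j++) = M.muK;
      samples(row, j++) = M.sigK; samples(row, j++) = M.muT;
      samples(row, j++) = M.sigT; samples(row, j++) = M.aMu;
      samples(row, j++) = M.aK;   samples(row, j++) = M.aT;
      for (int s = 0; s < S; ++s) samples(row, j++) = M.mu[s];
      for (int s = 0; s < S; ++s) samples(row, j++) = M.del[s];
      for (int s = 0; s < S; ++s) samples(row, j++) = M.kap[s];
      for (int s = 0; s < S; ++s) samples(row, j++) = M.tau[s];
      samples(row, j++) = M.fullLogPost();
      stateIdx[row] = t;
      ++row;
    }
    if (t % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector accRate(NB), finalSd(NB);
  for (int b = 0; b < NB; ++b) {
    accRate[b] = postP[b] > 0.0 ? postA[b] / postP[b] : NA_REAL;
    finalSd[b] = sd[b];
  }
  return List::create(
    _["samples"] = samples, _["state"] = stateIdx,
    _["acceptance"] = accRate, _["proposalSd"] = finalSd,
    _["tunedAcceptance"] = NumericVector(tunedAcc.begin(), tunedAcc.end()),
    _["burnIters"] = burnIters);
}
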