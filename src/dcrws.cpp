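// Two-state switching first-difference correlated random walk, fit by
// Metropolis-within-Gibbs: single-site random-walk MH on the latent 8-h
// positions, forward-filtering backward-sampling for the hidden behavioural
// chain, conjugate Beta draws for the transition probabilities and
// random-walk MH for the remaining movement parameters. Observations are
// linear interpolations between bracketing states plus per-location-class
// Student-t errors scaled by a free inflation psi.
//
// State 1 (index 0) = migration, constrained gamma1 > gamma2.

#include <Rcpp.h>
using namespace Rcpp;

static inline double logdt(double resid, double df, double scale) {
  return R::dt(resid / scale, df, 1) - std::log(scale);
}

struct Model {
  int n, m;                  // observations, states
  NumericMatrix y;           // n x 2 (lon, lat) degrees
  NumericVector jfrac;       // fractional position within interval [0,1)
  IntegerVector idx;         // 0-based left state index per observation
  NumericVector tdf;         // t degrees of freedom per obs
  NumericMatrix tsc;         // n x 2 t scale (deg) per obs, psi-free
  std::vector<std::vector<int> > obsBy; // obs indices per interval (m-1)

  // latent state
  NumericMatrix x;           // m x 2
  std::vector<int> b;        // m-1 step states in {0,1}; process term for s>=2

  // parameters
  double gamma[2], theta[2], alpha[2], sigma[2], psi;

  double procTerm(int s) const {
    // density of d_s given d_{s-1}, s in [2, m-1]
    double d0 = x(s, 0) - x(s - 1, 0), d1 = x(s, 1) - x(s - 1, 1);
    double p0 = x(s - 1, 0) - x(s - 2, 0), p1 = x(s - 1, 1) - x(s - 2, 1);
    int k = b[s - 1];
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    double mu0 = gamma[k] * (ct * p0 - st * p1);
    double mu1 = gamma[k] * (st * p0 + ct * p1);
    return R::dnorm(d0, mu0, sigma[0], 1) + R::dnorm(d1, mu1, sigma[1], 1);
  }

  double procTermState(int s, int k) const {
    double d0 = x(s, 0) - x(s - 1, 0), d1 = x(s, 1) - x(s - 1, 1);
    double p0 = x(s - 1, 0) - x(s - 2, 0), p1 = x(s - 1, 1) - x(s - 2, 1);
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    double mu0 = gamma[k] * (ct * p0 - st * p1);
    double mu1 = gamma[k] * (st * p0 + ct * p1);
    return R::dnorm(d0, mu0, sigma[0], 1) + R::dnorm(d1, mu1, sigma[1], 1);
  }

  double procLogLik() const {
    double ll = 0.0;
    for (int s = 2; s <= m - 1; ++s) ll += procTerm(s);
    return ll;
  }

  // marginal process likelihood with the hidden chain summed out (forward
  // algorithm); used for the collapsed movement-parameter updates so the
  // sampler can reallocate states implicitly while moving gamma/theta/sigma
  double forwardLogLik() const {
    double a1 = alpha[0], a2 = alpha[1];
    double P[2][2] = { { a1, 1.0 - a1 }, { a2, 1.0 - a2 } };
    double pi1 = a2 / (1.0 - a1 + a2);
    double f0 = pi1, f1 = 1.0 - pi1; // flat emission at s = 1
    double ll = 0.0;
    for (int s = 2; s <= m - 1; ++s) {
      double e0 = procTermState(s, 0), e1 = procTermState(s, 1);
      double mx = std::max(e0, e1);
      double g0 = (f0 * P[0][0] + f1 * P[1][0]) * std::exp(e0 - mx);
      double g1 = (f0 * P[0][1] + f1 * P[1][1]) * std::exp(e1 - mx);
      double nz = g0 + g1;
      ll += mx + std::log(nz);
      f0 = g0 / nz; f1 = g1 / nz;
    }
    return ll;
  }

  double obsTerm(int i) const {
    int t = idx[i];
    double j = jfrac[i], ll = 0.0;
    for (int c = 0; c < 2; ++c) {
      double mu = (1.0 - j) * x(t, c) + j * x(t + 1, c);
      ll += logdt(y(i, c) - mu, tdf[i], psi * tsc(i, c));
    }
    return ll;
  }

  double obsLogLik() const {
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += obsTerm(i);
    return ll;
  }

  double localLogPost(int t) const {
    double ll = 0.0;
    if (t > 0) for (size_t q = 0; q < obsBy[t - 1].size(); ++q) ll += obsTerm(obsBy[t - 1][q]);
    if (t < m - 1) for (size_t q = 0; q < obsBy[t].size(); ++q) ll += obsTerm(obsBy[t][q]);
    int lo = std::max(2, t), hi = std::min(m - 1, t + 2);
    for (int s = lo; s <= hi; ++s) ll += procTerm(s);
    return ll;
  }
};

static void ffbs(Model &M) {
  // hidden chain over steps s = 1..m-1 (stored b[0..m-2]); emission for the
  // first step is flat (its predecessor difference is diffuse)
  int S = M.m - 1;
  double a1 = M.alpha[0], a2 = M.alpha[1];
  double P[2][2] = { { a1, 1.0 - a1 }, { a2, 1.0 - a2 } };
  // stationary distribution of the 2-state chain
  double pi1 = a2 / (1.0 - a1 + a2);
  std::vector<double> f0(S), f1(S);
  double e0 = 0.0, e1 = 0.0; // flat emission at s=1
  double l0 = std::log(pi1) + e0, l1 = std::log(1.0 - pi1) + e1;
  double mx = std::max(l0, l1);
  f0[0] = std::exp(l0 - mx); f1[0] = std::exp(l1 - mx);
  double norm = f0[0] + f1[0]; f0[0] /= norm; f1[0] /= norm;
  for (int s = 2; s <= S; ++s) {
    double le0 = M.procTermState(s, 0), le1 = M.procTermState(s, 1);
    double p0 = f0[s - 2] * P[0][0] + f1[s - 2] * P[1][0];
    double p1 = f0[s - 2] * P[0][1] + f1[s - 2] * P[1][1];
    double g0 = std::log(p0 + 1e-300) + le0, g1 = std::log(p1 + 1e-300) + le1;
    double gm = std::max(g0, g1);
    f0[s - 1] = std::exp(g0 - gm); f1[s - 1] = std::exp(g1 - gm);
    double nz = f0[s - 1] + f1[s - 1];
    f0[s - 1] /= nz; f1[s - 1] /= nz;
  }
  // backward sampling
  M.b[S - 1] = (R::unif_rand() < f1[S - 1]) ? 1 : 0;
  for (int s = S - 1; s >= 1; --s) {
    int nxt = M.b[s];
    double w0 = f0[s - 1] * P[0][nxt];
    double w1 = f1[s - 1] * P[1][nxt];
    M.b[s - 1] = (R::unif_rand() < w1 / (w0 + w1)) ? 1 : 0;
  }
}

static inline double wrapAngle(double th) {
  while (th > M_PI) th -= 2.0 * M_PI;
  while (th <= -M_PI) th += 2.0 * M_PI;
  return th;
}

// [[Rcpp::export(name = ".dcrwsChain")]]
List dcrwsChain(NumericMatrix y, NumericVector jfrac, IntegerVector idx,
                int m, NumericVector tdf, NumericMatrix tsc,
                int nsweep, int burnin, int thin,
                NumericMatrix xinit, IntegerVector binit,
                NumericVector parinit, double sigmaPriorScale,
                double xstep0, double parstep0, int xrep,
                NumericMatrix xanchor, double anchorScale) {
  RNGScope scope;
  Model M;
  M.n = y.nrow(); M.m = m; M.y = y; M.jfrac = jfrac; M.idx = idx;
  M.tdf = tdf; M.tsc = tsc;
  M.obsBy.assign(m - 1, std::vector<int>());
  for (int i = 0; i < M.n; ++i) M.obsBy[idx[i]].push_back(i);
  M.x = clone(xinit);
  M.b.assign(binit.begin(), binit.end());
  M.gamma[0] = parinit[0]; M.gamma[1] = parinit[1];
  M.theta[0] = parinit[2]; M.theta[1] = parinit[3];
  M.alpha[0] = parinit[4]; M.alpha[1] = parinit[5];
  M.sigma[0] = parinit[6]; M.sigma[1] = parinit[7];
  M.psi = parinit[8];

  int nkeep = nsweep / thin;
  NumericMatrix pars(nkeep, 9);
  NumericVector bsum(m - 1);
  NumericMatrix xsum(m, 2);

  double xstep = xstep0;
  double pstep[7]; // gamma1, gamma2, theta1, theta2, sigma0, sigma1, psi
  for (int k = 0; k < 7; ++k) pstep[k] = parstep0;
  int xacc = 0, xtry = 0, pacc[7] = {0}, ptry[7] = {0};
  int kept = 0;

  for (int sweep = 0; sweep < burnin + nsweep; ++sweep) {
    // --- latent positions, single-site MH; several sweeps per iteration and
    // an occasional wide proposal so the path decorrelates from its
    // interpolated initialisation
    for (int rep = 0; rep < xrep; ++rep) {
      for (int t = 0; t < m; ++t) {
        double old0 = M.x(t, 0), old1 = M.x(t, 1);
        double u = R::unif_rand();
        if (u < 0.2) {
          // anchored independence proposal: jump to the data-interpolated
          // position; lets the path recover observation detail even from an
          // over-smoothed configuration (heavy-tailed errors otherwise allow
          // the path to ignore fixes cheaply)
          double ll0 = M.localLogPost(t);
          double prop0 = xanchor(t, 0) + R::norm_rand() * anchorScale;
          double prop1 = xanchor(t, 1) + R::norm_rand() * anchorScale;
          double lq0 = R::dnorm(old0, xanchor(t, 0), anchorScale, 1) +
            R::dnorm(old1, xanchor(t, 1), anchorScale, 1);
          double lq1 = R::dnorm(prop0, xanchor(t, 0), anchorScale, 1) +
            R::dnorm(prop1, xanchor(t, 1), anchorScale, 1);
          M.x(t, 0) = prop0; M.x(t, 1) = prop1;
          double ll1 = M.localLogPost(t);
          if (std::log(R::unif_rand()) >= ll1 - ll0 + lq0 - lq1) {
            M.x(t, 0) = old0; M.x(t, 1) = old1;
          }
        } else {
          double step = (u < 0.3) ? 5.0 * xstep : xstep;
          double ll0 = M.localLogPost(t);
          M.x(t, 0) = old0 + R::norm_rand() * step;
          M.x(t, 1) = old1 + R::norm_rand() * step;
          double ll1 = M.localLogPost(t);
          ++xtry;
          if (std::log(R::unif_rand()) < ll1 - ll0) { ++xacc; }
          else { M.x(t, 0) = old0; M.x(t, 1) = old1; }
        }
      }
    }

    // --- movement parameters: collapsed random-walk MH with the hidden
    // chain marginalised by the forward algorithm (the chain is redrawn by
    // FFBS immediately afterwards, making this a valid partially collapsed
    // Gibbs step and preventing the single-regime allocation trap)
    // gamma_k with ordering gamma1 > gamma2, uniform(0,1) prior
    for (int k = 0; k < 2; ++k) {
      double old = M.gamma[k];
      double prop = old + R::norm_rand() * pstep[k];
      ++ptry[k];
      bool ok = prop > 0.0 && prop < 1.0 &&
        ((k == 0) ? (prop > M.gamma[1]) : (prop < M.gamma[0]));
      if (ok) {
        double ll0 = M.forwardLogLik();
        M.gamma[k] = prop;
        double ll1 = M.forwardLogLik();
        if (std::log(R::unif_rand()) < ll1 - ll0) ++pacc[k];
        else M.gamma[k] = old;
      }
    }
    // theta_k, uniform prior on (-pi, pi]
    for (int k = 0; k < 2; ++k) {
      double old = M.theta[k];
      double prop = wrapAngle(old + R::norm_rand() * pstep[2 + k] * M_PI);
      ++ptry[2 + k];
      double ll0 = M.forwardLogLik();
      M.theta[k] = prop;
      double ll1 = M.forwardLogLik();
      if (std::log(R::unif_rand()) < ll1 - ll0) ++pacc[2 + k];
      else M.theta[k] = old;
    }
    // sigma_c, half-normal prior, log random walk
    for (int c = 0; c < 2; ++c) {
      double old = M.sigma[c];
      double prop = old * std::exp(R::norm_rand() * pstep[4 + c]);
      ++ptry[4 + c];
      double ll0 = M.forwardLogLik() +
        R::dnorm(old, 0.0, sigmaPriorScale, 1) + std::log(old);
      M.sigma[c] = prop;
      double ll1 = M.forwardLogLik() +
        R::dnorm(prop, 0.0, sigmaPriorScale, 1) + std::log(prop);
      if (std::log(R::unif_rand()) < ll1 - ll0) ++pacc[4 + c];
      else M.sigma[c] = old;
    }

    // --- hidden behavioural chain, then its transition probabilities
    ffbs(M);
    {
      int n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int s = 1; s < m - 1; ++s) {
        int prev = M.b[s - 1], nxt = M.b[s];
        if (prev == 0) { if (nxt == 0) ++n11; else ++n12; }
        else           { if (nxt == 0) ++n21; else ++n22; }
      }
      M.alpha[0] = R::rbeta(1.0 + n11, 1.0 + n12);
      M.alpha[1] = R::rbeta(1.0 + n21, 1.0 + n22);
    }
    // psi, lognormal(0, 1) prior, log random walk. Warm-up: for the first
    // half of burn-in psi is pinned low so the latent path tracks the data
    // closely; this exposes the rough inter-nesting step structure and keeps
    // the sampler out of the over-smoothed single-regime basin.
    if (sweep < burnin / 2) {
      M.psi = 0.3;
    } else if (sweep == burnin / 2) {
      M.psi = parinit[8];
    } else {
      double old = M.psi;
      double prop = old * std::exp(R::norm_rand() * pstep[6]);
      ++ptry[6];
      double ll0 = M.obsLogLik() + R::dnorm(std::log(old), 0.0, 1.0, 1);
      M.psi = prop;
      double ll1 = M.obsLogLik() + R::dnorm(std::log(prop), 0.0, 1.0, 1);
      if (std::log(R::unif_rand()) < ll1 - ll0) ++pacc[6];
      else M.psi = old;
    }

    // --- step-size adaptation during burn-in only
    if (sweep < burnin && (sweep + 1) % 50 == 0) {
      double ar = xtry > 0 ? (double)xacc / xtry : 0.0;
      xstep *= (ar > 0.3) ? 1.15 : 0.87;
      for (int k = 0; k < 7; ++k) {
        double pr = ptry[k] > 0 ? (double)pacc[k] / ptry[k] : 0.0;
        pstep[k] *= (pr > 0.35) ? 1.15 : 0.87;
        pacc[k] = 0; ptry[k] = 0;
      }
      xacc = 0; xtry = 0;
    }

    // --- record
    if (sweep >= burnin && (sweep - burnin) % thin == thin - 1) {
      pars(kept, 0) = M.gamma[0]; pars(kept, 1) = M.gamma[1];
      pars(kept, 2) = M.theta[0]; pars(kept, 3) = M.theta[1];
      pars(kept, 4) = M.alpha[0]; pars(kept, 5) = M.alpha[1];
      pars(kept, 6) = M.sigma[0]; pars(kept, 7) = M.sigma[1];
      pars(kept, 8) = M.psi;
      for (int s = 0; s < m - 1; ++s) bsum[s] += M.b[s] + 1; // 1 or 2
      for (int t = 0; t < m; ++t) {
        xsum(t, 0) += M.x(t, 0);
        xsum(t, 1) += M.x(t, 1);
      }
      ++kept;
    }
  }

  return List::create(
    _["pars"] = pars, _["bsum"] = bsum, _["xsum"] = xsum,
    _["nkeep"] = kept,
    _["xAccept"] = xtry > 0 ? (double)xacc / xtry : NA_REAL
  );
}
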