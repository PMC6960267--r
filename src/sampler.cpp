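// Metropolis-within-Gibbs core for the joint hierarchical model of binary
// responses and lognormal response times. Three response submodels share the
// response-time submodel and hyper-structure:
//   model 0: plain 2PL (traditional hierarchical model, M0)
//   model 1: response moderation (alpha * Z inside the 2PL linear predictor)
//   model 2: speed-accuracy tradeoff (2PL asymptote times 1 - exp(-exp(alpha*Z + zeta)))
//   model 3: response-time likelihood only (validation mode)
// All randomness comes from R's RNG so chains are reproducible from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double L2PI = 1.837877066409345483560659472811;

static inline double l1pe(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-likelihood of one response.
// eta = a*theta - b; z = standardized residual log time.
static inline double resp_ll_cell(int u, double eta, double z,
                                  double alpha, double zeta, int model) {
  switch (model) {
  case 3: return 0.0;
  case 0: return u ? -l1pe(-eta) : -l1pe(eta);
  case 1: {
    double e = eta + alpha * z;
    return u ? -l1pe(-e) : -l1pe(e);
  }
  default: {
    // P = lam * (1 - exp(-g)), g = exp(alpha*z + zeta), lam = plogis(eta)
    double arg = alpha * z + zeta;
    if (arg > 700.0) arg = 700.0;
    double g = std::exp(arg);
    if (u) {
      double ltt = (g < 1e-280) ? arg : std::log(-std::expm1(-g));
      return -l1pe(-eta) + ltt;
    }
    // 1 - P = (1 + exp(eta - g)) / (1 + exp(eta))
    return l1pe(eta - g) - l1pe(eta);
  }
  }
}

static inline double rt_ll_cell(double z, double lsig, double logt) {
  return -lsig - 0.5 * L2PI - 0.5 * z * z - logt;
}

// Summed response and response-time log-likelihoods at a fixed state.
// Used for deviance-at-posterior-mean and for cross-checks against the pure-R
// reference likelihood.
// [[Rcpp::export]]
List loglik_sums_cpp(const arma::imat& U, const arma::mat& logT,
                     const arma::imat& obs, int model,
                     const arma::vec& theta, const arma::vec& tau,
                     const arma::vec& a, const arma::vec& b,
                     const arma::vec& beta, const arma::vec& sigma,
                     const arma::vec& alpha, double zeta) {
  const int N = logT.n_rows, J = logT.n_cols;
  double rs = 0.0, ts = 0.0;
  for (int j = 0; j < J; ++j) {
    double lsig = std::log(sigma(j));
    for (int i = 0; i < N; ++i) {
      if (!obs(i, j)) continue;
      double z = (logT(i, j) - (beta(j) - tau(i))) / sigma(j);
      double eta = a(j) * theta(i) - b(j);
      rs += resp_ll_cell(U(i, j), eta, z, alpha(j), zeta, model);
      ts += rt_ll_cell(z, lsig, logT(i, j));
    }
  }
  return List::create(_["resp"] = rs, _["rt"] = ts);
}

// [[Rcpp::export]]
List sathm_chain_cpp(const arma::imat& U, const arma::mat& logT,
                     const arma::imat& obs, int model, const List& init,
                     const List& ctrl) {
  const int N = logT.n_rows, J = logT.n_cols;
  const int n_iter = as<int>(ctrl["n_iter"]);
  const int burn_in = as<int>(ctrl["burn_in"]);
  const int thin = as<int>(ctrl["thin"]);
  const bool alpha_trunc = as<bool>(ctrl["alpha_truncated"]);
  const int batch = as<int>(ctrl["adapt_batch"]);
  const double vague_var = as<double>(ctrl["vague_var"]);

  arma::vec theta = as<arma::vec>(init["theta"]), tau = as<arma::vec>(init["tau"]);
  arma::vec a = as<arma::vec>(init["a"]), b = as<arma::vec>(init["b"]);
  arma::vec beta = as<arma::vec>(init["beta"]), sigma = as<arma::vec>(init["sigma"]);
  arma::vec alpha = as<arma::vec>(init["alpha"]);
  double zeta = as<double>(init["zeta"]);
  double rho = as<double>(init["rho"]);
  arma::vec mu = as<arma::vec>(init["mu"]);
  arma::mat Sig = as<arma::mat>(init["Sigma_I"]);

  arma::vec s = 1.0 / sigma;            // sampled coordinate: reciprocal residual SD
  arma::vec lsig = arma::log(sigma);

  const bool upd_alpha = (model == 1 || model == 2);
  const bool upd_zeta = (model == 2);
  const bool upd_resp = (model != 3);
  const bool z_in_resp = (model == 1 || model == 2);

  // cached per-cell quantities at the current state
  arma::mat Z(N, J, arma::fill::zeros), eta(N, J, arma::fill::zeros);
  arma::mat rLL(N, J, arma::fill::zeros), tLL(N, J, arma::fill::zeros);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) {
      if (!obs(i, j)) continue;
      Z(i, j) = (logT(i, j) - (beta(j) - tau(i))) / sigma(j);
      eta(i, j) = a(j) * theta(i) - b(j);
      rLL(i, j) = resp_ll_cell(U(i, j), eta(i, j), Z(i, j), alpha(j), zeta, model);
      tLL(i, j) = rt_ll_cell(Z(i, j), lsig(j), logT(i, j));
    }

  // proposal scales and acceptance bookkeeping (overridable starting values;
  // adaptation during burn-in tunes them per unit)
  double s0p = ctrl.containsElementNamed("scale_person") ? as<double>(ctrl["scale_person"]) : 0.5;
  double s0ab = ctrl.containsElementNamed("scale_ab") ? as<double>(ctrl["scale_ab"]) : 0.25;
  double s0be = ctrl.containsElementNamed("scale_beta") ? as<double>(ctrl["scale_beta"]) : 0.1;
  double s0sg = ctrl.containsElementNamed("scale_sigma") ? as<double>(ctrl["scale_sigma"]) : 0.1;
  double s0al = ctrl.containsElementNamed("scale_alpha") ? as<double>(ctrl["scale_alpha"]) : 0.3;
  arma::vec sp(N); sp.fill(s0p);
  arma::vec sab(J); sab.fill(s0ab);
  arma::vec sbe(J); sbe.fill(s0be);
  arma::vec ssg(J); ssg.fill(s0sg);
  arma::vec sal(J); sal.fill(s0al);
  double szeta = ctrl.containsElementNamed("scale_zeta") ? as<double>(ctrl["scale_zeta"]) : 0.05;
  double srho = ctrl.containsElementNamed("scale_rho") ? as<double>(ctrl["scale_rho"]) : 0.05;
  arma::vec accP(N, arma::fill::zeros), accAB(J, arma::fill::zeros),
            accBE(J, arma::fill::zeros), accSG(J, arma::fill::zeros),
            accAL(J, arma::fill::zeros);
  double accZ = 0.0, accR = 0.0;
  arma::vec bP(N, arma::fill::zeros), bAB(J, arma::fill::zeros),
            bBE(J, arma::fill::zeros), bSG(J, arma::fill::zeros),
            bAL(J, arma::fill::zeros);
  double bZ = 0.0, bR = 0.0;
  int nbatch = 0;

  // draw storage
  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int P = 2 * N + 5 * J + 7;
  arma::mat out(n_keep, P);
  arma::vec devJ(n_keep), devR(n_keep);
  int keep = 0;

  // scratch buffers
  arma::vec zp(J), ep(J), rp(J), tp(J);        // person row proposals
  arma::vec epc(N), rpc(N), zpc(N), tpc(N);    // item column proposals
  arma::mat rZeta(N, J);                       // zeta proposal

  for (int it = 0; it < n_iter; ++it) {
    double om = 1.0 - rho * rho;

    // ---- persons: joint random-walk on (theta_i, tau_i) ----
    for (int i = 0; i < N; ++i) {
      double thp = theta(i) + sp(i) * norm_rand();
      double tap = tau(i) + sp(i) * norm_rand();
      double d =
        -(thp * thp - 2.0 * rho * thp * tap + tap * tap) / (2.0 * om) +
        (theta(i) * theta(i) - 2.0 * rho * theta(i) * tau(i) + tau(i) * tau(i)) / (2.0 * om);
      for (int j = 0; j < J; ++j) {
        if (!obs(i, j)) continue;
        double zq = (logT(i, j) - (beta(j) - tap)) / sigma(j);
        double eq = a(j) * thp - b(j);
        double rq = resp_ll_cell(U(i, j), eq, zq, alpha(j), zeta, model);
        double tq = rt_ll_cell(zq, lsig(j), logT(i, j));
        zp(j) = zq; ep(j) = eq; rp(j) = rq; tp(j) = tq;
        d += rq + tq - rLL(i, j) - tLL(i, j);
      }
      if (std::log(unif_rand()) < d) {
        theta(i) = thp; tau(i) = tap;
        for (int j = 0; j < J; ++j) {
          if (!obs(i, j)) continue;
          Z(i, j) = zp(j); eta(i, j) = ep(j); rLL(i, j) = rp(j); tLL(i, j) = tp(j);
        }
        accP(i) += 1.0; bP(i) += 1.0;
      }
    }

    // ---- items: joint (a_j, b_j), prior b | beta from the item MVN ----
    double s11 = Sig(0, 0), s12 = Sig(0, 1), s22 = Sig(1, 1);
    double vb = s11 - s12 * s12 / s22;
    double vbe = s22 - s12 * s12 / s11;
    for (int j = 0; j < J; ++j) {
      double ap = a(j) + sab(j) * norm_rand();
      double bp = b(j) + sab(j) * norm_rand();
      if (ap <= 0.0) continue;
      double mb = mu(0) + s12 / s22 * (beta(j) - mu(1));
      double d = -0.5 * ap * ap + 0.5 * a(j) * a(j)
        - (bp - mb) * (bp - mb) / (2.0 * vb)
        + (b(j) - mb) * (b(j) - mb) / (2.0 * vb);
      if (upd_resp) {
        for (int i = 0; i < N; ++i) {
          if (!obs(i, j)) continue;
          double eq = ap * theta(i) - bp;
          double rq = resp_ll_cell(U(i, j), eq, Z(i, j), alpha(j), zeta, model);
          epc(i) = eq; rpc(i) = rq;
          d += rq - rLL(i, j);
        }
      }
      if (std::log(unif_rand()) < d) {
        a(j) = ap; b(j) = bp;
        if (upd_resp)
          for (int i = 0; i < N; ++i) {
            if (!obs(i, j)) continue;
            eta(i, j) = epc(i); rLL(i, j) = rpc(i);
          }
        accAB(j) += 1.0; bAB(j) += 1.0;
      }
    }

    // ---- items: beta_j (time intensity), prior beta | b ----
    for (int j = 0; j < J; ++j) {
      double bep = beta(j) + sbe(j) * norm_rand();
      double mbe = mu(1) + s12 / s11 * (b(j) - mu(0));
      double d = -(bep - mbe) * (bep - mbe) / (2.0 * vbe)
        + (beta(j) - mbe) * (beta(j) - mbe) / (2.0 * vbe);
      for (int i = 0; i < N; ++i) {
        if (!obs(i, j)) continue;
        double zq = (logT(i, j) - (bep - tau(i))) / sigma(j);
        double tq = rt_ll_cell(zq, lsig(j), logT(i, j));
        double rq = z_in_resp
          ? resp_ll_cell(U(i, j), eta(i, j), zq, alpha(j), zeta, model)
          : rLL(i, j);
        zpc(i) = zq; tpc(i) = tq; rpc(i) = rq;
        d += rq + tq - rLL(i, j) - tLL(i, j);
      }
      if (std::log(unif_rand()) < d) {
        beta(j) = bep;
        for (int i = 0; i < N; ++i) {
          if (!obs(i, j)) continue;
          Z(i, j) = zpc(i); tLL(i, j) = tpc(i); rLL(i, j) = rpc(i);
        }
        accBE(j) += 1.0; bBE(j) += 1.0;
      }
    }

    // ---- items: 1/sigma_j via log-scale random walk (scale-free moves) ----
    for (int j = 0; j < J; ++j) {
      double ssp = s(j) * std::exp(ssg(j) * norm_rand());
      double sigp = 1.0 / ssp, lsp = -std::log(ssp);
      // log-normal proposal: Jacobian term log(ssp/s)
      double d = std::log(ssp / s(j))
        - 0.5 * ssp * ssp + 0.5 * s(j) * s(j);
      for (int i = 0; i < N; ++i) {
        if (!obs(i, j)) continue;
        double zq = (logT(i, j) - (beta(j) - tau(i))) * ssp;
        double tq = rt_ll_cell(zq, lsp, logT(i, j));
        double rq = z_in_resp
          ? resp_ll_cell(U(i, j), eta(i, j), zq, alpha(j), zeta, model)
          : rLL(i, j);
        zpc(i) = zq; tpc(i) = tq; rpc(i) = rq;
        d += rq + tq - rLL(i, j) - tLL(i, j);
      }
      if (std::log(unif_rand()) < d) {
        s(j) = ssp; sigma(j) = sigp; lsig(j) = lsp;
        for (int i = 0; i < N; ++i) {
          if (!obs(i, j)) continue;
          Z(i, j) = zpc(i); tLL(i, j) = tpc(i); rLL(i, j) = rpc(i);
        }
        accSG(j) += 1.0; bSG(j) += 1.0;
      }
    }

    // ---- items: alpha_j (residual-time slope) ----
    if (upd_alpha) {
      for (int j = 0; j < J; ++j) {
        double alp = alpha(j) + sal(j) * norm_rand();
        if (alpha_trunc && alp <= 0.0) continue;
        double d = -0.5 * alp * alp + 0.5 * alpha(j) * alpha(j);
        for (int i = 0; i < N; ++i) {
          if (!obs(i, j)) continue;
          double rq = resp_ll_cell(U(i, j), eta(i, j), Z(i, j), alp, zeta, model);
          rpc(i) = rq;
          d += rq - rLL(i, j);
        }
        if (std::log(unif_rand()) < d) {
          alpha(j) = alp;
          for (int i = 0; i < N; ++i) {
            if (!obs(i, j)) continue;
            rLL(i, j) = rpc(i);
          }
          accAL(j) += 1.0; bAL(j) += 1.0;
        }
      }
    }

    // ---- zeta (test-level residual-time intercept) ----
    if (upd_zeta) {
      double zep = zeta + szeta * norm_rand();
      double d = -0.5 * zep * zep + 0.5 * zeta * zeta;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < N; ++i) {
          if (!obs(i, j)) continue;
          double rq = resp_ll_cell(U(i, j), eta(i, j), Z(i, j), alpha(j), zep, model);
          rZeta(i, j) = rq;
          d += rq - rLL(i, j);
        }
      if (std::log(unif_rand()) < d) {
        zeta = zep;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < N; ++i)
            if (obs(i, j)) rLL(i, j) = rZeta(i, j);
        accZ += 1.0; bZ += 1.0;
      }
    }

    // ---- rho (ability-speed correlation), doubly truncated prior ----
    {
      double rpp = rho + srho * norm_rand();
      if (std::abs(rpp) < 1.0) {
        double Stt = arma::dot(theta, theta), Stu = arma::dot(theta, tau),
               Suu = arma::dot(tau, tau);
        double o0 = 1.0 - rho * rho, o1 = 1.0 - rpp * rpp;
        double l0 = -0.5 * N * std::log(o0) - (Stt - 2.0 * rho * Stu + Suu) / (2.0 * o0)
                    - 0.5 * rho * rho;
        double l1 = -0.5 * N * std::log(o1) - (Stt - 2.0 * rpp * Stu + Suu) / (2.0 * o1)
                    - 0.5 * rpp * rpp;
        if (std::log(unif_rand()) < l1 - l0) { rho = rpp; accR += 1.0; bR += 1.0; }
      }
    }

    // ---- (mu_b, mu_beta): conjugate normal update ----
    {
      arma::mat Sinv = arma::inv_sympd(Sig);
      arma::mat Lam = (double)J * Sinv;
      Lam(0, 0) += 1.0 / vague_var; Lam(1, 1) += 1.0 / vague_var;
      arma::mat V = arma::inv_sympd(Lam);
      arma::vec xs(2);
      xs(0) = arma::accu(b); xs(1) = arma::accu(beta);
      arma::vec mpost = V * (Sinv * xs);
      arma::mat Lv = arma::chol(V, "lower");
      arma::vec zz(2); zz(0) = norm_rand(); zz(1) = norm_rand();
      mu = mpost + Lv * zz;
    }

    // ---- Sigma_I: conjugate inverse-Wishart update ----
    {
      arma::mat Smat(2, 2, arma::fill::zeros);
      for (int j = 0; j < J; ++j) {
        arma::vec dj(2); dj(0) = b(j) - mu(0); dj(1) = beta(j) - mu(1);
        Smat += dj * dj.t();
      }
      arma::mat Psi = Smat;
      Psi(0, 0) += 1.0; Psi(1, 1) += 1.0;
      double df = 2.0 + (double)J;
      arma::mat Vw = arma::inv_sympd(Psi);
      arma::mat Lw = arma::chol(Vw, "lower");
      arma::mat A(2, 2, arma::fill::zeros);
      A(0, 0) = std::sqrt(R::rchisq(df));
      A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
      A(1, 0) = norm_rand();
      arma::mat LA = Lw * A;
      Sig = arma::inv_sympd(LA * LA.t());
    }

    // ---- proposal-scale adaptation during burn-in ----
    if (batch > 0 && ((it + 1) % batch) == 0 && (it + 1) <= burn_in) {
      ++nbatch;
      double del = std::min(0.05, 1.0 / std::sqrt((double)nbatch));
      double inv = 1.0 / (double)batch;
      for (int i = 0; i < N; ++i) {
        sp(i) *= std::exp(bP(i) * inv > 0.35 ? del : -del); bP(i) = 0.0;
      }
      for (int j = 0; j < J; ++j) {
        sab(j) *= std::exp(bAB(j) * inv > 0.35 ? del : -del); bAB(j) = 0.0;
        sbe(j) *= std::exp(bBE(j) * inv > 0.44 ? del : -del); bBE(j) = 0.0;
        ssg(j) *= std::exp(bSG(j) * inv > 0.44 ? del : -del); bSG(j) = 0.0;
        sal(j) *= std::exp(bAL(j) * inv > 0.44 ? del : -del); bAL(j) = 0.0;
      }
      szeta *= std::exp(bZ * inv > 0.44 ? del : -del); bZ = 0.0;
      srho *= std::exp(bR * inv > 0.44 ? del : -del); bR = 0.0;
    }

    // ---- store ----
    if (it >= burn_in && ((it - burn_in) % thin) == 0) {
      int k = 0;
      for (int i = 0; i < N; ++i) out(keep, k++) = theta(i);
      for (int i = 0; i < N; ++i) out(keep, k++) = tau(i);
      for (int j = 0; j < J; ++j) out(keep, k++) = a(j);
      for (int j = 0; j < J; ++j) out(keep, k++) = b(j);
      for (int j = 0; j < J; ++j) out(keep, k++) = beta(j);
      for (int j = 0; j < J; ++j) out(keep, k++) = sigma(j);
      for (int j = 0; j < J; ++j) out(keep, k++) = alpha(j);
      out(keep, k++) = zeta; out(keep, k++) = rho;
      out(keep, k++) = mu(0); out(keep, k++) = mu(1);
      out(keep, k++) = Sig(0, 0); out(keep, k++) = Sig(0, 1); out(keep, k++) = Sig(1, 1);
      double rs = arma::accu(rLL), ts = arma::accu(tLL);
      devJ(keep) = -2.0 * (rs + ts);
      devR(keep) = -2.0 * rs;
      ++keep;
    }

    if ((it % 500) == 0) Rcpp::checkUserInterrupt();
  }

  double ni = (double)n_iter;
  return List::create(
    _["draws"] = out,
    _["dev_joint"] = devJ,
    _["dev_resp"] = devR,
    _["accept"] = List::create(
      _["person"] = arma::mean(accP) / ni,
      _["item_ab"] = arma::mean(accAB) / ni,
      _["item_beta"] = arma::mean(accBE) / ni,
      _["item_sigma"] = arma::mean(accSG) / ni,
      _["item_alpha"] = upd_alpha ? arma::mean(accAL) / ni : NA_REAL,
      _["zeta"] = upd_zeta ? accZ / ni : NA_REAL,
      _["rho"] = accR / ni));
}
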