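#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Geometry helpers for Queen/Rook contiguity detection
// ---------------------------------------------------------------------------

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// distance from point p to segment [a, b]
static double point_seg_dist(double px, double py, double ax, double ay,
                             double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double wx = px - ax, wy = py - ay;
  double vv = vx * vx + vy * vy;
  double t = vv > 0.0 ? (wx * vx + wy * vy) / vv : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
  return std::sqrt(dx * dx + dy * dy);
}

static double seg_seg_dist(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  // proper intersection => distance zero
  double d1 = cross2(dx - cx, dy - cy, ax - cx, ay - cy);
  double d2 = cross2(dx - cx, dy - cy, bx - cx, by - cy);
  double d3 = cross2(bx - ax, by - ay, cx - ax, cy - ay);
  double d4 = cross2(bx - ax, by - ay, dx - ax, dy - ay);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return 0.0;
  double m = point_seg_dist(ax, ay, cx, cy, dx, dy);
  m = std::min(m, point_seg_dist(bx, by, cx, cy, dx, dy));
  m = std::min(m, point_seg_dist(cx, cy, ax, ay, bx, by));
  m = std::min(m, point_seg_dist(dx, dy, ax, ay, bx, by));
  return m;
}

// shared collinear overlap length between segments (0 if not collinear)
static double collinear_overlap(double ax, double ay, double bx, double by,
                                double cx, double cy, double dx, double dy,
                                double tol) {
  double vx = bx - ax, vy = by - ay;
  double len = std::sqrt(vx * vx + vy * vy);
  if (len < tol) return 0.0;
  vx /= len; vy /= len;
  // both endpoints of cd must lie on line ab
  if (std::fabs(cross2(vx, vy, cx - ax, cy - ay)) > tol ||
      std::fabs(cross2(vx, vy, dx - ax, dy - ay)) > tol)
    return 0.0;
  double t0 = 0.0, t1 = len;
  double s0 = (cx - ax) * vx + (cy - ay) * vy;
  double s1 = (dx - ax) * vx + (dy - ay) * vy;
  if (s0 > s1) std::swap(s0, s1);
  double lo = std::max(t0, s0), hi = std::min(t1, s1);
  return hi > lo ? hi - lo : 0.0;
}

// [[Rcpp::export]]
bool cpp_segments_touch(NumericMatrix A, NumericMatrix B, double tol,
                        bool rook) {
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      if (rook) {
        if (collinear_overlap(A(i, 0), A(i, 1), A(i, 2), A(i, 3),
                              B(j, 0), B(j, 1), B(j, 2), B(j, 3), tol) > tol)
          return true;
      } else {
        if (seg_seg_dist(A(i, 0), A(i, 1), A(i, 2), A(i, 3),
                         B(j, 0), B(j, 1), B(j, 2), B(j, 3)) <= tol)
          return true;
      }
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Shared MCMC pieces
// ---------------------------------------------------------------------------

// numerically stable log(1 + exp(x))
static inline double stable_log1pexp(double x) {
  return x > 0.0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// CAR quadratic form: rho * sum_{i~j, i<j} (u_i - u_j)^2 + (1-rho) * sum u^2
static double car_quadform(const std::vector<double>& u,
                           const std::vector<std::vector<int> >& nb,
                           double rho) {
  double qpair = 0.0, ssq = 0.0;
  int n = u.size();
  for (int j = 0; j < n; ++j) {
    ssq += u[j] * u[j];
    for (size_t k = 0; k < nb[j].size(); ++k) {
      int i = nb[j][k];
      if (i > j) {
        double d = u[j] - u[i];
        qpair += d * d;
      }
    }
  }
  return rho * qpair + (1.0 - rho) * ssq;
}

// one conjugate draw of tau^2 given the CAR quadratic form: the precision
// 1/tau^2 has a gamma(alpha + nstar/2, beta + Q/2) full conditional
static double draw_tau2(double Q, int nstar, double alpha, double beta) {
  double shape = alpha + 0.5 * nstar;
  double rate = beta + 0.5 * Q;
  double prec = R::rgamma(shape, 1.0 / rate);
  return 1.0 / prec;
}

// exported so the conjugate step can be exercised in isolation at fixed u
// (same code path the samplers use)
// [[Rcpp::export]]
NumericVector cpp_tau2_gibbs_draws(NumericVector u, List adj, double rho,
                                   double alpha, double beta, int nstar,
                                   int ndraws) {
  int n = u.size();
  std::vector<std::vector<int> > nb(n);
  for (int j = 0; j < n; ++j) nb[j] = as<std::vector<int> >(adj[j]);
  std::vector<double> uu(u.begin(), u.end());
  double Q = car_quadform(uu, nb, rho);
  NumericVector out(ndraws);
  for (int s = 0; s < ndraws; ++s) out[s] = draw_tau2(Q, nstar, alpha, beta);
  return out;
}

static std::vector<std::vector<int> > adj_to_nb(List adj) {
  int n = adj.size();
  std::vector<std::vector<int> > nb(n);
  for (int j = 0; j < n; ++j) nb[j] = as<std::vector<int> >(adj[j]);
  return nb;
}

struct Adapt {
  double sd;
  int acc, att;
  Adapt(double s) : sd(s), acc(0), att(0) {}
  void tune() {
    if (att == 0) return;
    double rate = double(acc) / att;
    if (rate > 0.5) sd *= 1.15;
    else if (rate < 0.3) sd /= 1.15;
    if (sd < 1e-4) sd = 1e-4;
    if (sd > 5.0) sd = 5.0;
    acc = 0; att = 0;
  }
};

// ---------------------------------------------------------------------------
// Binomial logistic CAR sampler (Leroux / BYM / ICAR-only / iid-only)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_binomial_car_mcmc(NumericVector y, NumericVector N, NumericMatrix X,
                           List adj,
                           double alpha_u, double beta_u,
                           double alpha_v, double beta_v,
                           double beta_prior_sd,
                           NumericVector offset,
                           NumericVector lambda,
                           bool has_u, bool has_v, bool rho_free,
                           double rho_init, int nstar_icar,
                           int n_iter, int burn_in, int thin) {
  int n = y.size(), p = X.ncol();
  std::vector<std::vector<int> > nb = adj_to_nb(adj);
  std::vector<bool> obs(n);
  for (int r = 0; r < n; ++r) obs[r] = !NumericVector::is_na(y[r]) && N[r] > 0;

  // state
  std::vector<double> beta(p, 0.0), u(n, 0.0), v(n, 0.0), eta(n);
  double tau2_u = 0.1, tau2_v = 0.1;
  double rho = rho_free ? rho_init : (has_u ? 1.0 : 0.0);
  // initialize intercept at the pooled logit prevalence
  {
    double sy = 0.0, sN = 0.0;
    for (int r = 0; r < n; ++r) if (obs[r]) { sy += y[r]; sN += N[r]; }
    double pbar = (sy + 0.5) / (sN + 1.0);
    beta[0] = std::log(pbar / (1.0 - pbar));
  }
  for (int r = 0; r < n; ++r) {
    eta[r] = offset[r];
    for (int j = 0; j < p; ++j) eta[r] += X(r, j) * beta[j];
  }

  double bp2 = beta_prior_sd * beta_prior_sd;
  std::vector<Adapt> ad_beta(p, Adapt(0.05));
  Adapt ad_u(0.1), ad_v(0.1), ad_rho(0.5), ad_su(0.1), ad_sv(0.05);

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix keep_beta(n_keep, p), keep_u(n_keep, n), keep_v(n_keep, n);
  NumericVector keep_t2u(n_keep), keep_t2v(n_keep), keep_rho(n_keep);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // --- fixed effects: component-wise random-walk Metropolis
    for (int j = 0; j < p; ++j) {
      double prop = beta[j] + ad_beta[j].sd * norm_rand();
      double diff = prop - beta[j];
      double dlp = -(prop * prop - beta[j] * beta[j]) / (2.0 * bp2);
      for (int r = 0; r < n; ++r) {
        if (!obs[r]) continue;
        double e1 = eta[r] + X(r, j) * diff;
        dlp += y[r] * (e1 - eta[r]) - N[r] * (stable_log1pexp(e1) - stable_log1pexp(eta[r]));
      }
      ad_beta[j].att++;
      if (std::log(unif_rand()) < dlp) {
        for (int r = 0; r < n; ++r) eta[r] += X(r, j) * diff;
        beta[j] = prop;
        ad_beta[j].acc++;
      }
    }

    // --- structured effects: single-site Metropolis on the Leroux/ICAR
    //     full conditional (prior part) times the region's likelihood
    if (has_u) {
      for (int j = 0; j < n; ++j) {
        double dj = nb[j].size();
        double S = 0.0;
        for (size_t k = 0; k < nb[j].size(); ++k) S += u[nb[j][k]];
        double denom = rho * dj + (1.0 - rho);
        double m = rho * S / denom;
        double prec = denom / tau2_u;
        double prop = u[j] + ad_u.sd * norm_rand();
        double dlp = -0.5 * prec * ((prop - m) * (prop - m) -
                                    (u[j] - m) * (u[j] - m));
        if (obs[j]) {
          double e1 = eta[j] + (prop - u[j]);
          dlp += y[j] * (e1 - eta[j]) -
                 N[j] * (stable_log1pexp(e1) - stable_log1pexp(eta[j]));
        }
        ad_u.att++;
        if (std::log(unif_rand()) < dlp) {
          eta[j] += prop - u[j];
          u[j] = prop;
          ad_u.acc++;
        }
      }
      // ICAR impropriety: recentre u, absorb the shift in the intercept
      if (!rho_free) {
        double mbar = 0.0;
        for (int j = 0; j < n; ++j) mbar += u[j];
        mbar /= n;
        for (int j = 0; j < n; ++j) u[j] -= mbar;
        beta[0] += mbar; // X column 0 is the intercept, eta unchanged
      }
      double Q = car_quadform(u, nb, rho);
      int nstar = rho_free ? n : nstar_icar;
      tau2_u = draw_tau2(Q, nstar, alpha_u, beta_u);
    }

    // --- unstructured effects
    if (has_v) {
      for (int j = 0; j < n; ++j) {
        double prop = v[j] + ad_v.sd * norm_rand();
        double dlp = -(prop * prop - v[j] * v[j]) / (2.0 * tau2_v);
        if (obs[j]) {
          double e1 = eta[j] + (prop - v[j]);
          dlp += y[j] * (e1 - eta[j]) -
                 N[j] * (stable_log1pexp(e1) - stable_log1pexp(eta[j]));
        }
        ad_v.att++;
        if (std::log(unif_rand()) < dlp) {
          eta[j] += prop - v[j];
          v[j] = prop;
          ad_v.acc++;
        }
      }
      double ssv = 0.0;
      for (int j = 0; j < n; ++j) ssv += v[j] * v[j];
      tau2_v = draw_tau2(ssv, n, alpha_v, beta_v);
    }

    // --- interweaving shift moves: (beta0 + d, u - d) and (beta0 + d, v - d)
    //     leave the likelihood invariant and traverse the level-identifiability
    //     ridge between the intercept and the random-effect mean
    if (has_u && rho_free) {
      double d = ad_su.sd * norm_rand();
      double su = 0.0, ssq_delta = 0.0;
      for (int j = 0; j < n; ++j) su += u[j];
      ssq_delta = n * d * d - 2.0 * d * su; // sum((u-d)^2) - sum(u^2)
      double b0p = beta[0] + d;
      double dlp = -(1.0 - rho) * ssq_delta / (2.0 * tau2_u) -
                   (b0p * b0p - beta[0] * beta[0]) / (2.0 * bp2);
      ad_su.att++;
      if (std::log(unif_rand()) < dlp) {
        for (int j = 0; j < n; ++j) u[j] -= d;
        beta[0] = b0p;
        ad_su.acc++;
      }
    }
    if (has_v) {
      double d = ad_sv.sd * norm_rand();
      double sv = 0.0;
      for (int j = 0; j < n; ++j) sv += v[j];
      double ssq_delta = n * d * d - 2.0 * d * sv;
      double b0p = beta[0] + d;
      double dlp = -ssq_delta / (2.0 * tau2_v) -
                   (b0p * b0p - beta[0] * beta[0]) / (2.0 * bp2);
      ad_sv.att++;
      if (std::log(unif_rand()) < dlp) {
        for (int j = 0; j < n; ++j) v[j] -= d;
        beta[0] = b0p;
        ad_sv.acc++;
      }
    }

    // --- Leroux mixing parameter: Metropolis on logit(rho), uniform prior
    if (has_u && rho_free) {
      double lr = std::log(rho / (1.0 - rho));
      double lrp = lr + ad_rho.sd * norm_rand();
      double rp = 1.0 / (1.0 + std::exp(-lrp));
      double Qc = car_quadform(u, nb, rho);
      double Qp = car_quadform(u, nb, rp);
      double dlp = -(Qp - Qc) / (2.0 * tau2_u);
      for (int i = 0; i < n; ++i)
        dlp += 0.5 * (std::log(rp * lambda[i] + 1.0 - rp) -
                      std::log(rho * lambda[i] + 1.0 - rho));
      // Jacobian of the logit transform
      dlp += std::log(rp) + std::log(1.0 - rp) -
             std::log(rho) - std::log(1.0 - rho);
      ad_rho.att++;
      if (std::log(unif_rand()) < dlp) { rho = rp; ad_rho.acc++; }
    }

    // --- adaptation, frozen after burn-in to preserve detailed balance
    if (it <= burn_in && it % 50 == 0) {
      for (int j = 0; j < p; ++j) ad_beta[j].tune();
      ad_u.tune(); ad_v.tune(); ad_rho.tune(); ad_su.tune(); ad_sv.tune();
    }
    if (it == burn_in) {
      for (int j = 0; j < p; ++j) { ad_beta[j].acc = 0; ad_beta[j].att = 0; }
      ad_u.acc = ad_u.att = 0; ad_v.acc = ad_v.att = 0;
      ad_rho.acc = ad_rho.att = 0;
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) keep_beta(kept, j) = beta[j];
      for (int j = 0; j < n; ++j) { keep_u(kept, j) = u[j]; keep_v(kept, j) = v[j]; }
      keep_t2u[kept] = tau2_u;
      keep_t2v[kept] = tau2_v;
      keep_rho[kept] = rho;
      ++kept;
    }
  }

  NumericVector acc = NumericVector::create(
    _["beta"] = ad_beta[0].att ? double(ad_beta[0].acc) / ad_beta[0].att : NA_REAL,
    _["u"] = ad_u.att ? double(ad_u.acc) / ad_u.att : NA_REAL,
    _["v"] = ad_v.att ? double(ad_v.acc) / ad_v.att : NA_REAL,
    _["rho"] = ad_rho.att ? double(ad_rho.acc) / ad_rho.att : NA_REAL);

  return List::create(_["beta"] = keep_beta, _["u"] = keep_u, _["v"] = keep_v,
                      _["tau2_u"] = keep_t2u, _["tau2_v"] = keep_t2v,
                      _["rho"] = keep_rho, _["acceptance"] = acc,
                      _["n_kept"] = kept);
}

// ---------------------------------------------------------------------------
// Gaussian BYM smoother (all-Gibbs), used for covariate imputation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gaussian_bym_mcmc(NumericVector yobs, List adj,
                           double alpha_u, double beta_u,
                           double alpha_v, double beta_v,
                           double alpha_e, double beta_e,
                           double intercept_prior_sd, int nstar_icar,
                           int n_iter, int burn_in, int thin) {
  int n = yobs.size();
  std::vector<std::vector<int> > nb = adj_to_nb(adj);
  std::vector<bool> obs(n);
  int n_obs = 0;
  double ybar = 0.0;
  for (int r = 0; r < n; ++r) {
    obs[r] = !NumericVector::is_na(yobs[r]);
    if (obs[r]) { ++n_obs; ybar += yobs[r]; }
  }
  if (n_obs > 0) ybar /= n_obs;

  double alpha = ybar, tau2_u = 0.5, tau2_v = 0.5, sig2e = 0.5;
  std::vector<double> u(n, 0.0), v(n, 0.0);
  double a_prec0 = 1.0 / (intercept_prior_sd * intercept_prior_sd);

  std::vector<double> surf_sum(n, 0.0), surf_ssq(n, 0.0);
  int n_keep = (n_iter - burn_in) / thin;
  NumericVector keep_alpha(n_keep), keep_t2u(n_keep), keep_t2v(n_keep),
      keep_s2e(n_keep);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    {
      double prec = n_obs / sig2e + a_prec0, num = 0.0;
      for (int r = 0; r < n; ++r)
        if (obs[r]) num += (yobs[r] - u[r] - v[r]) / sig2e;
      alpha = num / prec + norm_rand() / std::sqrt(prec);
    }
    // structured effects (ICAR), conjugate single-site draws
    for (int j = 0; j < n; ++j) {
      double dj = nb[j].size();
      double S = 0.0;
      for (size_t k = 0; k < nb[j].size(); ++k) S += u[nb[j][k]];
      double prec = dj / tau2_u, num = S / tau2_u;
      if (obs[j]) {
        prec += 1.0 / sig2e;
        num += (yobs[j] - alpha - v[j]) / sig2e;
      }
      u[j] = num / prec + norm_rand() / std::sqrt(prec);
    }
    {
      double mbar = 0.0;
      for (int j = 0; j < n; ++j) mbar += u[j];
      mbar /= n;
      for (int j = 0; j < n; ++j) u[j] -= mbar;
      alpha += mbar;
    }
    // unstructured effects
    for (int j = 0; j < n; ++j) {
      double prec = 1.0 / tau2_v, num = 0.0;
      if (obs[j]) {
        prec += 1.0 / sig2e;
        num += (yobs[j] - alpha - u[j]) / sig2e;
      }
      v[j] = num / prec + norm_rand() / std::sqrt(prec);
    }
    // variances
    tau2_u = draw_tau2(car_quadform(u, nb, 1.0), nstar_icar, alpha_u, beta_u);
    double ssv = 0.0;
    for (int j = 0; j < n; ++j) ssv += v[j] * v[j];
    tau2_v = draw_tau2(ssv, n, alpha_v, beta_v);
    double sse = 0.0;
    for (int r = 0; r < n; ++r) {
      if (!obs[r]) continue;
      double e = yobs[r] - alpha - u[r] - v[r];
      sse += e * e;
    }
    sig2e = draw_tau2(sse, n_obs, alpha_e, beta_e);

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int r = 0; r < n; ++r) {
        double s = alpha + u[r] + v[r];
        surf_sum[r] += s;
        surf_ssq[r] += s * s;
      }
      keep_alpha[kept] = alpha;
      keep_t2u[kept] = tau2_u;
      keep_t2v[kept] = tau2_v;
      keep_s2e[kept] = sig2e;
      ++kept;
    }
  }

  NumericVector mean(n), sdv(n);
  for (int r = 0; r < n; ++r) {
    mean[r] = surf_sum[r] / kept;
    double vv = surf_ssq[r] / kept - mean[r] * mean[r];
    sdv[r] = vv > 0 ? std::sqrt(vv * kept / (kept - 1.0)) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sdv,
                      _["alpha"] = keep_alpha, _["tau2_u"] = keep_t2u,
                      _["tau2_v"] = keep_t2v, _["sigma2_e"] = keep_s2e,
                      _["n_kept"] = kept);
}
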