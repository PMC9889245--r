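#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Poisson log-likelihood kernel for one cell, dropping the lgamma(y+1)
// constant (it cancels in every Metropolis ratio).
static inline double cell_ll(double y, double eta) {
  return y * eta - std::exp(eta);
}

// Random-walk-1 prior sum-of-squares contribution of position t in a path,
// evaluated at candidate value v.
static inline double rw1_terms(const std::vector<double>& x, int t, int T, double v) {
  double s = 0.0;
  if (t > 0)     { double d = v - x[t - 1]; s += d * d; }
  if (t < T - 1) { double d = x[t + 1] - v; s += d * d; }
  return s;
}

// Metropolis-within-Gibbs sampler for the space-time Poisson lognormal model
//   log mu_it = alpha + X_it beta + phi_i + xi_t + delta_it
// with an ICAR (or iid) prior on phi, RW1 on xi, and independent per-area
// RW1 interactions delta constrained to sum to zero over time within each
// area.  Uses R's RNG, so set.seed() on the R side gives reproducibility.
//
// Cell order throughout: c = i + N*t (area fastest).
// [[Rcpp::export]]
List stcar_mcmc_cpp(IntegerMatrix y, NumericMatrix X, List nb,
                    int n_isolated, int rank_phi,
                    int n_burnin, int n_keep, int thin,
                    bool inc_spatial, bool inc_temporal, bool inc_interaction,
                    bool iid_spatial, bool prior_only,
                    double prior_shape, double prior_rate, double beta_var,
                    bool fix_var_phi, bool fix_var_xi, bool fix_var_delta,
                    double var_phi0, double var_xi0, double var_delta0,
                    double alpha0, NumericVector beta0, NumericVector phi0,
                    NumericVector xi0, NumericMatrix delta0,
                    NumericMatrix prop_chol, NumericVector prop_scales,
                    bool adapt,
                    bool upd_ab, bool upd_phi, bool upd_xi, bool upd_delta,
                    bool upd_vars, double eta_bound) {
  const int N = y.nrow(), T = y.ncol(), P = X.ncol(), NT = N * T;
  const int n_iter = n_burnin + n_keep * thin;

  // ---- state ----
  double alpha = alpha0;
  std::vector<double> beta(P), phi(N), xi(T), delta(NT), xb(NT), yv(NT);
  for (int p = 0; p < P; ++p) beta[p] = beta0[p];
  for (int i = 0; i < N; ++i) phi[i] = phi0[i];
  for (int t = 0; t < T; ++t) xi[t] = xi0[t];
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) delta[i + N * t] = delta0(i, t);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) yv[i + N * t] = (double) y(i, t);
  for (int c = 0; c < NT; ++c) {
    double s = 0.0;
    for (int p = 0; p < P; ++p) s += X(c, p) * beta[p];
    xb[c] = s;
  }
  double var_phi = var_phi0, var_xi = var_xi0, var_delta = var_delta0;

  // neighbour structure and unique edge list (for the ICAR quadratic form)
  std::vector< std::vector<int> > nbr(N);
  for (int i = 0; i < N; ++i) nbr[i] = as< std::vector<int> >(nb[i]);
  std::vector<int> e1, e2;
  for (int i = 0; i < N; ++i)
    for (size_t k = 0; k < nbr[i].size(); ++k)
      if (nbr[i][k] > i) { e1.push_back(i); e2.push_back(nbr[i][k]); }
  // global recentring of phi is an exact move only when the ICAR prior is
  // invariant to a constant shift, i.e. no isolated areas under iid priors
  const bool centre_phi = inc_spatial && !iid_spatial && (n_isolated == 0);

  // ---- proposal scales: 0 = (alpha,beta) block, 1 = phi, 2 = xi, 3 = delta
  double s_ab = prop_scales[0], s_phi = prop_scales[1],
         s_xi = prop_scales[2], s_de = prop_scales[3];
  double acc[4] = {0, 0, 0, 0}, att[4] = {0, 0, 0, 0};
  double acc_b[4] = {0, 0, 0, 0}, att_b[4] = {0, 0, 0, 0};  // per-batch
  const int batch = 50;
  int n_batch = 0;

  // ---- storage ----
  NumericVector out_alpha(n_keep), out_vphi(n_keep), out_vxi(n_keep), out_vde(n_keep);
  NumericMatrix out_beta(n_keep, P), out_phi(n_keep, N), out_xi(n_keep, T);
  NumericMatrix out_delta(n_keep, inc_interaction ? NT : 0);

  std::vector<double> beta_new(P), xb_new(NT), z(P + 1), step(P + 1);
  int keep = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- (alpha, beta) joint block, multivariate normal proposal ----
    if (upd_ab) {
      for (int k = 0; k <= P; ++k) z[k] = norm_rand();
      for (int r = 0; r <= P; ++r) {
        double s = 0.0;
        for (int k = 0; k <= r; ++k) s += prop_chol(r, k) * z[k];
        step[r] = s_ab * s;
      }
      double alpha_new = alpha + step[0];
      for (int p = 0; p < P; ++p) beta_new[p] = beta[p] + step[1 + p];
      bool ok = true;
      double dll = 0.0;
      for (int c = 0; c < NT; ++c) {
        double s = 0.0;
        for (int p = 0; p < P; ++p) s += X(c, p) * beta_new[p];
        xb_new[c] = s;
      }
      if (!prior_only) {
        for (int t = 0; t < T && ok; ++t) {
          for (int i = 0; i < N; ++i) {
            int c = i + N * t;
            double rest = phi[i] + xi[t] + delta[c];
            double en = alpha_new + xb_new[c] + rest;
            if (std::fabs(en) > eta_bound) { ok = false; break; }
            dll += cell_ll(yv[c], en) - cell_ll(yv[c], alpha + xb[c] + rest);
          }
        }
      }
      double dpr = 0.0;
      for (int p = 0; p < P; ++p)
        dpr += (beta[p] * beta[p] - beta_new[p] * beta_new[p]) / (2.0 * beta_var);
      att[0] += 1; att_b[0] += 1;
      if (ok && std::log(unif_rand()) < dll + dpr) {
        alpha = alpha_new; beta = beta_new; xb = xb_new;
        acc[0] += 1; acc_b[0] += 1;
      }
    }

    // ---- phi: single-site random-walk Metropolis ----
    if (inc_spatial && upd_phi) {
      for (int i = 0; i < N; ++i) {
        int ni = (int) nbr[i].size();
        double m = 0.0, v;
        if (iid_spatial || ni == 0) {
          v = var_phi;
        } else {
          for (int k = 0; k < ni; ++k) m += phi[nbr[i][k]];
          m /= ni; v = var_phi / ni;
        }
        double pn = phi[i] + s_phi * norm_rand();
        bool ok = true;
        double dll = 0.0;
        if (!prior_only) {
          for (int t = 0; t < T; ++t) {
            int c = i + N * t;
            double base = alpha + xb[c] + xi[t] + delta[c];
            double en = base + pn;
            if (std::fabs(en) > eta_bound) { ok = false; break; }
            dll += cell_ll(yv[c], en) - cell_ll(yv[c], base + phi[i]);
          }
        }
        double d0 = phi[i] - m, d1 = pn - m;
        double dpr = (d0 * d0 - d1 * d1) / (2.0 * v);
        att[1] += 1; att_b[1] += 1;
        if (ok && std::log(unif_rand()) < dll + dpr) {
          phi[i] = pn; acc[1] += 1; acc_b[1] += 1;
        }
      }
      if (centre_phi) {  // exact: flat-prior alpha absorbs the free level
        double m = 0.0;
        for (int i = 0; i < N; ++i) m += phi[i];
        m /= N;
        for (int i = 0; i < N; ++i) phi[i] -= m;
        alpha += m;
      }
    }

    // ---- xi: single-site random-walk Metropolis ----
    if (inc_temporal && upd_xi) {
      for (int t = 0; t < T; ++t) {
        double xn = xi[t] + s_xi * norm_rand();
        bool ok = true;
        double dll = 0.0;
        if (!prior_only) {
          for (int i = 0; i < N; ++i) {
            int c = i + N * t;
            double base = alpha + xb[c] + phi[i] + delta[c];
            double en = base + xn;
            if (std::fabs(en) > eta_bound) { ok = false; break; }
            dll += cell_ll(yv[c], en) - cell_ll(yv[c], base + xi[t]);
          }
        }
        double dpr = (rw1_terms(xi, t, T, xi[t]) - rw1_terms(xi, t, T, xn)) /
                     (2.0 * var_xi);
        att[2] += 1; att_b[2] += 1;
        if (ok && std::log(unif_rand()) < dll + dpr) {
          xi[t] = xn; acc[2] += 1; acc_b[2] += 1;
        }
      }
      double m = 0.0;
      for (int t = 0; t < T; ++t) m += xi[t];
      m /= T;
      for (int t = 0; t < T; ++t) xi[t] -= m;
      alpha += m;
    }

    // ---- delta: per-cell proposals confined to the row-sum-zero subspace
    // (candidate adds e at year t and -e/T across the whole row, so the
    // constrained RW1 prior that identifies phi is the exact target) ----
    if (inc_interaction && upd_delta) {
      std::vector<double> row(T), rown(T);
      for (int i = 0; i < N; ++i) {
        for (int t = 0; t < T; ++t) row[t] = delta[i + N * t];
        for (int t = 0; t < T; ++t) {
          double e = s_de * norm_rand();
          for (int u = 0; u < T; ++u)
            rown[u] = row[u] + (u == t ? e * (1.0 - 1.0 / T) : -e / T);
          bool ok = true;
          double dll = 0.0;
          if (!prior_only) {
            for (int u = 0; u < T && ok; ++u) {
              int c = i + N * u;
              double base = alpha + xb[c] + phi[i] + xi[u];
              double en = base + rown[u];
              if (std::fabs(en) > eta_bound) { ok = false; break; }
              dll += cell_ll(yv[c], en) - cell_ll(yv[c], base + row[u]);
            }
          }
          double q0 = 0.0, q1 = 0.0;
          for (int u = 1; u < T; ++u) {
            double a = row[u] - row[u - 1], b = rown[u] - rown[u - 1];
            q0 += a * a; q1 += b * b;
          }
          double dpr = (q0 - q1) / (2.0 * var_delta);
          att[3] += 1; att_b[3] += 1;
          if (ok && std::log(unif_rand()) < dll + dpr) {
            row = rown; acc[3] += 1; acc_b[3] += 1;
          }
        }
        // write back, re-projecting float drift off the constraint
        double m = 0.0;
        for (int t = 0; t < T; ++t) m += row[t];
        m /= T;
        for (int t = 0; t < T; ++t) delta[i + N * t] = row[t] - m;
      }
    }

    // ---- variances: conjugate Gibbs on the precisions ----
    if (upd_vars) {
      if (inc_spatial && !fix_var_phi) {
        double qf = 0.0;
        int rk;
        if (iid_spatial) {
          for (int i = 0; i < N; ++i) qf += phi[i] * phi[i];
          rk = N;
        } else {
          for (size_t k = 0; k < e1.size(); ++k) {
            double d = phi[e1[k]] - phi[e2[k]];
            qf += d * d;
          }
          for (int i = 0; i < N; ++i)
            if (nbr[i].empty()) qf += phi[i] * phi[i];
          rk = rank_phi;
        }
        double tau = R::rgamma(prior_shape + rk / 2.0,
                               1.0 / (prior_rate + qf / 2.0));
        var_phi = 1.0 / std::max(tau, 1e-12);
      }
      if (inc_temporal && !fix_var_xi) {
        double qf = 0.0;
        for (int t = 1; t < T; ++t) {
          double d = xi[t] - xi[t - 1];
          qf += d * d;
        }
        double tau = R::rgamma(prior_shape + (T - 1) / 2.0,
                               1.0 / (prior_rate + qf / 2.0));
        var_xi = 1.0 / std::max(tau, 1e-12);
      }
      if (inc_interaction && !fix_var_delta) {
        double qf = 0.0;
        for (int i = 0; i < N; ++i)
          for (int t = 1; t < T; ++t) {
            double d = delta[i + N * t] - delta[i + N * (t - 1)];
            qf += d * d;
          }
        double tau = R::rgamma(prior_shape + N * (T - 1) / 2.0,
                               1.0 / (prior_rate + qf / 2.0));
        var_delta = 1.0 / std::max(tau, 1e-12);
      }
    }

    // ---- adaptation (burn-in only): Robbins-Monro on log proposal scales
    if (adapt && iter < n_burnin && (iter + 1) % batch == 0) {
      ++n_batch;
      double gain = 1.0 / std::sqrt((double) n_batch);
      double targets[4] = {0.30, 0.44, 0.44, 0.44};
      double* sc[4] = {&s_ab, &s_phi, &s_xi, &s_de};
      for (int b = 0; b < 4; ++b) {
        if (att_b[b] > 0) {
          double r = acc_b[b] / att_b[b];
          *sc[b] *= std::exp(gain * (r - targets[b]));
          *sc[b] = std::min(std::max(*sc[b], 1e-6), 50.0);
        }
        acc_b[b] = 0; att_b[b] = 0;
      }
    }

    // ---- storage ----
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && keep < n_keep) {
      out_alpha[keep] = alpha;
      for (int p = 0; p < P; ++p) out_beta(keep, p) = beta[p];
      for (int i = 0; i < N; ++i) out_phi(keep, i) = phi[i];
      for (int t = 0; t < T; ++t) out_xi(keep, t) = xi[t];
      if (inc_interaction)
        for (int c = 0; c < NT; ++c) out_delta(keep, c) = delta[c];
      out_vphi[keep] = var_phi; out_vxi[keep] = var_xi; out_vde[keep] = var_delta;
      ++keep;
    }
  }

  NumericVector rates(4), scales(4);
  for (int b = 0; b < 4; ++b) {
    rates[b] = att[b] > 0 ? acc[b] / att[b] : NA_REAL;
  }
  scales[0] = s_ab; scales[1] = s_phi; scales[2] = s_xi; scales[3] = s_de;
  rates.names() = CharacterVector::create("alpha_beta", "phi", "xi", "delta");
  scales.names() = CharacterVector::create("alpha_beta", "phi", "xi", "delta");

  NumericMatrix delta_final(N, T);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < N; ++i) delta_final(i, t) = delta[i + N * t];
  NumericVector beta_fin(P), phi_fin(N), xi_fin(T);
  for (int p = 0; p < P; ++p) beta_fin[p] = beta[p];
  for (int i = 0; i < N; ++i) phi_fin[i] = phi[i];
  for (int t = 0; t < T; ++t) xi_fin[t] = xi[t];

  return List::create(
      _["alpha"] = out_alpha, _["beta"] = out_beta, _["phi"] = out_phi,
      _["xi"] = out_xi, _["delta"] = out_delta,
      _["var_phi"] = out_vphi, _["var_xi"] = out_vxi, _["var_delta"] = out_vde,
      _["acceptance"] = rates, _["scales"] = scales,
      _["final_state"] = List::create(
          _["alpha"] = alpha, _["beta"] = beta_fin, _["phi"] = phi_fin,
          _["xi"] = xi_fin, _["delta"] = delta_final,
          _["var_phi"] = var_phi, _["var_xi"] = var_xi,
          _["var_delta"] = var_delta));
}
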