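// Gibbs chains for the univariate (BayesR) and multivariate (BayesMV)
// mixture-of-normals whole-genome regressions. The conditional
// distributions mirror the R kernel functions; everything draws from R's
// RNG so set.seed() makes a chain bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double VAR_FLOOR = 1e-12;

// log integrated likelihood of a component, effect marginalized out
static inline double log_comp_lik(double rhs, double lhs, double s2k) {
  if (s2k == 0.0) return 0.0;
  double d = 1.0 + lhs * s2k;
  return -0.5 * std::log(d) + 0.5 * rhs * rhs * s2k / d;
}

// categorical draw from unnormalized log-weights (length K)
static inline int sample_cat_log(const double* logw, int K) {
  double mx = logw[0];
  for (int k = 1; k < K; ++k) if (logw[k] > mx) mx = logw[k];
  double tot = 0.0, w[8];
  for (int k = 0; k < K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) { c += w[k]; if (u <= c) return k; }
  return K - 1;
}

static inline double rinvchisq_scaled(double ssq, double df) {
  double x = Rf_rchisq(df);
  if (x <= 0) x = 1e-300;
  return std::max(ssq / x, VAR_FLOOR);
}

// Dirichlet(counts + 1) draw
static inline void draw_dirichlet(const arma::ivec& counts, arma::vec& q) {
  double tot = 0.0;
  for (arma::uword k = 0; k < q.n_elem; ++k) {
    q[k] = Rf_rgamma(counts[k] + 1.0, 1.0);
    tot += q[k];
  }
  q /= tot;
}

// Fisher-Yates shuffle of 0..m-1 using R's RNG
static inline void shuffle_order(std::vector<int>& ord) {
  const int m = (int)ord.size();
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

struct PolyState {
  bool enabled = false;
  arma::mat U;        // eigenvectors of A
  arma::vec d;        // eigenvalues of A (floored)
  arma::vec a;        // current polygenic values
  double sigma2_a = 0.0;
  bool update_var = true;
};

// one polygenic update (unit weights); r excludes nothing: a is added back
static void update_polygenic(arma::vec& r, PolyState& ps, double sigma2_e,
                             int n) {
  r += ps.a;
  arma::vec rstar = ps.U.t() * r;
  arma::vec astar(n);
  double quad = 0.0;
  for (int i = 0; i < n; ++i) {
    double prec = 1.0 / sigma2_e + 1.0 / (ps.d[i] * ps.sigma2_a);
    double mu = (rstar[i] / sigma2_e) / prec;
    astar[i] = mu + norm_rand() / std::sqrt(prec);
    quad += astar[i] * astar[i] / ps.d[i];
  }
  ps.a = ps.U * astar;
  r -= ps.a;
  if (ps.update_var) ps.sigma2_a = rinvchisq_scaled(quad, (double)n - 2.0);
}

// [[Rcpp::export(name = ".bayesr_chain_cpp")]]
List bayesr_chain_cpp(const arma::mat& W, const arma::vec& y,
                      const arma::vec& weights, const arma::vec& sigma2_k,
                      int n_iter, int burn_in, int thin,
                      double sigma2_e_init, arma::vec q,
                      bool update_q, bool update_sigma2e,
                      bool fit_intercept,
                      const arma::mat& A_U, const arma::vec& A_d,
                      double sigma2_a_init, bool update_sigma2a,
                      int resync_every, bool permute_order) {
  const int n = W.n_rows, m = W.n_cols, K = sigma2_k.n_elem;
  const bool unit_w = arma::all(weights == 1.0);
  const arma::vec ew = weights;  // diagonal of E^{-1}
  const double wsum = arma::accu(ew);

  // per-SNP w' E^{-1} w
  arma::vec wEw(m);
  for (int j = 0; j < m; ++j) {
    wEw[j] = unit_w ? arma::dot(W.col(j), W.col(j))
                    : arma::accu(ew % arma::square(W.col(j)));
  }

  PolyState ps;
  if (A_U.n_rows == (arma::uword)n) {
    if (!unit_w) stop("compiled polygenic update requires unit weights");
    ps.enabled = true;
    ps.U = A_U;
    ps.d = arma::clamp(A_d, 1e-10, arma::datum::inf);
    ps.a.zeros(n);
    ps.sigma2_a = sigma2_a_init;
    ps.update_var = update_sigma2a;
  }

  arma::vec v(m, arma::fill::zeros);
  arma::ivec comp(m, arma::fill::ones);   // labels 1..K
  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  double mu = 0.0, sigma2_e = sigma2_e_init;
  arma::vec r = y;

  // accumulators
  arma::mat pp(m, K, arma::fill::zeros);
  arma::vec v_sum(m, arma::fill::zeros);
  arma::vec class_counts(K, arma::fill::zeros);
  arma::vec q_sum(K, arma::fill::zeros);
  double s2e_sum = 0.0, s2a_sum = 0.0, mu_sum = 0.0;
  arma::vec a_sum(n, arma::fill::zeros);
  int n_stored = 0;
  // joint posterior over all K^m component configurations, kept on tiny
  // problems so chains can be checked against exhaustive enumeration
  const bool track_joint = m <= 6;
  arma::vec joint_hist;
  if (track_joint) joint_hist.zeros((int)std::pow((double)K, m));

  double logw[8];
  GetRNGstate();
  for (int it = 1; it <= n_iter; ++it) {
    if (fit_intercept) {
      r += mu;
      double rbar = unit_w ? arma::accu(r) / wsum
                           : arma::accu(ew % r) / wsum;
      mu = rbar + norm_rand() * std::sqrt(sigma2_e / wsum);
      r -= mu;
    }
    if (ps.enabled) update_polygenic(r, ps, sigma2_e, n);

    arma::ivec counts(K, arma::fill::zeros);
    if (permute_order) shuffle_order(order);
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      double wr = unit_w ? arma::dot(W.col(j), r)
                         : arma::accu(ew % W.col(j) % r);
      double rhs = (wr + wEw[j] * v[j]) / sigma2_e;  // add SNP j back in
      double lhs = wEw[j] / sigma2_e;
      for (int k = 0; k < K; ++k) {
        logw[k] = (q[k] > 0 ? std::log(q[k]) : -1e300) +
                  log_comp_lik(rhs, lhs, sigma2_k[k]);
      }
      int k = sample_cat_log(logw, K);
      counts[k] += 1;
      comp[j] = k + 1;
      double v_new = 0.0;
      if (sigma2_k[k] > 0.0) {
        double prec = lhs + 1.0 / sigma2_k[k];
        v_new = rhs / prec + norm_rand() / std::sqrt(prec);
      }
      if (v_new != v[j]) {
        r += W.col(j) * (v[j] - v_new);
        v[j] = v_new;
      }
    }

    if (update_q) draw_dirichlet(counts, q);
    if (update_sigma2e) {
      double ssq = unit_w ? arma::dot(r, r) : arma::accu(ew % arma::square(r));
      sigma2_e = rinvchisq_scaled(ssq, (double)n - 2.0);
    }
    if (resync_every > 0 && it % resync_every == 0) {
      r = y - W * v - mu;
      if (ps.enabled) r -= ps.a;
    }

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_stored;
      for (int j = 0; j < m; ++j) pp(j, comp[j] - 1) += 1.0;
      v_sum += v;
      for (int k = 0; k < K; ++k) class_counts[k] += counts[k];
      q_sum += q;
      s2e_sum += sigma2_e;
      s2a_sum += ps.sigma2_a;
      mu_sum += mu;
      if (ps.enabled) a_sum += ps.a;
      if (track_joint) {
        int idx = 0, base = 1;
        for (int j = 0; j < m; ++j) { idx += (comp[j] - 1) * base; base *= K; }
        joint_hist[idx] += 1.0;
      }
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  if (!r.is_finite()) stop("chain diverged (non-finite residual)");
  double ns = std::max(n_stored, 1);
  return List::create(
    _["pp"] = pp / ns,
    _["mean_effect"] = v_sum / ns,
    _["class_counts"] = class_counts / ns,
    _["q_mean"] = q_sum / ns,
    _["sigma2_e_mean"] = s2e_sum / ns,
    _["sigma2_a_mean"] = s2a_sum / ns,
    _["intercept_mean"] = mu_sum / ns,
    _["polygenic_mean"] = a_sum / ns,
    _["joint_hist"] = track_joint ? (joint_hist / ns) : arma::vec(),
    _["n_stored"] = n_stored
  );
}

// [[Rcpp::export(name = ".bayesmv_chain_cpp")]]
List bayesmv_chain_cpp(const arma::mat& W, const arma::mat& Y,
                       const arma::mat& weights, const arma::mat& sigma2_k,
                       int n_iter, int burn_in, int thin,
                       double p_init, bool update_p,
                       arma::mat q, bool update_q,
                       arma::vec sigma2_e, bool update_sigma2e,
                       bool fit_intercept,
                       const arma::mat& A_U, const arma::vec& A_d,
                       arma::vec sigma2_a_init, bool update_sigma2a,
                       int resync_every, bool permute_order) {
  const int n = W.n_rows, m = W.n_cols;
  const int t = Y.n_cols, K = sigma2_k.n_rows;
  const int n_joint = (1 << t) + 1;  // unassociated + 2^t nonzero patterns
  const bool unit_w = arma::all(arma::vectorise(weights) == 1.0);

  arma::vec wEw_base(m);  // unit-weight w'w; per-trait rescale if weighted
  for (int j = 0; j < m; ++j) wEw_base[j] = arma::dot(W.col(j), W.col(j));
  arma::mat wEw(m, t);
  for (int tr = 0; tr < t; ++tr) {
    if (unit_w) {
      wEw.col(tr) = wEw_base;
    } else {
      for (int j = 0; j < m; ++j) {
        wEw(j, tr) = arma::accu(weights.col(tr) % arma::square(W.col(j)));
      }
    }
  }

  std::vector<PolyState> ps(t);
  if (A_U.n_rows == (arma::uword)n) {
    if (!unit_w) stop("compiled polygenic update requires unit weights");
    for (int tr = 0; tr < t; ++tr) {
      ps[tr].enabled = true;
      ps[tr].U = A_U;
      ps[tr].d = arma::clamp(A_d, 1e-10, arma::datum::inf);
      ps[tr].a.zeros(n);
      ps[tr].sigma2_a = sigma2_a_init[tr];
      ps[tr].update_var = update_sigma2a;
    }
  }

  arma::mat v(m, t, arma::fill::zeros);
  arma::imat comp(m, t, arma::fill::ones);
  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  arma::ivec delta(m, arma::fill::zeros);
  arma::vec mu(t, arma::fill::zeros);
  double p = p_init;
  arma::mat r = Y;
  arma::vec wsum(t);
  for (int tr = 0; tr < t; ++tr) wsum[tr] = arma::accu(weights.col(tr));

  // accumulators
  arma::vec pp_assoc(m, arma::fill::zeros), pp_any(m, arma::fill::zeros);
  arma::cube pp_comp(m, K, t, arma::fill::zeros);
  arma::mat v_sum(m, t, arma::fill::zeros);
  arma::vec joint_counts(n_joint, arma::fill::zeros);
  arma::mat q_sum(K, t, arma::fill::zeros);
  arma::vec s2e_sum(t, arma::fill::zeros), s2a_sum(t, arma::fill::zeros);
  double p_sum = 0.0;
  int n_stored = 0;
  // per-SNP latent state: 0 = unassociated, else 1 + mixed-radix component
  // code; the joint histogram over all SNPs is kept on tiny problems for
  // exhaustive-enumeration checks
  const int n_state = 1 + (int)std::pow((double)K, t);
  const bool track_joint = std::pow((double)n_state, m) <= 5000.0;
  arma::vec joint_hist;
  if (track_joint) joint_hist.zeros((int)std::pow((double)n_state, m));

  double logw[8];
  GetRNGstate();
  for (int it = 1; it <= n_iter; ++it) {
    for (int tr = 0; tr < t; ++tr) {
      if (fit_intercept) {
        arma::vec rc = r.col(tr);
        rc += mu[tr];
        double rbar = unit_w ? arma::accu(rc) / wsum[tr]
                             : arma::accu(weights.col(tr) % rc) / wsum[tr];
        mu[tr] = rbar + norm_rand() * std::sqrt(sigma2_e[tr] / wsum[tr]);
        r.col(tr) = rc - mu[tr];
      }
      if (ps[tr].enabled) {
        arma::vec rc = r.col(tr);
        update_polygenic(rc, ps[tr], sigma2_e[tr], n);
        r.col(tr) = rc;
      }
    }

    arma::imat counts(K, t, arma::fill::zeros);  // among associated SNPs
    int n_unassoc = 0;
    std::vector<double> rhs(t), lhs(t), logS(t);
    if (permute_order) shuffle_order(order);
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      // per-trait sufficient statistics with SNP j added back
      double log_odds = std::log1p(-p) - std::log(std::max(p, 1e-300));
      for (int tr = 0; tr < t; ++tr) {
        double wr = unit_w
          ? arma::dot(W.col(j), r.col(tr))
          : arma::accu(weights.col(tr) % W.col(j) % r.col(tr));
        rhs[tr] = (wr + wEw(j, tr) * v(j, tr)) / sigma2_e[tr];
        lhs[tr] = wEw(j, tr) / sigma2_e[tr];
        // log sum_k q_k L_k for this trait
        double mx = -1e300;
        double lw[8];
        for (int k = 0; k < K; ++k) {
          lw[k] = (q(k, tr) > 0 ? std::log(q(k, tr)) : -1e300) +
                  log_comp_lik(rhs[tr], lhs[tr], sigma2_k(k, tr));
          if (lw[k] > mx) mx = lw[k];
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += std::exp(lw[k] - mx);
        logS[tr] = mx + std::log(s);
        log_odds += logS[tr];  // L_{tr,1} = 1 in the denominator
      }
      int d_new;
      if (p <= 0.0) {
        d_new = 1;
      } else if (p >= 1.0) {
        d_new = 0;
      } else {
        double pr1 = 1.0 / (1.0 + std::exp(-log_odds));
        d_new = (unif_rand() < pr1) ? 1 : 0;
      }
      delta[j] = d_new;
      if (d_new == 0) {
        ++n_unassoc;
        for (int tr = 0; tr < t; ++tr) {
          comp(j, tr) = 1;
          if (v(j, tr) != 0.0) {
            r.col(tr) += W.col(j) * v(j, tr);
            v(j, tr) = 0.0;
          }
        }
      } else {
        for (int tr = 0; tr < t; ++tr) {
          for (int k = 0; k < K; ++k) {
            logw[k] = (q(k, tr) > 0 ? std::log(q(k, tr)) : -1e300) +
                      log_comp_lik(rhs[tr], lhs[tr], sigma2_k(k, tr));
          }
          int k = sample_cat_log(logw, K);
          comp(j, tr) = k + 1;
          counts(k, tr) += 1;
          double v_new = 0.0;
          if (sigma2_k(k, tr) > 0.0) {
            double prec = lhs[tr] + 1.0 / sigma2_k(k, tr);
            v_new = rhs[tr] / prec + norm_rand() / std::sqrt(prec);
          }
          if (v_new != v(j, tr)) {
            r.col(tr) += W.col(j) * (v(j, tr) - v_new);
            v(j, tr) = v_new;
          }
        }
      }
    }

    if (update_p) {
      double g1 = Rf_rgamma(n_unassoc + 1.0, 1.0);
      double g2 = Rf_rgamma((double)(m - n_unassoc) + 1.0, 1.0);
      p = g1 / (g1 + g2);
    }
    for (int tr = 0; tr < t; ++tr) {
      if (update_q) {
        arma::ivec ctr = counts.col(tr);
        arma::vec qtr = q.col(tr);
        draw_dirichlet(ctr, qtr);
        q.col(tr) = qtr;
      }
      if (update_sigma2e) {
        double ssq = unit_w
          ? arma::dot(r.col(tr), r.col(tr))
          : arma::accu(weights.col(tr) % arma::square(r.col(tr)));
        sigma2_e[tr] = rinvchisq_scaled(ssq, (double)n - 2.0);
      }
    }
    if (resync_every > 0 && it % resync_every == 0) {
      r = Y - W * v;
      for (int tr = 0; tr < t; ++tr) {
        r.col(tr) -= mu[tr];
        if (ps[tr].enabled) r.col(tr) -= ps[tr].a;
      }
    }

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_stored;
      for (int j = 0; j < m; ++j) {
        bool any_nz = false;
        int pattern = 0;
        for (int tr = 0; tr < t; ++tr) {
          pp_comp(j, comp(j, tr) - 1, tr) += 1.0;
          if (comp(j, tr) > 1) { any_nz = true; pattern |= (1 << tr); }
        }
        if (delta[j] == 1) pp_assoc[j] += 1.0;
        if (any_nz) pp_any[j] += 1.0;
        joint_counts[delta[j] == 0 ? 0 : 1 + pattern] += 1.0;
      }
      v_sum += v;
      q_sum += q;
      s2e_sum += sigma2_e;
      for (int tr = 0; tr < t; ++tr) s2a_sum[tr] += ps[tr].sigma2_a;
      p_sum += p;
      if (track_joint) {
        int idx = 0, base = 1;
        for (int j = 0; j < m; ++j) {
          int st = 0;
          if (delta[j] == 1) {
            st = 1;
            int cb = 1;
            for (int tr = 0; tr < t; ++tr) {
              st += (comp(j, tr) - 1) * cb;
              cb *= K;
            }
          }
          idx += st * base;
          base *= n_state;
        }
        joint_hist[idx] += 1.0;
      }
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  if (!r.is_finite()) stop("chain diverged (non-finite residual)");
  double ns = std::max(n_stored, 1);
  return List::create(
    _["pp_assoc"] = pp_assoc / ns,
    _["pp_any"] = pp_any / ns,
    _["pp_comp"] = pp_comp / ns,
    _["mean_effect"] = v_sum / ns,
    _["joint_class_counts"] = joint_counts / ns,
    _["q_mean"] = q_sum / ns,
    _["p_mean"] = p_sum / ns,
    _["sigma2_e_mean"] = s2e_sum / ns,
    _["sigma2_a_mean"] = s2a_sum / ns,
    _["joint_hist"] = track_joint ? (joint_hist / ns) : arma::vec(),
    _["n_stored"] = n_stored
  );
}
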