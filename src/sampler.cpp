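#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs sampler for the multinomial
// logit model with Laplace-penalised covariate effects, study random effects
// with bounded SD, and per-study binary aggregation of true causes into
// reported categories.
//
// Parameterisation passed from R:
//   beta: C x (K+1) matrix, base-cause row fixed at 0 (column 0 = intercept)
//   u:    S x C matrix, base-cause column fixed at 0
//   sigma: scalar in (0, sigma_bound]
// Study s likelihood: y_s ~ Multinomial(N_s, G_s softmax(X_s beta' + u_s));
// the multinomial coefficient is constant in the parameters and dropped.

static double study_loglik(const IntegerVector& y, const IntegerVector& gidx,
                           const NumericMatrix& eta, int s, int C, int J) {
  // softmax over true causes with max-subtraction, then aggregate to
  // reported categories via gidx (1-based reported index per true cause)
  double m = eta(s, 0);
  for (int c = 1; c < C; ++c) if (eta(s, c) > m) m = eta(s, c);
  std::vector<double> q(J, 0.0);
  double denom = 0.0;
  for (int c = 0; c < C; ++c) {
    double e = std::exp(eta(s, c) - m);
    denom += e;
    q[gidx[c] - 1] += e;
  }
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    if (y[j] > 0) {
      if (q[j] <= 0.0) return R_NegInf;
      ll += y[j] * (std::log(q[j]) - std::log(denom));
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".run_mcmc")]]
List run_mcmc(List counts, List gidx_list, NumericMatrix X, int base1,
              double lambda, double sigma_bound, double intercept_sd,
              int n_keep, int burnin,
              NumericMatrix beta_init, NumericMatrix u_init,
              double sigma_init, int adapt_interval) {
  const int S = X.nrow();
  const int K1 = X.ncol();
  const int C = beta_init.nrow();
  const int base = base1 - 1;

  NumericMatrix beta = clone(beta_init);
  NumericMatrix u = clone(u_init);
  double sigma = sigma_init;

  std::vector<IntegerVector> Y(S), GI(S);
  std::vector<int> J(S);
  for (int s = 0; s < S; ++s) {
    Y[s] = counts[s];
    GI[s] = gidx_list[s];
    J[s] = Y[s].size();
  }

  // cached linear predictor and per-study log likelihood
  NumericMatrix eta(S, C);
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < C; ++c) {
      double v = u(s, c);
      for (int k = 0; k < K1; ++k) v += X(s, k) * beta(c, k);
      eta(s, c) = v;
    }
  std::vector<double> ll(S);
  double total_ll = 0.0;
  for (int s = 0; s < S; ++s) {
    ll[s] = study_loglik(Y[s], GI[s], eta, s, C, J[s]);
    total_ll += ll[s];
  }
  if (!R_finite(total_ll))
    stop("non-finite log likelihood at initialisation");

  const int n_beta = (C - 1) * K1;
  const int n_u = S * (C - 1);
  const int P = n_beta + n_u + 1;

  std::vector<double> lsc(P, std::log(0.1));   // per-parameter log step size
  std::vector<int> acc(P, 0);
  std::vector<int> att(P, 0);
  NumericMatrix out(n_keep, P);
  std::vector<double> acc_total(P, 0.0), att_total(P, 0.0);

  RNGScope scope;
  const int n_iter = burnin + n_keep;
  int batch = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- beta entries (skip base row) ---
    int pidx = 0;
    for (int c = 0; c < C; ++c) {
      if (c == base) continue;
      for (int k = 0; k < K1; ++k, ++pidx) {
        double old = beta(c, k);
        double prop = old + std::exp(lsc[pidx]) * R::norm_rand();
        double delta = prop - old;
        // candidate log likelihood over all studies (eta col c shifts)
        double new_total = 0.0;
        std::vector<double> new_ll(S);
        for (int s = 0; s < S; ++s) eta(s, c) += X(s, k) * delta;
        for (int s = 0; s < S; ++s) {
          new_ll[s] = study_loglik(Y[s], GI[s], eta, s, C, J[s]);
          new_total += new_ll[s];
        }
        double lp_diff;
        if (k == 0)   // intercepts: wide normal, unpenalised
          lp_diff = (-0.5 * prop * prop + 0.5 * old * old) /
                    (intercept_sd * intercept_sd);
        else          // Laplace(0, 1/lambda)
          lp_diff = -lambda * (std::fabs(prop) - std::fabs(old));
        double lr = new_total - total_ll + lp_diff;
        ++att[pidx];
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          beta(c, k) = prop;
          ll = new_ll;
          total_ll = new_total;
          ++acc[pidx];
        } else {
          for (int s = 0; s < S; ++s) eta(s, c) -= X(s, k) * delta;
        }
      }
    }
    // --- random effects ---
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < C; ++c) {
        if (c == base) continue;
        int p = n_beta + s * (C - 1) + (c > base ? c - 1 : c);
        double old = u(s, c);
        double prop = old + std::exp(lsc[p]) * R::norm_rand();
        eta(s, c) += prop - old;
        double new_ll_s = study_loglik(Y[s], GI[s], eta, s, C, J[s]);
        double lp_diff = (-0.5 * prop * prop + 0.5 * old * old) /
                         (sigma * sigma);
        double lr = new_ll_s - ll[s] + lp_diff;
        ++att[p];
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          u(s, c) = prop;
          total_ll += new_ll_s - ll[s];
          ll[s] = new_ll_s;
          ++acc[p];
        } else {
          eta(s, c) -= prop - old;
        }
      }
    }
    // --- sigma: log-scale random walk, uniform prior on (0, bound] ---
    {
      int p = P - 1;
      double lprop = std::log(sigma) + std::exp(lsc[p]) * R::norm_rand();
      double sprop = std::exp(lprop);
      ++att[p];
      if (sprop > 0.0 && sprop <= sigma_bound) {
        double sumU2 = 0.0;
        for (int s = 0; s < S; ++s)
          for (int c = 0; c < C; ++c)
            if (c != base) sumU2 += u(s, c) * u(s, c);
        double nd = (double)S * (C - 1);
        double lr = -nd * (std::log(sprop) - std::log(sigma))
                    - 0.5 * sumU2 * (1.0 / (sprop * sprop) -
                                     1.0 / (sigma * sigma))
                    + (std::log(sprop) - std::log(sigma));  // Jacobian
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          sigma = sprop;
          ++acc[p];
        }
      }
    }
    // --- step-size adaptation (burn-in only, batched) ---
    if (iter < burnin && (iter + 1) % adapt_interval == 0) {
      ++batch;
      double d = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int p = 0; p < P; ++p) {
        if (att[p] > 0) {
          double rate = (double)acc[p] / att[p];
          lsc[p] += (rate > 0.44) ? d : -d;
        }
        acc[p] = 0;
        att[p] = 0;
      }
    }
    if (iter == burnin - 1) {  // reset counters for reported rates
      for (int p = 0; p < P; ++p) { acc[p] = 0; att[p] = 0; }
    }
    // --- store ---
    if (iter >= burnin) {
      int row = iter - burnin;
      int q = 0;
      for (int c = 0; c < C; ++c) {
        if (c == base) continue;
        for (int k = 0; k < K1; ++k) out(row, q++) = beta(c, k);
      }
      for (int s = 0; s < S; ++s)
        for (int c = 0; c < C; ++c)
          if (c != base) out(row, q++) = u(s, c);
      out(row, q) = sigma;
    }
  }

  NumericVector rates(P);
  for (int p = 0; p < P; ++p)
    rates[p] = att[p] > 0 ? (double)acc[p] / att[p] : NA_REAL;
  return List::create(_["draws"] = out, _["accept"] = rates);
}
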