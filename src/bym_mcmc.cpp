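// Adaptive Metropolis-within-Gibbs sampler for the BYM spatiotemporal model.
//
// Linear predictor for block i, round r (time value t_r):
//   eta_ir = alpha + beta * t_r + u_i + v_i [+ delta_i * t_r]
// Binomial family: y_ir ~ Binomial(n_ir, logit^-1(eta_ir))
// Poisson  family: y_ir ~ Poisson(n_ir * exp(eta_ir))
//
// u: intrinsic CAR (pairwise-difference prior over graph edges), recentred
//    per sweep; v: iid Normal(0, 1/tau_v); delta: iid Normal(0, 1/tau_delta),
//    recentred per sweep with beta compensation so eta is untouched.
// Precisions: conjugate gamma Gibbs updates. eta-level parameters:
// random-walk Metropolis, proposal scales adapted toward 0.44 acceptance
// during burn-in only. Uses R's RNG, so runs are reproducible via set.seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log-likelihood kernel of one cell (constants in y dropped; fine for MH)
static inline double cell_kernel(double y, double n, double eta, int family) {
  if (family == 0) return y * eta - n * log1pexp_(eta);  // binomial-logit
  return y * eta - n * std::exp(eta);                    // Poisson-log
}

// full log-pmf of one cell (for deviance draws)
static inline double cell_logpmf(double y, double n, double eta, int family) {
  if (family == 0)
    return R::dbinom(y, n, 1.0 / (1.0 + std::exp(-eta)), 1);
  return R::dpois(y, n * std::exp(eta), 1);
}

struct Adapt {
  std::vector<double> lsd;   // log proposal sd
  std::vector<int> acc, tot;
  void init(int k, double s) {
    lsd.assign(k, std::log(s)); acc.assign(k, 0); tot.assign(k, 0);
  }
  void tune() {  // called every 50 burn-in iterations
    for (size_t j = 0; j < lsd.size(); ++j) {
      if (tot[j] == 0) continue;
      double rate = (double)acc[j] / tot[j];
      lsd[j] += (rate > 0.44 ? 0.1 : -0.1);
      if (lsd[j] < -8.0) lsd[j] = -8.0;
      if (lsd[j] > 4.0) lsd[j] = 4.0;
      acc[j] = 0; tot[j] = 0;
    }
  }
};

// [[Rcpp::export]]
List bym_mcmc_chain(NumericMatrix y, NumericMatrix n, LogicalMatrix obs,
                    NumericVector tvals, List nbr, IntegerMatrix edges,
                    IntegerVector comp, int n_comp,
                    int family, bool interaction,
                    double a_tau, double b_tau,
                    double prec_alpha, double prec_beta,
                    NumericVector fixed_tau,
                    int n_iter, int n_burn, int thin,
                    NumericVector init) {
  const int nb = y.nrow(), nr = y.ncol();
  std::vector<std::vector<int>> nblist(nb);
  std::vector<int> deg(nb);
  for (int i = 0; i < nb; ++i) {
    IntegerVector vi = nbr[i];
    nblist[i] = as<std::vector<int>>(vi);
    deg[i] = nblist[i].size();
  }
  // state
  double alpha = init[0], beta = init[1];
  double tau_u = init[2], tau_v = init[3], tau_d = init[4];
  std::vector<double> u(nb, 0.0), v(nb, 0.0), del(nb, 0.0);
  for (int i = 0; i < nb; ++i) { u[i] = init[5 + i]; v[i] = init[5 + nb + i]; }
  if (interaction)
    for (int i = 0; i < nb; ++i) del[i] = init[5 + 2 * nb + i];

  bool fix_u = !NumericVector::is_na(fixed_tau[0]);
  bool fix_v = !NumericVector::is_na(fixed_tau[1]);
  bool fix_d = !NumericVector::is_na(fixed_tau[2]);
  if (fix_u) tau_u = fixed_tau[0];
  if (fix_v) tau_v = fixed_tau[1];
  if (fix_d) tau_d = fixed_tau[2];

  int rank_u = nb - n_comp;

  // slots 0-1: alpha, beta random walks; 2-4: log-scale moves on u, v, delta
  Adapt ad_ab, ad_u, ad_v, ad_d;
  ad_ab.init(5, 0.1); ad_u.init(nb, 0.3); ad_v.init(nb, 0.3);
  if (interaction) ad_d.init(nb, 0.2);

  // block-level likelihood kernel as a function of that block's offset pieces
  auto block_ll = [&](int i, double ui, double vi, double di,
                      double a, double b) {
    double s = 0.0;
    for (int r = 0; r < nr; ++r) {
      if (!obs(i, r)) continue;
      double eta = a + b * tvals[r] + ui + vi + di * tvals[r];
      s += cell_kernel(y(i, r), n(i, r), eta, family);
    }
    return s;
  };
  auto total_ll = [&](double a, double b) {
    double s = 0.0;
    for (int i = 0; i < nb; ++i) s += block_ll(i, u[i], v[i], del[i], a, b);
    return s;
  };
  // likelihood with one random-effect vector rescaled by c
  auto total_ll_scaled = [&](double cu, double cv, double cd) {
    double s = 0.0;
    for (int i = 0; i < nb; ++i)
      s += block_ll(i, cu * u[i], cv * v[i], cd * del[i], alpha, beta);
    return s;
  };
  auto quad_u = [&]() {  // u' Q u over graph edges
    double ss = 0.0;
    for (int e = 0; e < edges.nrow(); ++e) {
      double d = u[edges(e, 0) - 1] - u[edges(e, 1) - 1];
      ss += d * d;
    }
    return ss;
  };

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericVector k_alpha(n_keep), k_beta(n_keep), k_tu(n_keep), k_tv(n_keep),
      k_td(n_keep), k_dev(n_keep);
  NumericMatrix k_u(n_keep, nb), k_v(n_keep, nb), k_del(n_keep, nb);

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- alpha, beta ---
    {
      double cur = total_ll(alpha, beta);
      double prop = alpha + R::rnorm(0.0, std::exp(ad_ab.lsd[0]));
      double lr = total_ll(prop, beta) - cur
                  - 0.5 * prec_alpha * (prop * prop - alpha * alpha);
      ad_ab.tot[0]++;
      if (std::log(R::runif(0, 1)) < lr) { alpha = prop; ad_ab.acc[0]++; }

      cur = total_ll(alpha, beta);
      prop = beta + R::rnorm(0.0, std::exp(ad_ab.lsd[1]));
      lr = total_ll(alpha, prop) - cur
           - 0.5 * prec_beta * (prop * prop - beta * beta);
      ad_ab.tot[1]++;
      if (std::log(R::runif(0, 1)) < lr) { beta = prop; ad_ab.acc[1]++; }
    }

    // --- spatial field u (single-site, ICAR full-conditional prior) ---
    for (int i = 0; i < nb; ++i) {
      if (deg[i] == 0) continue;  // isolated block: pinned at 0 by centering
      double mnb = 0.0;
      for (int j : nblist[i]) mnb += u[j];
      mnb /= deg[i];
      double prop = u[i] + R::rnorm(0.0, std::exp(ad_u.lsd[i]));
      double lr = block_ll(i, prop, v[i], del[i], alpha, beta)
                - block_ll(i, u[i], v[i], del[i], alpha, beta)
                - 0.5 * tau_u * deg[i] *
                  ((prop - mnb) * (prop - mnb) - (u[i] - mnb) * (u[i] - mnb));
      ad_u.tot[i]++;
      if (std::log(R::runif(0, 1)) < lr) { u[i] = prop; ad_u.acc[i]++; }
    }
    // recentre u per component; single-component shift is absorbed by alpha
    {
      std::vector<double> cm(n_comp, 0.0);
      std::vector<int> cn(n_comp, 0);
      for (int i = 0; i < nb; ++i) { cm[comp[i] - 1] += u[i]; cn[comp[i] - 1]++; }
      for (int c = 0; c < n_comp; ++c) cm[c] /= cn[c];
      for (int i = 0; i < nb; ++i) u[i] -= cm[comp[i] - 1];
      if (n_comp == 1) alpha += cm[0];
    }

    // --- unstructured heterogeneity v ---
    for (int i = 0; i < nb; ++i) {
      double prop = v[i] + R::rnorm(0.0, std::exp(ad_v.lsd[i]));
      double lr = block_ll(i, u[i], prop, del[i], alpha, beta)
                - block_ll(i, u[i], v[i], del[i], alpha, beta)
                - 0.5 * tau_v * (prop * prop - v[i] * v[i]);
      ad_v.tot[i]++;
      if (std::log(R::runif(0, 1)) < lr) { v[i] = prop; ad_v.acc[i]++; }
    }

    // --- ridge Gibbs: resample the u_i / v_i split holding their sum.
    // Only u_i + v_i enters eta, and along that line the conditional of
    // v_i is Gaussian: exact draw, always accepted. ---
    for (int i = 0; i < nb; ++i) {
      if (deg[i] == 0) continue;
      double mnb = 0.0;
      for (int j : nblist[i]) mnb += u[j];
      mnb /= deg[i];
      double s = u[i] + v[i];
      double prec = tau_u * deg[i] + tau_v;
      double mean = tau_u * deg[i] * (s - mnb) / prec;
      v[i] = R::rnorm(mean, 1.0 / std::sqrt(prec));
      u[i] = s - v[i];
    }

    // --- space-time interaction delta ---
    if (interaction) {
      for (int i = 0; i < nb; ++i) {
        double prop = del[i] + R::rnorm(0.0, std::exp(ad_d.lsd[i]));
        double lr = block_ll(i, u[i], v[i], prop, alpha, beta)
                  - block_ll(i, u[i], v[i], del[i], alpha, beta)
                  - 0.5 * tau_d * (prop * prop - del[i] * del[i]);
        ad_d.tot[i]++;
        if (std::log(R::runif(0, 1)) < lr) { del[i] = prop; ad_d.acc[i]++; }
      }
      double m = 0.0;
      for (int i = 0; i < nb; ++i) m += del[i];
      m /= nb;
      for (int i = 0; i < nb; ++i) del[i] -= m;
      beta += m;  // eta unchanged: beta absorbs the mean trend deviation
    }

    // --- joint scale moves (break the vector/precision coupling),
    // interleaved with the precision Gibbs updates; repeating the cheap
    // pair several times decorrelates the precisions ---
    for (int rep = 0; rep < 3; ++rep) {
    if (rank_u > 0) {
      double c = std::exp(R::rnorm(0.0, std::exp(ad_ab.lsd[2])));
      double lr = total_ll_scaled(c, 1.0, 1.0) - total_ll(alpha, beta)
                  - 0.5 * tau_u * (c * c - 1.0) * quad_u()
                  + rank_u * std::log(c);
      ad_ab.tot[2]++;
      if (std::log(R::runif(0, 1)) < lr) {
        for (int i = 0; i < nb; ++i) u[i] *= c;
        ad_ab.acc[2]++;
      }
    }
    {
      double c = std::exp(R::rnorm(0.0, std::exp(ad_ab.lsd[3])));
      double sv = 0.0;
      for (int i = 0; i < nb; ++i) sv += v[i] * v[i];
      double lr = total_ll_scaled(1.0, c, 1.0) - total_ll(alpha, beta)
                  - 0.5 * tau_v * (c * c - 1.0) * sv + nb * std::log(c);
      ad_ab.tot[3]++;
      if (std::log(R::runif(0, 1)) < lr) {
        for (int i = 0; i < nb; ++i) v[i] *= c;
        ad_ab.acc[3]++;
      }
    }
    if (interaction) {
      double c = std::exp(R::rnorm(0.0, std::exp(ad_ab.lsd[4])));
      double sd2 = 0.0;
      for (int i = 0; i < nb; ++i) sd2 += del[i] * del[i];
      double lr = total_ll_scaled(1.0, 1.0, c) - total_ll(alpha, beta)
                  - 0.5 * tau_d * (c * c - 1.0) * sd2
                  + (nb - 1) * std::log(c);
      ad_ab.tot[4]++;
      if (std::log(R::runif(0, 1)) < lr) {
        for (int i = 0; i < nb; ++i) del[i] *= c;
        ad_ab.acc[4]++;
      }
    }

    // --- precisions (conjugate gamma) ---
    if (!fix_u && rank_u > 0) {
      double ss = quad_u();
      tau_u = R::rgamma(a_tau + 0.5 * rank_u, 1.0 / (b_tau + 0.5 * ss));
    }
    if (!fix_v) {
      double ss = 0.0;
      for (int i = 0; i < nb; ++i) ss += v[i] * v[i];
      tau_v = R::rgamma(a_tau + 0.5 * nb, 1.0 / (b_tau + 0.5 * ss));
    }
    if (interaction && !fix_d) {
      double ss = 0.0;
      for (int i = 0; i < nb; ++i) ss += del[i] * del[i];
      tau_d = R::rgamma(a_tau + 0.5 * (nb - 1), 1.0 / (b_tau + 0.5 * ss));
    }
    }  // end scale/precision interleave

    // --- adaptation (burn-in only) ---
    if (it < n_burn && (it + 1) % 50 == 0) {
      ad_ab.tune(); ad_u.tune(); ad_v.tune();
      if (interaction) ad_d.tune();
    }

    // --- record ---
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      k_alpha[kept] = alpha; k_beta[kept] = beta;
      k_tu[kept] = tau_u; k_tv[kept] = tau_v; k_td[kept] = tau_d;
      double dev = 0.0;
      for (int i = 0; i < nb; ++i)
        for (int r = 0; r < nr; ++r) {
          if (!obs(i, r)) continue;
          double eta = alpha + beta * tvals[r] + u[i] + v[i] +
                       del[i] * tvals[r];
          dev += cell_logpmf(y(i, r), n(i, r), eta, family);
        }
      k_dev[kept] = -2.0 * dev;
      for (int i = 0; i < nb; ++i) {
        k_u(kept, i) = u[i]; k_v(kept, i) = v[i]; k_del(kept, i) = del[i];
      }
      ++kept;
    }
  }

  return List::create(
      _["alpha"] = k_alpha, _["beta"] = k_beta,
      _["tau_u"] = k_tu, _["tau_v"] = k_tv, _["tau_delta"] = k_td,
      _["u"] = k_u, _["v"] = k_v, _["delta"] = k_del,
      _["deviance"] = k_dev);
}
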