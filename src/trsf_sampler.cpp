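// Adaptive random-walk Metropolis-within-Gibbs sampler for the hierarchical
// multinomial temporal resource-selection model.
//
// The linear predictor eta (I x K), its exponential E and the row sums
// `denom` are cached; scalar proposals touch a single category column (beta)
// or a single city's rows (intercepts), so each update costs O(I) or O(I_c)
// exponentials rather than a full likelihood evaluation. mu_k and tau_k are
// conjugate Gibbs draws; the Laplace rate pi has a truncated-Gamma full
// conditional drawn exactly by inverse CDF. Step sizes adapt toward a target
// acceptance rate during burn-in only.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List run_trsf_chain(NumericMatrix X, IntegerVector y, NumericMatrix log_alpha,
                    IntegerVector city, int n_city,
                    NumericMatrix beta0, NumericMatrix b0,
                    NumericVector mu0, NumericVector tau0, double pi0,
                    int n_burn, int n_keep, int thin,
                    double target_accept, int adapt_interval) {
  const int I = X.nrow(), J = X.ncol(), K = log_alpha.ncol(), Km = K - 1,
            C = n_city;

  NumericMatrix beta(clone(beta0)), b(clone(b0));
  NumericVector mu(clone(mu0)), tau(clone(tau0));
  double piv = pi0;

  std::vector<double> eta(I * K), E(I * K), denom(I), scratch(I);

  std::vector< std::vector<int> > cidx(C);
  for (int i = 0; i < I; ++i) cidx[city[i] - 1].push_back(i);

  auto recompute = [&]() {
    for (int i = 0; i < I; ++i) {
      eta[i] = log_alpha(i, 0);
      for (int km = 0; km < Km; ++km) {
        double v = b(city[i] - 1, km) + log_alpha(i, km + 1);
        for (int j = 0; j < J; ++j) v += X(i, j) * beta(j, km);
        eta[i + I * (km + 1)] = v;
      }
      double d = 0.0;
      for (int k = 0; k < K; ++k) {
        E[i + I * k] = std::exp(eta[i + I * k]);
        d += E[i + I * k];
      }
      denom[i] = d;
    }
  };
  recompute();

  // step sizes (log scale) and acceptance bookkeeping
  std::vector<double> ls_beta(J * Km, std::log(0.1)), ls_b(C * Km, std::log(0.1));
  std::vector<int> acc_beta(J * Km, 0), att_beta(J * Km, 0),
                   acc_b(C * Km, 0), att_b(C * Km, 0);
  std::vector<long> tacc_beta(J * Km, 0), tatt_beta(J * Km, 0),
                    tacc_b(C * Km, 0), tatt_b(C * Km, 0);

  const int P = Km * (J + C + 2) + 1;
  NumericMatrix draws(n_keep, P);
  const int total = n_burn + n_keep * thin;
  int stored = 0;

  for (int it = 1; it <= total; ++it) {
    // --- selection coefficients beta[j, km], category column k = km + 1 ---
    for (int km = 0; km < Km; ++km) {
      const int k = km + 1;
      double *Ek = &E[(size_t)I * k];
      for (int j = 0; j < J; ++j) {
        const int s = km * J + j;
        const double *xj = &X(0, j);
        const double ob = beta(j, km);
        const double delta = norm_rand() * std::exp(ls_beta[s]);
        const double nb = ob + delta;
        double dll = -piv * (std::fabs(nb) - std::fabs(ob));
        double prod = 1.0;  // running product of denom ratios; log taken rarely
        bool bad = false;
        for (int i = 0; i < I; ++i) {
          const double d = xj[i] * delta;
          const double ne = (d != 0.0) ? Ek[i] * std::exp(d) : Ek[i];
          scratch[i] = ne;
          const double nd = denom[i] - Ek[i] + ne;
          if (!(nd > 0.0) || !std::isfinite(nd)) { bad = true; break; }
          if (y[i] - 1 == k) dll += d;
          prod *= denom[i] / nd;
          if (prod > 1e250 || prod < 1e-250) { dll += std::log(prod); prod = 1.0; }
        }
        ++att_beta[s]; ++tatt_beta[s];
        if (!bad && std::log(unif_rand()) < dll + std::log(prod)) {
          ++acc_beta[s]; ++tacc_beta[s];
          beta(j, km) = nb;
          for (int i = 0; i < I; ++i) {
            denom[i] += scratch[i] - Ek[i];
            Ek[i] = scratch[i];
            eta[i + (size_t)I * k] += xj[i] * delta;
          }
        }
      }
    }

    // --- city random intercepts b[c, km] ---
    for (int km = 0; km < Km; ++km) {
      const int k = km + 1;
      double *Ek = &E[(size_t)I * k];
      for (int c = 0; c < C; ++c) {
        const int s = km * C + c;
        const double ob = b(c, km);
        const double delta = norm_rand() * std::exp(ls_b[s]);
        const double nb = ob + delta;
        const double f = std::exp(delta);
        double dll = -0.5 * tau[km] *
          ((nb - mu[km]) * (nb - mu[km]) - (ob - mu[km]) * (ob - mu[km]));
        double prod = 1.0;
        bool bad = false;
        for (size_t ii = 0; ii < cidx[c].size(); ++ii) {
          const int i = cidx[c][ii];
          const double ne = Ek[i] * f;
          const double nd = denom[i] - Ek[i] + ne;
          if (!(nd > 0.0) || !std::isfinite(nd)) { bad = true; break; }
          if (y[i] - 1 == k) dll += delta;
          prod *= denom[i] / nd;
          if (prod > 1e250 || prod < 1e-250) { dll += std::log(prod); prod = 1.0; }
        }
        dll += std::log(prod);
        ++att_b[s]; ++tatt_b[s];
        if (!bad && std::log(unif_rand()) < dll) {
          ++acc_b[s]; ++tacc_b[s];
          b(c, km) = nb;
          for (size_t ii = 0; ii < cidx[c].size(); ++ii) {
            const int i = cidx[c][ii];
            const double ne = Ek[i] * f;
            denom[i] += ne - Ek[i];
            Ek[i] = ne;
            eta[i + (size_t)I * k] += delta;
          }
        }
      }
    }

    // --- conjugate draws: mu_k ~ Normal, tau_k ~ Gamma (precision) ---
    for (int km = 0; km < Km; ++km) {
      double sb = 0.0;
      for (int c = 0; c < C; ++c) sb += b(c, km);
      const double prec = C * tau[km] + 0.1;  // prior Normal(0, var 10)
      const double mean = tau[km] * sb / prec;
      mu[km] = mean + norm_rand() / std::sqrt(prec);
      double ss = 0.0;
      for (int c = 0; c < C; ++c) {
        const double d = b(c, km) - mu[km];
        ss += d * d;
      }
      tau[km] = R::rgamma(1.0 + 0.5 * C, 1.0 / (1.0 + 0.5 * ss));
      if (tau[km] < 1e-8) tau[km] = 1e-8;
    }

    // --- Laplace rate pi: truncated Gamma(m + 1, sum|beta|) on [0.001, 10] ---
    {
      double S = 0.0;
      for (int km = 0; km < Km; ++km)
        for (int j = 0; j < J; ++j) S += std::fabs(beta(j, km));
      if (S < 1e-10) S = 1e-10;
      const double shape = J * Km + 1.0, scale = 1.0 / S;
      const double plo = R::pgamma(0.001, shape, scale, 1, 0);
      const double phi = R::pgamma(10.0, shape, scale, 1, 0);
      if (phi - plo > 1e-12) {
        const double u = plo + unif_rand() * (phi - plo);
        piv = R::qgamma(u, shape, scale, 1, 0);
      } else {
        piv = (plo > 0.5) ? 0.001 : 10.0;  // conditional mass outside window
      }
      if (piv < 0.001) piv = 0.001;
      if (piv > 10.0) piv = 10.0;
    }

    // --- step-size adaptation (burn-in only) ---
    if (it <= n_burn && it % adapt_interval == 0) {
      const double d = std::min(0.25, 2.0 / std::sqrt((double)(it / adapt_interval)));
      for (int s = 0; s < J * Km; ++s) {
        if (att_beta[s] > 0)
          ls_beta[s] += ((double)acc_beta[s] / att_beta[s] > target_accept) ? d : -d;
        acc_beta[s] = att_beta[s] = 0;
      }
      for (int s = 0; s < C * Km; ++s) {
        if (att_b[s] > 0)
          ls_b[s] += ((double)acc_b[s] / att_b[s] > target_accept) ? d : -d;
        acc_b[s] = att_b[s] = 0;
      }
    }

    if (it % 512 == 0) recompute();  // kill floating-point drift in caches

    if (it > n_burn && (it - n_burn) % thin == 0 && stored < n_keep) {
      int p = 0;
      for (int km = 0; km < Km; ++km)
        for (int j = 0; j < J; ++j) draws(stored, p++) = beta(j, km);
      for (int km = 0; km < Km; ++km)
        for (int c = 0; c < C; ++c) draws(stored, p++) = b(c, km);
      for (int km = 0; km < Km; ++km) draws(stored, p++) = mu[km];
      for (int km = 0; km < Km; ++km) draws(stored, p++) = tau[km];
      draws(stored, p) = piv;
      ++stored;
    }

    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector ab(J * Km), abb(C * Km);
  for (int s = 0; s < J * Km; ++s)
    ab[s] = tatt_beta[s] ? (double)tacc_beta[s] / tatt_beta[s] : NA_REAL;
  for (int s = 0; s < C * Km; ++s)
    abb[s] = tatt_b[s] ? (double)tacc_b[s] / tatt_b[s] : NA_REAL;

  return List::create(_["draws"] = draws,
                      _["accept_beta"] = ab,
                      _["accept_b"] = abb);
}
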