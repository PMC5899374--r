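// Adaptive random-walk Metropolis-within-Gibbs sampler for the three-test,
// two-population latent class model with conditional dependence between
// tests 1 and 2.  Parameter order throughout:
//   0 pi1, 1 pi2, 2 se1, 3 sp1, 4 se2, 5 sp2, 6 se3, 7 sp3,
//   8 cov_se, 9 cov_sp
#include <Rcpp.h>
using namespace Rcpp;

static const int N_PAR = 10;

// bounds of the conditional covariance given positivity probs p, q
static inline void covBounds(double p, double q, double &lo, double &hi) {
  lo = std::max(-p * q, -(1.0 - p) * (1.0 - q));
  hi = std::min(p * (1.0 - q), (1.0 - p) * q);
}

// log posterior: multinomial likelihood over 2x8 cells + Beta priors on the
// eight probability parameters + uniform priors on the covariances over
// their admissible ranges.  -Inf outside the support (incl. se3+sp3<=1).
static double logPost(const double *th, const NumericMatrix &counts,
                      const NumericMatrix &ab) {
  const double pi1 = th[0], pi2 = th[1];
  const double se1 = th[2], sp1 = th[3], se2 = th[4], sp2 = th[5];
  const double se3 = th[6], sp3 = th[7];
  const double cse = th[8], csp = th[9];

  for (int j = 0; j < 8; ++j)
    if (th[j] <= 0.0 || th[j] >= 1.0) return R_NegInf;
  if (se3 + sp3 <= 1.0) return R_NegInf;

  double loSe, hiSe, loSp, hiSp;
  covBounds(se1, se2, loSe, hiSe);
  covBounds(sp1, sp2, loSp, hiSp);
  if (cse < loSe || cse > hiSe || csp < loSp || csp > hiSp)
    return R_NegInf;

  double lp = 0.0;
  for (int pop = 0; pop < 2; ++pop) {
    const double pi = (pop == 0) ? pi1 : pi2;
    for (int cell = 0; cell < 8; ++cell) {
      const double n = counts(pop, cell);
      if (n <= 0.0) continue;
      const int i = cell / 4, j = (cell / 2) % 2, k = cell % 2;
      const double dlt = (i == j) ? 1.0 : -1.0;
      const double dis =
          ((i ? se1 : 1.0 - se1) * (j ? se2 : 1.0 - se2) + dlt * cse) *
          (k ? se3 : 1.0 - se3);
      const double nod =
          ((i ? 1.0 - sp1 : sp1) * (j ? 1.0 - sp2 : sp2) + dlt * csp) *
          (k ? 1.0 - sp3 : sp3);
      const double p = pi * dis + (1.0 - pi) * nod;
      if (p <= 0.0) return R_NegInf;
      lp += n * std::log(p);
    }
  }
  // Beta priors, shapes in sampler order for parameters 0..7
  for (int j = 0; j < 8; ++j)
    lp += R::dbeta(th[j], ab(j, 0), ab(j, 1), 1);
  // uniform covariance priors over the current admissible range
  lp += -std::log(hiSe - loSe) - std::log(hiSp - loSp);
  return lp;
}

// [[Rcpp::export]]
double lc_log_posterior_cpp(NumericVector theta, NumericMatrix counts,
                            NumericMatrix prior_ab) {
  if (theta.size() != N_PAR) stop("theta must have length 10");
  return logPost(REAL(theta), counts, prior_ab);
}

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double invlogit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// One chain.  `fixed` flags parameters that are held at their initial
// value.  Proposals: logit random walk for probabilities; for covariances a
// random walk on the logit of the position within the current admissible
// range.  Scales adapt toward ~44% acceptance during burn-in only.
// [[Rcpp::export]]
List lc_mcmc_chain_cpp(NumericMatrix counts, NumericMatrix prior_ab,
                       NumericVector init, LogicalVector fixed,
                       int burn_in, int thin, int n_keep,
                       NumericVector init_scales, bool adapt) {
  double th[N_PAR];
  for (int j = 0; j < N_PAR; ++j) th[j] = init[j];
  double lp = logPost(th, counts, prior_ab);
  if (!R_finite(lp)) stop("initial values have non-finite log posterior");

  double scales[N_PAR];
  for (int j = 0; j < N_PAR; ++j) scales[j] = init_scales[j];

  const int n_iter = burn_in + thin * n_keep;
  NumericMatrix draws(n_keep, N_PAR);
  NumericVector acc_rate(N_PAR);
  IntegerVector n_upd(N_PAR);
  int win_acc[N_PAR] = {0}, win_n[N_PAR] = {0};
  const int ADAPT_WIN = 100;

  RNGScope rngScope;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < N_PAR; ++j) {
      if (fixed[j]) continue;
      const double old = th[j];
      bool ok = true;
      double log_jac = 0.0;  // log q(old|new) - log q(new|old)
      if (j < 8) {
        const double z = logit(old) + scales[j] * R::norm_rand();
        th[j] = invlogit(z);
        // Jacobian of the logit transform: dp/dz = p(1-p)
        log_jac = std::log(th[j] * (1.0 - th[j])) -
                  std::log(old * (1.0 - old));
        if (th[j] <= 0.0 || th[j] >= 1.0 || !R_finite(th[j])) ok = false;
      } else {
        double lo, hi;
        if (j == 8) covBounds(th[2], th[4], lo, hi);
        else covBounds(th[3], th[5], lo, hi);
        const double w = (old - lo) / (hi - lo);
        if (w <= 0.0 || w >= 1.0) {
          // current value sits on the boundary of the (updated) range;
          // nudge strictly inside before transforming
          const double eps = 1e-12;
          const double wc = std::min(1.0 - eps, std::max(eps, w));
          const double z = logit(wc) + scales[j] * R::norm_rand();
          const double wn = invlogit(z);
          th[j] = lo + (hi - lo) * wn;
          log_jac = std::log(wn * (1.0 - wn)) - std::log(wc * (1.0 - wc));
        } else {
          const double z = logit(w) + scales[j] * R::norm_rand();
          const double wn = invlogit(z);
          th[j] = lo + (hi - lo) * wn;
          log_jac = std::log(wn * (1.0 - wn)) - std::log(w * (1.0 - w));
        }
      }
      double lp_new = ok ? logPost(th, counts, prior_ab) : R_NegInf;
      bool accept = false;
      if (R_finite(lp_new)) {
        const double log_alpha = lp_new - lp + log_jac;
        accept = (log_alpha >= 0.0) || (std::log(unif_rand()) < log_alpha);
      }
      if (accept) {
        lp = lp_new;
      } else {
        th[j] = old;
      }
      if (it >= burn_in) {
        if (accept) acc_rate[j] += 1.0;
        n_upd[j] += 1;
      } else if (adapt) {
        win_n[j] += 1;
        if (accept) win_acc[j] += 1;
        if (win_n[j] == ADAPT_WIN) {
          const double rate = (double)win_acc[j] / ADAPT_WIN;
          scales[j] *= std::exp(rate - 0.44);
          if (scales[j] < 1e-3) scales[j] = 1e-3;
          if (scales[j] > 10.0) scales[j] = 10.0;
          win_n[j] = 0;
          win_acc[j] = 0;
        }
      }
    }
    if (it >= burn_in && ((it - burn_in + 1) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < N_PAR; ++j) draws(kept, j) = th[j];
      ++kept;
    }
  }
  for (int j = 0; j < N_PAR; ++j)
    if (n_upd[j] > 0) acc_rate[j] /= n_upd[j];

  NumericVector final_scales(N_PAR);
  for (int j = 0; j < N_PAR; ++j) final_scales[j] = scales[j];
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["scales"] = final_scales);
}
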