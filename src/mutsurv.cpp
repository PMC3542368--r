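// Core numerical routines: Cox partial-likelihood Newton solver (Efron/Breslow),
// multi-gene two-group log-rank screen, and the complete leave-one-out
// cross-validation loop with per-fold gene re-selection and standardization.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Tie-group layout of a cohort sorted by descending follow-up time, so the
// risk set at each event time is accumulated by a single forward pass.
struct TimeGroups {
  std::vector<int> order;        // patient indices, time descending
  std::vector<int> group_start;  // offsets into order; one group per distinct time
  std::vector<int> group_end;
};

TimeGroups make_groups(const arma::vec& time) {
  const int n = time.n_elem;
  TimeGroups tg;
  tg.order.resize(n);
  for (int i = 0; i < n; ++i) tg.order[i] = i;
  std::stable_sort(tg.order.begin(), tg.order.end(),
                   [&](int a, int b) { return time[a] > time[b]; });
  int start = 0;
  for (int k = 1; k <= n; ++k) {
    if (k == n || time[tg.order[k]] != time[tg.order[start]]) {
      tg.group_start.push_back(start);
      tg.group_end.push_back(k);
      start = k;
    }
  }
  return tg;
}

// Partial log-likelihood, score and information at beta.  X rows are patients.
void cox_eval(const arma::mat& X, const arma::ivec& event, const TimeGroups& tg,
              bool efron, const arma::vec& beta,
              double& ll, arma::vec& grad, arma::mat& info) {
  const int p = X.n_cols;
  arma::vec eta = X * beta;
  arma::vec w = arma::exp(eta);
  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  ll = 0.0;
  grad.zeros(p);
  info.zeros(p, p);

  for (size_t g = 0; g < tg.group_start.size(); ++g) {
    int d = 0;
    double S0d = 0.0;
    arma::vec S1d(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);
    for (int k = tg.group_start[g]; k < tg.group_end[g]; ++k) {
      const int i = tg.order[k];
      const arma::rowvec xi = X.row(i);
      S0 += w[i];
      S1 += w[i] * xi.t();
      S2 += w[i] * (xi.t() * xi);
      if (event[i] == 1) {
        ++d;
        ll += eta[i];
        grad += xi.t();
        if (efron) {
          S0d += w[i];
          S1d += w[i] * xi.t();
          S2d += w[i] * (xi.t() * xi);
        }
      }
    }
    if (d == 0) continue;
    if (efron) {
      for (int k = 0; k < d; ++k) {
        const double f = double(k) / double(d);
        const double den = S0 - f * S0d;
        const arma::vec mu = (S1 - f * S1d) / den;
        ll -= std::log(den);
        grad -= mu;
        info += (S2 - f * S2d) / den - mu * mu.t();
      }
    } else {
      const arma::vec mu = S1 / S0;
      ll -= d * std::log(S0);
      grad -= d * mu;
      info += d * (S2 / S0 - mu * mu.t());
    }
  }
}

}  // namespace

// Newton-Raphson maximization of the Cox partial likelihood from beta = 0,
// with step-halving on likelihood decrease.  Non-convergence (e.g. monotone
// likelihood) is flagged, never an error.
// [[Rcpp::export]]
List cox_fit_cpp(const arma::mat& X, const arma::vec& time,
                 const arma::ivec& event, bool efron = true, int maxit = 50,
                 double eps_grad = 1e-9, double eps_loglik = 1e-12) {
  const int p = X.n_cols;
  TimeGroups tg = make_groups(time);
  arma::vec beta(p, arma::fill::zeros), grad(p);
  arma::mat info(p, p);
  double ll;
  cox_eval(X, event, tg, efron, beta, ll, grad, info);
  const double ll0 = ll;
  bool converged = false, singular = false;
  int iter = 0;
  while (iter < maxit) {
    if (arma::abs(grad).max() <= eps_grad) { converged = true; break; }
    arma::vec step;
    if (!arma::solve(step, info, grad, arma::solve_opts::no_approx)) {
      singular = true; break;
    }
    double ll_new;
    arma::vec beta_new, grad_new;
    arma::mat info_new;
    double shrink = 1.0;
    for (int h = 0; h < 25; ++h) {
      beta_new = beta + shrink * step;
      cox_eval(X, event, tg, efron, beta_new, ll_new, grad_new, info_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      shrink *= 0.5;
    }
    ++iter;
    const double rel = std::fabs(ll_new - ll) / (std::fabs(ll) + 1e-300);
    beta = beta_new; grad = grad_new; info = info_new;
    const bool small_change = rel <= eps_loglik;
    ll = ll_new;
    if (arma::abs(grad).max() <= eps_grad || small_change) {
      converged = true;
      break;
    }
  }
  arma::vec se(p);
  arma::mat vcov;
  if (arma::inv_sympd(vcov, info)) {
    se = arma::sqrt(vcov.diag());
  } else {
    vcov = arma::pinv(info);
    se = arma::sqrt(arma::abs(vcov.diag()));
  }
  return List::create(_["coefficients"] = beta, _["se"] = se,
                      _["loglik0"] = ll0, _["loglik"] = ll,
                      _["score"] = grad, _["converged"] = converged && !singular,
                      _["n_iterations"] = iter, _["vcov"] = vcov);
}

namespace {

// Sparse per-patient list of mutated gene indices.
std::vector<std::vector<int>> gene_lists(const IntegerMatrix& X) {
  const int n = X.nrow(), G = X.ncol();
  std::vector<std::vector<int>> lists(n);
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < n; ++i)
      if (X(i, g) != 0) lists[i].push_back(g);
  return lists;
}

// Two-group log-rank accumulation (mutated vs wild-type), all genes at once,
// optionally excluding one patient (LOOCV fold).  Fills per-gene O-E sums,
// hypergeometric variances, and mutated-patient counts.
void logrank_screen_core(const std::vector<std::vector<int>>& lists, int G,
                         const arma::ivec& event, const TimeGroups& tg,
                         int exclude, std::vector<double>& OE,
                         std::vector<double>& V, std::vector<int>& m1) {
  std::fill(OE.begin(), OE.end(), 0.0);
  std::fill(V.begin(), V.end(), 0.0);
  std::fill(m1.begin(), m1.end(), 0);
  std::vector<double> riskM(G, 0.0);
  int riskN = 0;
  std::vector<int> ev_genes;  // genes mutated among this group's events
  std::vector<int> ev_count(G, 0);
  for (size_t gr = 0; gr < tg.group_start.size(); ++gr) {
    int d = 0;
    ev_genes.clear();
    for (int k = tg.group_start[gr]; k < tg.group_end[gr]; ++k) {
      const int i = tg.order[k];
      if (i == exclude) continue;
      ++riskN;
      for (int g : lists[i]) { riskM[g] += 1.0; ++m1[g]; }
      if (event[i] == 1) {
        ++d;
        for (int g : lists[i]) {
          if (ev_count[g]++ == 0) ev_genes.push_back(g);
        }
      }
    }
    if (d > 0 && riskN > 0) {
      const double dn = double(d) / double(riskN);
      const double vfac =
          riskN > 1 ? double(d) * double(riskN - d) / double(riskN - 1) : 0.0;
      for (int g = 0; g < G; ++g) {
        const double pr = riskM[g] / double(riskN);
        OE[g] -= dn * riskM[g];
        V[g] += vfac * pr * (1.0 - pr);
      }
      for (int g : ev_genes) { OE[g] += ev_count[g]; ev_count[g] = 0; }
    } else {
      for (int g : ev_genes) ev_count[g] = 0;
    }
  }
}

}  // namespace

// Per-gene (or per arbitrary binary grouping column) two-group log-rank
// statistics on the full cohort.
// [[Rcpp::export]]
List logrank_screen_cpp(const IntegerMatrix& X, const arma::vec& time,
                        const arma::ivec& event) {
  const int n = X.nrow(), G = X.ncol();
  TimeGroups tg = make_groups(time);
  std::vector<std::vector<int>> lists = gene_lists(X);
  std::vector<double> OE(G), V(G);
  std::vector<int> m1(G);
  logrank_screen_core(lists, G, event, tg, -1, OE, V, m1);
  NumericVector stat(G), oe(G), var(G);
  IntegerVector n1(G);
  for (int g = 0; g < G; ++g) {
    oe[g] = OE[g];
    var[g] = V[g];
    n1[g] = m1[g];
    const bool degenerate = m1[g] == 0 || m1[g] == n || V[g] <= 0.0;
    stat[g] = degenerate ? NA_REAL : OE[g] * OE[g] / V[g];
  }
  return List::create(_["statistic"] = stat, _["obs_minus_exp"] = oe,
                      _["variance"] = var, _["n_group1"] = n1);
}

// Complete LOOCV: per fold, re-screen genes by log-rank at level alpha,
// standardize the selected columns by training mean/sd, fit Cox (with optional
// unstandardized clinical covariates forced in), and score the held-out
// patient with the training model.  Because out-of-fold linear predictors from
// different folds are not on a common scale (the fold-specific centering terms
// of patients carrying none of the selected genes track the held-out outcome),
// each held-out score is also reported centered at the median of the fold's
// training-set scores; the centered scores are the ones the median split and
// downstream ROC should use.
// [[Rcpp::export]]
List loocv_cpp(const IntegerMatrix& X, const arma::vec& time,
               const arma::ivec& event, double alpha,
               Nullable<NumericMatrix> Zopt, bool efron = true,
               bool keep_folds = true) {
  const int n = X.nrow(), G = X.ncol();
  const double crit = R::qchisq(alpha, 1.0, 0, 0);  // upper-tail critical value
  TimeGroups tg = make_groups(time);
  std::vector<std::vector<int>> lists = gene_lists(X);

  arma::mat Z;
  int q = 0;
  if (Zopt.isNotNull()) {
    Z = as<arma::mat>(Zopt.get());
    q = Z.n_cols;
  }

  std::vector<double> OE(G), V(G);
  std::vector<int> m1(G);
  NumericVector scores(n), scores_raw(n);
  IntegerVector sel_count(G, 0);
  int n_empty = 0, n_nonconverged = 0;
  List folds(keep_folds ? n : 0);

  std::vector<int> train_idx(n - 1);
  for (int i = 0; i < n; ++i) {
    logrank_screen_core(lists, G, event, tg, i, OE, V, m1);
    std::vector<int> sel;
    for (int g = 0; g < G; ++g) {
      if (m1[g] == 0 || m1[g] == n - 1 || V[g] <= 0.0) continue;
      if (OE[g] * OE[g] / V[g] > crit) sel.push_back(g);
    }
    for (int g : sel) ++sel_count[g];
    const int s = int(sel.size());

    int t = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) train_idx[t++] = j;

    arma::vec mu(s), sd(s);
    for (int k = 0; k < s; ++k) {
      const int g = sel[k];
      const double m = double(m1[g]) / double(n - 1);
      mu[k] = m;
      // binary column: sample sd with n-1 denominator in closed form
      sd[k] = std::sqrt(double(m1[g]) * double(n - 1 - m1[g]) /
                        (double(n - 1) * double(n - 2)));
    }

    // clinical columns constant within the fold carry no information; drop
    std::vector<int> zkeep;
    for (int c = 0; c < q; ++c) {
      double zmin = arma::datum::inf, zmax = -arma::datum::inf;
      for (int j : train_idx) {
        zmin = std::min(zmin, Z(j, c));
        zmax = std::max(zmax, Z(j, c));
      }
      if (zmax > zmin) zkeep.push_back(c);
    }
    const int qk = int(zkeep.size());

    double score_i = 0.0, train_median = 0.0;
    arma::vec beta;
    bool converged = true;
    if (s + qk > 0) {
      arma::mat W(n - 1, s + qk);
      arma::vec tt(n - 1);
      arma::ivec ee(n - 1);
      for (int r = 0; r < n - 1; ++r) {
        const int j = train_idx[r];
        tt[r] = time[j];
        ee[r] = event[j];
        for (int k = 0; k < s; ++k)
          W(r, k) = (double(X(j, sel[k])) - mu[k]) / sd[k];
        for (int c = 0; c < qk; ++c) W(r, s + c) = Z(j, zkeep[c]);
      }
      List fit = cox_fit_cpp(W, tt, ee, efron, 50, 1e-9, 1e-12);
      beta = as<arma::vec>(fit["coefficients"]);
      converged = as<bool>(fit["converged"]);
      if (!converged) ++n_nonconverged;
      for (int k = 0; k < s; ++k)
        score_i += beta[k] * (double(X(i, sel[k])) - mu[k]) / sd[k];
      for (int c = 0; c < qk; ++c) score_i += beta[s + c] * Z(i, zkeep[c]);
      arma::vec train_scores = W * beta;
      arma::vec ts = arma::sort(train_scores);
      const int m = ts.n_elem;
      train_median = (m % 2 == 1) ? ts[m / 2]
                                  : 0.5 * (ts[m / 2 - 1] + ts[m / 2]);
    }
    if (s == 0) ++n_empty;
    scores_raw[i] = score_i;
    scores[i] = score_i - train_median;

    if (keep_folds) {
      NumericVector p_sel(s), coef_g(s), fmu(s), fsd(s);
      IntegerVector gsel(s);
      for (int k = 0; k < s; ++k) {
        const int g = sel[k];
        gsel[k] = g + 1;
        p_sel[k] = R::pchisq(OE[g] * OE[g] / V[g], 1.0, 0, 0);
        coef_g[k] = (s + qk > 0) ? beta[k] : NA_REAL;
        fmu[k] = mu[k];
        fsd[k] = sd[k];
      }
      NumericVector coef_z(q, NA_REAL);
      for (int c = 0; c < qk; ++c) coef_z[zkeep[c]] = beta[s + c];
      folds[i] = List::create(_["genes"] = gsel, _["p_value"] = p_sel,
                              _["mean"] = fmu, _["sd"] = fsd,
                              _["coef"] = coef_g, _["coef_clinical"] = coef_z,
                              _["converged"] = converged);
    }
  }
  return List::create(_["scores"] = scores, _["scores_raw"] = scores_raw,
                      _["selection_count"] = sel_count,
                      _["folds"] = keep_folds ? SEXP(folds) : R_NilValue,
                      _["n_empty_folds"] = n_empty,
                      _["n_nonconverged"] = n_nonconverged);
}
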