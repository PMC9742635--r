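#include <Rcpp.h>
using namespace Rcpp;

// Likelihood units: an IPD study-arm (rows of individuals) or an AgD arm
// (category counts + the study's integration grid). Category probabilities
// come from an ordered probit/logit model: inclusive probability of being
// above threshold c is F(eta - a_c), categories by successive differencing.

static inline double plink(double x, int link) {
  return link == 0 ? R::pnorm(x, 0.0, 1.0, 1, 0) : R::plogis(x, 0.0, 1.0, 1, 0);
}

// category probabilities for one linear predictor value
static inline void cat_probs(double eta, const double* cuts, int C,
                             int link, double* out) {
  double prev = 1.0;
  for (int c = 0; c < C - 1; ++c) {
    double q = plink(eta - cuts[c], link);
    out[c] = prev - q;
    prev = q;
  }
  out[C - 1] = prev;
}

static inline double xdot(const NumericMatrix& X, int row,
                          const NumericVector& b) {
  double s = 0.0;
  for (int j = 0; j < b.size(); ++j) s += X(row, j) * b[j];
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_unit_loglik(List units, NumericVector mu, NumericVector cuts,
                              NumericVector beta1, NumericMatrix B2,
                              NumericVector eff, IntegerVector which,
                              int link) {
  const int C = cuts.size() + 1;
  const int p = beta1.size();
  std::vector<double> pc(C);
  NumericVector out(which.size());
  NumericVector b(p);
  for (int w = 0; w < which.size(); ++w) {
    int u = which[w] - 1;
    List unit = units[u];
    int type = as<int>(unit["type"]);
    int j = as<int>(unit["study"]) - 1;
    int k = as<int>(unit["trt"]) - 1;
    NumericMatrix X = unit["X"];
    double base = mu[j] + eff[u];
    for (int q = 0; q < p; ++q) b[q] = beta1[q] + B2(q, k);
    double ll = 0.0;
    if (type == 1) {
      IntegerVector y = unit["y"];
      for (int i = 0; i < X.nrow(); ++i) {
        double eta = base + xdot(X, i, b);
        cat_probs(eta, cuts.begin(), C, link, pc.data());
        double pr = pc[y[i] - 1];
        ll += std::log(pr > 1e-300 ? pr : 1e-300);
      }
    } else {
      NumericVector counts = unit["counts"];
      std::vector<double> pbar(C, 0.0);
      int n = X.nrow();
      for (int i = 0; i < n; ++i) {
        double eta = base + xdot(X, i, b);
        cat_probs(eta, cuts.begin(), C, link, pc.data());
        for (int c = 0; c < C; ++c) pbar[c] += pc[c];
      }
      for (int c = 0; c < C; ++c) {
        if (counts[c] > 0.0) {
          double pr = pbar[c] / n;
          ll += counts[c] * std::log(pr > 1e-300 ? pr : 1e-300);
        }
      }
    }
    out[w] = ll;
  }
  return out;
}

// Per-point fitted category probabilities in fixed point order:
// IPD units contribute one row per individual, AgD units one row per arm
// (grid-averaged probabilities).
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_probs(List units, NumericVector mu,
                                  NumericVector cuts, NumericVector beta1,
                                  NumericMatrix B2, NumericVector eff,
                                  int link) {
  const int C = cuts.size() + 1;
  const int p = beta1.size();
  int total = 0;
  for (int u = 0; u < units.size(); ++u) {
    List unit = units[u];
    int type = as<int>(unit["type"]);
    if (type == 1) {
      NumericMatrix X = unit["X"];
      total += X.nrow();
    } else total += 1;
  }
  NumericMatrix out(total, C);
  std::vector<double> pc(C);
  NumericVector b(p);
  int row = 0;
  for (int u = 0; u < units.size(); ++u) {
    List unit = units[u];
    int type = as<int>(unit["type"]);
    int j = as<int>(unit["study"]) - 1;
    int k = as<int>(unit["trt"]) - 1;
    NumericMatrix X = unit["X"];
    double base = mu[j] + eff[u];
    for (int q = 0; q < p; ++q) b[q] = beta1[q] + B2(q, k);
    if (type == 1) {
      for (int i = 0; i < X.nrow(); ++i) {
        double eta = base + xdot(X, i, b);
        cat_probs(eta, cuts.begin(), C, link, pc.data());
        for (int c = 0; c < C; ++c) out(row, c) = pc[c];
        ++row;
      }
    } else {
      std::vector<double> pbar(C, 0.0);
      int n = X.nrow();
      for (int i = 0; i < n; ++i) {
        double eta = base + xdot(X, i, b);
        cat_probs(eta, cuts.begin(), C, link, pc.data());
        for (int c = 0; c < C; ++c) pbar[c] += pc[c];
      }
      for (int c = 0; c < C; ++c) out(row, c) = pbar[c] / n;
      ++row;
    }
  }
  return out;
}

// Average category probabilities over a fixed grid for many posterior draws.
// G: grid (n x p, already centered/scaled); per draw d the linear predictor
// is eta_i = mu[d] + G_i . B(d,) + eff[d], cutpoints cuts(d,).
// Returns draws x C matrix of grid-averaged category probabilities.
// [[Rcpp::export]]
NumericMatrix cpp_avg_probs_draws(NumericMatrix G, NumericVector mu,
                                  NumericMatrix B, NumericVector eff,
                                  NumericMatrix cuts, int link) {
  const int D = mu.size();
  const int n = G.nrow();
  const int p = G.ncol();
  const int C = cuts.ncol() + 1;
  NumericMatrix out(D, C);
  std::vector<double> pc(C), pbar(C);
  std::vector<double> xb(n);
  NumericVector b(p);
  for (int d = 0; d < D; ++d) {
    for (int q = 0; q < p; ++q) b[q] = B(d, q);
    for (int i = 0; i < n; ++i) xb[i] = xdot(G, i, b);
    std::fill(pbar.begin(), pbar.end(), 0.0);
    double base = mu[d] + eff[d];
    const double* ct = &cuts(d, 0);
    // cuts is column-major; copy the row
    std::vector<double> crow(C - 1);
    for (int c = 0; c < C - 1; ++c) crow[c] = cuts(d, c);
    for (int i = 0; i < n; ++i) {
      cat_probs(base + xb[i], crow.data(), C, link, pc.data());
      for (int c = 0; c < C; ++c) pbar[c] += pc[c];
    }
    for (int c = 0; c < C; ++c) out(d, c) = pbar[c] / n;
    (void)ct;
  }
  return out;
}

// Solve, per draw, for the intercept mu* such that the grid-averaged
// inclusive probability at threshold `thr` (1-based) equals pstar, by
// safeguarded bisection on [-40, 40]. Returns NA when the target is outside
// the attainable range.
// [[Rcpp::export]]
NumericVector cpp_solve_mustar(NumericMatrix G, NumericMatrix B,
                               NumericVector eff, NumericMatrix cuts,
                               NumericVector pstar, int thr, int link,
                               double tol) {
  const int D = eff.size();
  const int n = G.nrow();
  const int p = G.ncol();
  NumericVector out(D);
  NumericVector b(p);
  std::vector<double> xb(n);
  for (int d = 0; d < D; ++d) {
    for (int q = 0; q < p; ++q) b[q] = B(d, q);
    for (int i = 0; i < n; ++i) xb[i] = xdot(G, i, b);
    double a = cuts(d, thr - 1);
    double offset = eff[d] - a;
    // inclusive prob at threshold: mean_i F(mu + xb_i + offset)
    auto f = [&](double m) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += plink(m + xb[i] + offset, link);
      return s / n;
    };
    double lo = -40.0, hi = 40.0;
    double flo = f(lo), fhi = f(hi);
    double target = pstar[d];
    if (target <= flo || target >= fhi) {
      out[d] = NA_REAL;
      continue;
    }
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      double fm = f(mid);
      if (std::fabs(fm - target) < tol && (hi - lo) < 1e-8) { lo = hi = mid; break; }
      if (fm < target) lo = mid; else hi = mid;
      if ((hi - lo) < 1e-10) break;
    }
    out[d] = 0.5 * (lo + hi);
  }
  return out;
}
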