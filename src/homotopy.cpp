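// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Lasso homotopy (LARS with drops) for
//   min ||beta||_1  subject to  ||y - B' beta|| <= epsilon
// where the rows of B (n x m) are the penalty-transformed training samples
// (the weighted problem min ||W alpha||_1 is mapped here by the caller via
// beta = w * alpha, rows b_i = x_i / w_i).
//
// The algorithm tracks the exact piecewise-linear solution path of the
// penalized problem from lambda_max down, and stops exactly where the
// residual norm first reaches epsilon (solving the quadratic for the
// crossing inside the segment). If the path reaches its minimum-residual
// end without attaining epsilon, the terminal solution (the l1-minimal
// least-squares solution on the visited active set) is returned and the
// caller flags infeasibility.
// [[Rcpp::export(name = ".homotopy_cpp")]]
List homotopy_cpp(const arma::mat& B, const arma::vec& y, double epsilon,
                  int max_steps, double ridge) {
  const int n = B.n_rows;
  arma::vec beta(n, arma::fill::zeros);
  arma::vec cvec = B * y;                 // correlations b_i' r
  double lam = arma::abs(cvec).max();
  arma::vec r = y;
  std::vector<int> A;                     // active set
  std::vector<bool> in_A(n, false);
  {
    arma::uword j = arma::index_max(arma::abs(cvec));
    A.push_back((int)j);
    in_A[j] = true;
  }
  int steps = 0;
  bool hit_eps = false;
  if (arma::norm(y) <= epsilon) {
    return List::create(_["beta"] = beta, _["lambda"] = R_PosInf,
                        _["steps"] = 0, _["residual"] = arma::norm(y),
                        _["feasible"] = true);
  }
  while (steps < max_steps) {
    ++steps;
    const int k = (int)A.size();
    arma::uvec Ai(k);
    for (int i = 0; i < k; ++i) Ai[i] = (arma::uword)A[i];
    arma::mat BA = B.rows(Ai);            // k x m
    arma::vec sA(k);
    for (int i = 0; i < k; ++i) sA[i] = (cvec[A[i]] >= 0.0) ? 1.0 : -1.0;
    arma::mat GA = BA * BA.t();
    double tr = arma::trace(GA) / k;
    GA.diag() += ridge * (tr > 0 ? tr : 1.0);
    arma::vec d;
    if (!arma::solve(d, GA, sA, arma::solve_opts::no_approx)) break;
    arma::vec u = BA.t() * d;             // direction of the fitted values
    arma::vec a_corr = B * u;             // d(correlation)/d(gamma)
    double gam = lam;                     // default: ride to lambda = 0
    int enter = -1, drop = -1;
    for (int j = 0; j < n; ++j) {         // entry events
      if (in_A[j]) continue;
      double den1 = 1.0 - a_corr[j];
      double den2 = 1.0 + a_corr[j];
      // a slightly negative candidate is a numerically tied column that
      // must enter with a zero-length step
      double g1 = (den1 > 1e-14) ? (lam - cvec[j]) / den1 : -1.0;
      double g2 = (den2 > 1e-14) ? (lam + cvec[j]) / den2 : -1.0;
      if (g1 > -1e-9 * lam && g1 < gam) { gam = std::max(g1, 0.0); enter = j; drop = -1; }
      if (g2 > -1e-9 * lam && g2 < gam) { gam = std::max(g2, 0.0); enter = j; drop = -1; }
    }
    for (int i = 0; i < k; ++i) {         // drop events
      if (d[i] == 0.0) continue;
      double g = -beta[A[i]] / d[i];
      if (g > 1e-12 && g < gam) { gam = g; drop = A[i]; enter = -1; }
    }
    // epsilon crossing inside the segment?
    double aa = arma::dot(u, u);
    double bb = arma::dot(r, u);
    double cc = arma::dot(r, r) - epsilon * epsilon;
    if (cc <= 0.0) { hit_eps = true; break; }
    if (aa > 0.0) {
      double disc = bb * bb - aa * cc;
      if (disc >= 0.0) {
        double g_eps = (bb - std::sqrt(disc)) / aa;
        if (g_eps > 0.0 && g_eps <= gam) {
          for (int i = 0; i < k; ++i) beta[A[i]] += g_eps * d[i];
          r -= g_eps * u;
          lam -= g_eps;
          hit_eps = true;
          break;
        }
      }
    }
    for (int i = 0; i < k; ++i) beta[A[i]] += gam * d[i];
    r -= gam * u;
    cvec -= gam * a_corr;
    lam -= gam;
    if (lam <= 1e-14 * arma::abs(cvec).max() || lam <= 0.0) break;
    if (drop >= 0) {
      beta[drop] = 0.0;
      in_A[drop] = false;
      A.erase(std::remove(A.begin(), A.end(), drop), A.end());
      if (A.empty()) break;
    } else if (enter >= 0) {
      A.push_back(enter);
      in_A[enter] = true;
    } else {
      break;                              // rode to lambda = 0
    }
  }
  double resid = arma::norm(y - B.t() * beta);
  return List::create(_["beta"] = beta,
                      _["lambda"] = lam,
                      _["steps"] = steps,
                      _["residual"] = resid,
                      _["feasible"] = hit_eps || resid <= epsilon + 1e-6);
}
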