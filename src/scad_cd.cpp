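#include <Rcpp.h>
using namespace Rcpp;

// SCAD penalty primitive p_lambda(|beta|).
static inline double scad_pen(double babs, double lam, double a) {
  if (babs <= lam) return lam * babs;
  if (babs <= a * lam)
    return (2.0 * a * lam * babs - babs * babs - lam * lam) / (2.0 * (a - 1.0));
  return lam * lam * (a + 1.0) / 2.0;
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Exact minimizer of f(x) = 0.5*v*x^2 - z*x + pen(|x|) for the SCAD (or
// lasso) penalty with curvature v > 0.  Each branch of the penalty gives a
// quadratic whose stationary point is clamped into the branch region; the
// global minimizer is found by evaluating f at every candidate (robust also
// when v <= 1/(a-1) and the middle branch is non-convex).
static double univariate_update(double z, double v, double lam, double a,
                                bool lasso) {
  if (lasso) return soft(z, lam) / v;
  double cand[6];
  int nc = 0;
  double s = (z >= 0) ? 1.0 : -1.0;
  // branch |x| <= lam
  double c1 = soft(z, lam) / v;
  if (std::abs(c1) > lam) c1 = s * lam;
  cand[nc++] = c1;
  // branch lam < |x| <= a*lam
  double denom = v - 1.0 / (a - 1.0);
  if (denom > 1e-12) {
    double c2 = soft(z, a * lam / (a - 1.0)) / denom;
    if (std::abs(c2) < lam) c2 = s * lam;
    if (std::abs(c2) > a * lam) c2 = s * a * lam;
    cand[nc++] = c2;
  }
  // branch |x| > a*lam (unpenalized slope)
  double c3 = z / v;
  if (std::abs(c3) < a * lam) c3 = s * a * lam;
  cand[nc++] = c3;
  cand[nc++] = 0.0;
  cand[nc++] = s * lam;
  cand[nc++] = s * a * lam;

  double best = 0.0, fbest = R_PosInf;
  for (int i = 0; i < nc; ++i) {
    double x = cand[i];
    double f = 0.5 * v * x * x - z * x + scad_pen(std::abs(x), lam, a);
    if (f < fbest - 1e-15 || (std::abs(f - fbest) <= 1e-15 && std::abs(x) < std::abs(best))) {
      fbest = f;
      best = x;
    }
  }
  return best;
}

static double objective(const NumericMatrix& V, const NumericVector& b,
                        const NumericVector& beta, const LogicalVector& pen,
                        double lam, double a, bool lasso) {
  int m = b.size();
  double quad = 0.0, lin = 0.0, penalty = 0.0;
  for (int j = 0; j < m; ++j) {
    if (beta[j] == 0.0) continue;
    double vb = 0.0;
    for (int l = 0; l < m; ++l) vb += V(l, j) * beta[l];
    quad += beta[j] * vb;
    lin += b[j] * beta[j];
  }
  for (int j = 0; j < m; ++j) {
    if (pen[j] && beta[j] != 0.0) {
      double ab = std::abs(beta[j]);
      penalty += lasso ? lam * ab : scad_pen(ab, lam, a);
    }
  }
  return 0.5 * quad - lin + penalty;
}

// Cyclic coordinate descent over the quadratic Lin-Ying loss
// 0.5*beta'V beta - b'beta plus a SCAD/lasso penalty on the masked columns,
// solved along a (descending) lambda path with warm starts.
// [[Rcpp::export]]
List scad_cd_path(NumericMatrix V, NumericVector b, LogicalVector penalized,
                  NumericVector lambdas, double a, double tol, int max_iter,
                  bool lasso, NumericVector beta_init, bool check_objective) {
  int m = b.size();
  int nlam = lambdas.size();
  NumericMatrix beta_path(m, nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> r(m); // residual r_j = b_j - sum_l V(j,l) beta_l
  const double* Vp = &V(0, 0); // column-major, columns contiguous

  for (int j = 0; j < m; ++j) {
    double vb = 0.0;
    const double* Vrow = Vp + (size_t)j * m; // V column j == row j (symmetric)
    for (int l = 0; l < m; ++l) vb += Vrow[l] * beta[l];
    r[j] = b[j] - vb;
  }

  bool increased = false;
  for (int k = 0; k < nlam; ++k) {
    double lam = lambdas[k];
    int it = 0;
    bool conv = false;
    double prev_obj = R_PosInf;
    if (check_objective) {
      NumericVector bv(beta.begin(), beta.end());
      prev_obj = objective(V, b, bv, penalized, lam, a, lasso);
    }
    for (; it < max_iter; ++it) {
      double maxchange = 0.0;
      for (int j = 0; j < m; ++j) {
        const double* Vcol = Vp + (size_t)j * m;
        double v = Vcol[j];
        double old = beta[j];
        double z = r[j] + v * old;
        double bnew;
        if (v <= 0.0) {
          bnew = 0.0; // degenerate column: coefficient pinned at zero
        } else if (!penalized[j]) {
          bnew = z / v;
        } else {
          bnew = univariate_update(z, v, lam, a, lasso);
        }
        double diff = bnew - old;
        if (diff != 0.0) {
          beta[j] = bnew;
          for (int l = 0; l < m; ++l) r[l] -= Vcol[l] * diff;
          double ad = std::abs(diff);
          if (ad > maxchange) maxchange = ad;
        }
      }
      if (check_objective) {
        NumericVector bv(beta.begin(), beta.end());
        double obj = objective(V, b, bv, penalized, lam, a, lasso);
        if (obj > prev_obj + 1e-10) increased = true;
        prev_obj = obj;
      }
      if (maxchange < tol) { conv = true; ++it; break; }
    }
    iters[k] = it;
    converged[k] = conv;
    for (int j = 0; j < m; ++j) beta_path(j, k) = beta[j];
  }

  return List::create(_["beta"] = beta_path, _["iters"] = iters,
                      _["converged"] = converged,
                      _["objective_increased"] = increased);
}
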