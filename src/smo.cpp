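// Deterministic SMO solver for the soft-margin kernel SVM dual.
//
// Follows Platt's SMO with an error cache and the |E1 - E2| second-choice
// heuristic, but with all randomized scan orders replaced by fixed orders so
// that training is bit-reproducible. The kernel matrix is precomputed by the
// caller; problems here are small (tens to a few hundred samples).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SMO {
  const NumericMatrix& K;
  const NumericVector& y;
  const NumericVector& C;   // per-sample box constraint (class weighting)
  double tol;
  double eps;
  int n;
  std::vector<double> alpha;
  std::vector<double> E;    // E_i = f(x_i) - y_i, f includes b
  double b;

  SMO(const NumericMatrix& K_, const NumericVector& y_,
      const NumericVector& C_, double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), eps(1e-12), n(K_.nrow()),
        alpha(n, 0.0), E(n), b(0.0) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = E[i1], E2 = E[i2];
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C[i2], C[i1] + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C[i1]);
      H = std::min(C[i2], a1 + a2);
    }
    if (L >= H) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // objective at the ends of the feasible segment
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L);
      double H1 = a1 + s * (a2 - H);
      double Lobj = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double Hobj = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (Lobj < Hobj - eps) a2new = L;
      else if (Lobj > Hobj + eps) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }

    // threshold update
    double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    bool a1free = a1new > eps && a1new < C[i1] - eps;
    bool a2free = a2new > eps && a2new < C[i2] - eps;
    if (a1free) bnew = b1;
    else if (a2free) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C[i2]) || (r2 > tol && a2 > 0)) {
      // heuristic 1: maximize |E1 - E2| over non-bound alphas
      int best = -1;
      double bestgap = 0.0;
      for (int i = 0; i < n; ++i) {
        if (alpha[i] > eps && alpha[i] < C[i] - eps) {
          double gap = std::fabs(E[i] - E2);
          if (gap > bestgap) { bestgap = gap; best = i; }
        }
      }
      if (best >= 0 && takeStep(best, i2)) return true;
      // heuristic 2: all non-bound, fixed order
      for (int i = 0; i < n; ++i)
        if (alpha[i] > eps && alpha[i] < C[i] - eps && takeStep(i, i2))
          return true;
      // heuristic 3: everything, fixed order
      for (int i = 0; i < n; ++i)
        if (takeStep(i, i2)) return true;
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, NumericVector C,
               double tol = 1e-3, int max_passes = 2000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n || C.size() != n)
    stop("inconsistent SMO inputs");
  for (int i = 0; i < n; ++i)
    if (y[i] != 1.0 && y[i] != -1.0) stop("labels must be +/-1");
  SMO smo(K, y, C, tol);
  int numChanged = 0;
  bool examineAll = true;
  int passes = 0;
  while ((numChanged > 0 || examineAll) && passes < max_passes) {
    numChanged = 0;
    if (examineAll) {
      for (int i = 0; i < n; ++i) numChanged += smo.examine(i);
    } else {
      for (int i = 0; i < n; ++i)
        if (smo.alpha[i] > smo.eps && smo.alpha[i] < C[i] - smo.eps)
          numChanged += smo.examine(i);
    }
    if (examineAll) examineAll = false;
    else if (numChanged == 0) examineAll = true;
    ++passes;
  }
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b,
                      _["passes"] = passes,
                      _["converged"] = passes < max_passes);
}
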