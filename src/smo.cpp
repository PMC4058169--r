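#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual
//   max_a  sum_i a_i - 1/2 a' H a,   H_ij = y_i y_j K_ij
//   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0
// Platt-style solver: outer sweeps alternate between all examples and the
// non-bound subset, examining KKT violations at tolerance `tol`; the second
// index is chosen to maximize |E1 - E2| with randomized fallback scans
// (R's RNG, so runs are reproducible under set.seed).

class SMO {
public:
  SMO(const NumericMatrix& K, const NumericVector& y, double C, double tol,
      double eps, int max_sweeps)
    : K(K), y(y), C(C), tol(tol), eps(eps), max_sweeps(max_sweeps),
      n(y.size()), alpha(y.size(), 0.0), E(y.size()), b(0.0) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // f = 0 at alpha = 0
  }

  List solve() {
    int num_changed = 0;
    bool examine_all = true;
    int sweeps = 0;
    bool converged = true;
    while (num_changed > 0 || examine_all) {
      if (++sweeps > max_sweeps) { converged = false; break; }
      num_changed = 0;
      if (examine_all) {
        for (int i = 0; i < n; ++i) num_changed += examineExample(i);
      } else {
        for (int i = 0; i < n; ++i)
          if (alpha[i] > 0 && alpha[i] < C) num_changed += examineExample(i);
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
    }
    return List::create(_["alpha"] = alpha, _["b"] = b,
                        _["sweeps"] = sweeps, _["converged"] = converged);
  }

private:
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol, eps;
  int max_sweeps, n;
  std::vector<double> alpha, E;
  double b;

  int examineExample(int i2) {
    double y2 = y[i2], alph2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if (!((r2 < -tol && alph2 < C) || (r2 > tol && alph2 > 0))) return 0;

    // heuristic 1: maximize |E1 - E2| over non-bound points
    int i1 = -1; double best = -1.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] > 0 && alpha[i] < C) {
        double d = std::fabs(E[i] - E2);
        if (d > best) { best = d; i1 = i; }
      }
    }
    if (i1 >= 0 && takeStep(i1, i2)) return 1;

    // heuristic 2: scan non-bound points from a random start
    int start = (int)(unif_rand() * n);
    for (int k = 0; k < n; ++k) {
      int i = (start + k) % n;
      if (alpha[i] > 0 && alpha[i] < C && takeStep(i, i2)) return 1;
    }
    // heuristic 3: scan all points from a random start
    start = (int)(unif_rand() * n);
    for (int k = 0; k < n; ++k) {
      int i = (start + k) % n;
      if (takeStep(i, i2)) return 1;
    }
    return 0;
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    double alph1 = alpha[i1], alph2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = E[i1], E2 = E[i2];
    double s = y1 * y2;
    double L, H;
    if (s > 0) {
      double gamma = alph1 + alph2;
      L = std::max(0.0, gamma - C);
      H = std::min(C, gamma);
    } else {
      L = std::max(0.0, alph2 - alph1);
      H = std::min(C, C + alph2 - alph1);
    }
    if (L >= H) return false;

    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2;
    if (eta > 0) {
      a2 = alph2 + y2 * (E1 - E2) / eta;
      if (a2 < L) a2 = L; else if (a2 > H) a2 = H;
    } else {
      // non-PSD kernel: evaluate the restricted dual at both clip ends
      double v1 = E1 + y1 - b - y1 * alph1 * k11 - y2 * alph2 * k12;
      double v2 = E2 + y2 - b - y1 * alph1 * k12 - y2 * alph2 * k22;
      double gamma = alph1 + s * alph2;
      double Lobj = objAt(L, gamma, s, y1, y2, v1, v2, k11, k12, k22);
      double Hobj = objAt(H, gamma, s, y1, y2, v1, v2, k11, k12, k22);
      if (Lobj > Hobj + eps) a2 = L;
      else if (Lobj < Hobj - eps) a2 = H;
      else a2 = alph2;
    }
    if (std::fabs(a2 - alph2) < eps * (a2 + alph2 + eps)) return false;
    double a1 = alph1 + s * (alph2 - a2);
    if (a1 < 0) a1 = 0; else if (a1 > C) a1 = C;

    double d1 = y1 * (a1 - alph1), d2 = y2 * (a2 - alph2);
    double b1 = b - E1 - d1 * k11 - d2 * k12;
    double b2 = b - E2 - d1 * k12 - d2 * k22;
    double b_new;
    if (a1 > 0 && a1 < C) b_new = b1;
    else if (a2 > 0 && a2 < C) b_new = b2;
    else b_new = 0.5 * (b1 + b2);

    double db = b_new - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + db;
    alpha[i1] = a1;
    alpha[i2] = a2;
    b = b_new;
    return true;
  }

  // restricted dual objective as a function of a2 (with a1 = gamma - s*a2),
  // dropping terms constant in (a1, a2)
  double objAt(double a2, double gamma, double s, double y1, double y2,
               double v1, double v2, double k11, double k12, double k22) {
    double a1 = gamma - s * a2;
    return a1 + a2
      - 0.5 * k11 * a1 * a1 - 0.5 * k22 * a2 * a2 - s * k12 * a1 * a2
      - y1 * a1 * v1 - y2 * a2 * v2;
  }
};

// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C,
                   double tol, double eps, int max_sweeps) {
  SMO solver(K, y, C, tol, eps, max_sweeps);
  return solver.solve();
}
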