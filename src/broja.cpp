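#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-synergy partial information decomposition: minimize
// I_Q(T : S1, S2) over all joints Q(t, s1, s2) >= 0 that preserve the two
// pairwise marginals P(t, s1) and P(t, s2). Because P(t) is fixed, this is
// equivalent to maximizing H_Q(T | S1, S2), a concave objective over the
// product of per-t transportation polytopes.
//
// Solver: entropic mirror descent (multiplicative update with the exact
// gradient log(Q/Q+)) followed by an iterative-proportional-fitting (Sinkhorn)
// KL-projection of every t-slice back onto its row/column marginals. The
// iterates stay strictly positive; cells whose optimum is on the boundary
// decay geometrically.
//
// p: array dim (nt, n1, n2), passed as a flat vector in R's column-major
// order. Returns the optimal Q and the achieved mutual information in bits.
// [[Rcpp::export]]
List cpp_broja_minimize(NumericVector p, int nt, int n1, int n2,
                        double step, int max_iter, double tol) {
  const int n12 = n1 * n2;
  auto IDX = [&](int t, int a, int b) { return t + nt * (a + n1 * b); };

  // fixed pairwise marginals
  std::vector<double> m1(nt * n1, 0.0), m2(nt * n2, 0.0);
  for (int t = 0; t < nt; ++t)
    for (int a = 0; a < n1; ++a)
      for (int b = 0; b < n2; ++b) {
        double v = p[IDX(t, a, b)];
        m1[t + nt * a] += v;
        m2[t + nt * b] += v;
      }

  // start from the margin-consistent independent coupling within each slice:
  // Q(t,a,b) = P(t,a) P(t,b) / P(t)
  std::vector<double> pt(nt, 0.0);
  for (int t = 0; t < nt; ++t)
    for (int a = 0; a < n1; ++a) pt[t] += m1[t + nt * a];
  std::vector<double> Q(nt * n12, 0.0);
  for (int t = 0; t < nt; ++t)
    for (int a = 0; a < n1; ++a)
      for (int b = 0; b < n2; ++b)
        Q[IDX(t, a, b)] = pt[t] > 0
          ? m1[t + nt * a] * m2[t + nt * b] / pt[t] : 0.0;

  const double tiny = 1e-300;
  std::vector<double> qplus(n12), grad(nt * n12), row(n1), col(n2);

  auto objective = [&]() {
    // sum Q log(Q / Q+) in nats (equals -H(T | S1,S2) up to sign convention)
    std::fill(qplus.begin(), qplus.end(), 0.0);
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < n1; ++a)
        for (int b = 0; b < n2; ++b)
          qplus[a + n1 * b] += Q[IDX(t, a, b)];
    double f = 0.0;
    // cells below 1e-15 are boundary dust; including them risks 0/0 and
    // denormal-underflow artefacts in the reductions
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < n1; ++a)
        for (int b = 0; b < n2; ++b) {
          double q = Q[IDX(t, a, b)];
          if (q > 1e-15 && qplus[a + n1 * b] > 1e-15)
            f += q * std::log(q / qplus[a + n1 * b]);
        }
    return f;
  };

  double f_prev = objective();
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // gradient of sum Q log(Q/Q+) is log(Q/Q+)
    std::fill(qplus.begin(), qplus.end(), 0.0);
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < n1; ++a)
        for (int b = 0; b < n2; ++b)
          qplus[a + n1 * b] += Q[IDX(t, a, b)];
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < n1; ++a)
        for (int b = 0; b < n2; ++b) {
          int k = IDX(t, a, b);
          grad[k] = (Q[k] > tiny && qplus[a + n1 * b] > tiny)
            ? std::log(Q[k] / qplus[a + n1 * b]) : 0.0;
        }

    // multiplicative (entropic mirror) step
    for (int k = 0; k < nt * n12; ++k)
      if (Q[k] > 0) Q[k] *= std::exp(-step * grad[k]);

    // Sinkhorn projection of every t-slice back onto its marginals
    for (int t = 0; t < nt; ++t) {
      if (pt[t] <= 0) continue;
      for (int rep = 0; rep < 60; ++rep) {
        double err = 0.0;
        std::fill(row.begin(), row.end(), 0.0);
        for (int a = 0; a < n1; ++a)
          for (int b = 0; b < n2; ++b) row[a] += Q[IDX(t, a, b)];
        for (int a = 0; a < n1; ++a) {
          double target = m1[t + nt * a];
          if (row[a] > tiny) {
            double fac = target / row[a];
            err = std::max(err, std::fabs(fac - 1.0));
            for (int b = 0; b < n2; ++b) Q[IDX(t, a, b)] *= fac;
          } else if (target > 0) {
            // re-seed a vanished row from the column marginals
            for (int b = 0; b < n2; ++b)
              Q[IDX(t, a, b)] = target * m2[t + nt * b] / pt[t];
            err = 1.0;
          }
        }
        std::fill(col.begin(), col.end(), 0.0);
        for (int b = 0; b < n2; ++b)
          for (int a = 0; a < n1; ++a) col[b] += Q[IDX(t, a, b)];
        for (int b = 0; b < n2; ++b) {
          double target = m2[t + nt * b];
          if (col[b] > tiny) {
            double fac = target / col[b];
            err = std::max(err, std::fabs(fac - 1.0));
            for (int a = 0; a < n1; ++a) Q[IDX(t, a, b)] *= fac;
          }
        }
        if (err < 1e-12) break;
      }
    }

    if ((it + 1) % 25 == 0) {
      double f = objective();
      if (std::fabs(f_prev - f) < tol) { f_prev = f; break; }
      f_prev = f;
    }
  }

  // achieved I_Q(T : S1,S2) in bits: sum Q log(Q/(P(t) Q+))
  std::fill(qplus.begin(), qplus.end(), 0.0);
  for (int t = 0; t < nt; ++t)
    for (int a = 0; a < n1; ++a)
      for (int b = 0; b < n2; ++b)
        qplus[a + n1 * b] += Q[IDX(t, a, b)];
  double mi = 0.0;
  for (int t = 0; t < nt; ++t)
    for (int a = 0; a < n1; ++a)
      for (int b = 0; b < n2; ++b) {
        double q = Q[IDX(t, a, b)];
        if (q > 1e-15 && pt[t] > 1e-15 && qplus[a + n1 * b] > 1e-15)
          mi += q * std::log(q / (pt[t] * qplus[a + n1 * b]));
      }
  mi /= std::log(2.0);

  return List::create(_["Q"] = wrap(Q), _["mi_bits"] = mi,
                      _["iterations"] = it + 1);
}
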