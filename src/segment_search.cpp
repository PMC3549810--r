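// Exhaustive knot-pair search for the continuous quadratic-linear-quadratic
// least-squares fit to a sorted log-score curve.
//
// The model on the rank axis u_i = i/L (scaled to (0,1] for conditioning) is
//   f(u) = b0 + b1*u + b3*(t1-u)_+ + b4*(t1-u)_+^2 + b5*(u-t2)_+ + b6*(u-t2)_+^2
// with knots t1 = k1/L, t2 = k2/L at data ranks.  The hinge basis makes the
// fit continuous at both knots; no derivative constraint.  For every
// admissible pair (k1, k2) — partition segments 1..k1, k1+1..k2, k2+1..L each
// of at least min_seg points — the normal equations are assembled in O(1)
// from prefix moment sums, giving an O(L^2) scan; the winning pair is refit
// by QR for accurate coefficients and SSE.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool solve_pair(const vec& P0, const vec& P1, const vec& P2,
                       const vec& P3, const vec& P4,
                       const vec& Q0, const vec& Q1, const vec& Q2,
                       int L, int k1, int k2, vec& beta, double& bdotr) {
  const double t1 = (double)k1 / L, t2 = (double)k2 / L;
  // left moments over ranks 1..k1, right moments over k2+1..L
  const double l0 = P0[k1], l1 = P1[k1], l2 = P2[k1], l3 = P3[k1], l4 = P4[k1];
  const double r0 = P0[L] - P0[k2], r1 = P1[L] - P1[k2], r2 = P2[L] - P2[k2],
               r3 = P3[L] - P3[k2], r4 = P4[L] - P4[k2];
  mat A(6, 6, fill::zeros);
  vec rhs(6);
  A(0,0) = P0[L];            A(0,1) = P1[L];            A(1,1) = P2[L];
  A(0,2) = t1*l0 - l1;
  A(0,3) = t1*t1*l0 - 2*t1*l1 + l2;
  A(1,2) = t1*l1 - l2;
  A(1,3) = t1*t1*l1 - 2*t1*l2 + l3;
  A(2,2) = A(0,3);
  A(2,3) = t1*t1*t1*l0 - 3*t1*t1*l1 + 3*t1*l2 - l3;
  A(3,3) = t1*t1*t1*t1*l0 - 4*t1*t1*t1*l1 + 6*t1*t1*l2 - 4*t1*l3 + l4;
  A(0,4) = r1 - t2*r0;
  A(0,5) = r2 - 2*t2*r1 + t2*t2*r0;
  A(1,4) = r2 - t2*r1;
  A(1,5) = r3 - 2*t2*r2 + t2*t2*r1;
  A(4,4) = A(0,5);
  A(4,5) = r3 - 3*t2*r2 + 3*t2*t2*r1 - t2*t2*t2*r0;
  A(5,5) = r4 - 4*t2*r3 + 6*t2*t2*r2 - 4*t2*t2*t2*r1 + t2*t2*t2*t2*r0;
  // hinge bases have disjoint support: A(2..3, 4..5) = 0
  A = symmatu(A);
  rhs[0] = Q0[L];
  rhs[1] = Q1[L];
  rhs[2] = t1*Q0[k1] - Q1[k1];
  rhs[3] = t1*t1*Q0[k1] - 2*t1*Q1[k1] + Q2[k1];
  rhs[4] = (Q1[L] - Q1[k2]) - t2*(Q0[L] - Q0[k2]);
  rhs[5] = (Q2[L] - Q2[k2]) - 2*t2*(Q1[L] - Q1[k2]) + t2*t2*(Q0[L] - Q0[k2]);
  bool ok = solve(beta, A, rhs, solve_opts::no_approx);
  if (ok) bdotr = dot(beta, rhs);
  return ok;
}

// [[Rcpp::export]]
Rcpp::List cpp_segment_search(Rcpp::NumericVector y_, int min_seg) {
  const int L = y_.size();
  if (L < 3 * min_seg) Rcpp::stop("curve too short for three segments");
  vec y(y_.begin(), L);
  vec u = regspace(1, L) / (double)L;

  // prefix sums with a leading 0 so P[k] = sum over ranks 1..k
  vec P0(L + 1, fill::zeros), P1(L + 1, fill::zeros), P2(L + 1, fill::zeros),
      P3(L + 1, fill::zeros), P4(L + 1, fill::zeros),
      Q0(L + 1, fill::zeros), Q1(L + 1, fill::zeros), Q2(L + 1, fill::zeros);
  double yty = 0;
  for (int i = 1; i <= L; ++i) {
    const double ui = u[i - 1], yi = y[i - 1];
    P0[i] = P0[i-1] + 1;        P1[i] = P1[i-1] + ui;
    P2[i] = P2[i-1] + ui*ui;    P3[i] = P3[i-1] + ui*ui*ui;
    P4[i] = P4[i-1] + ui*ui*ui*ui;
    Q0[i] = Q0[i-1] + yi;       Q1[i] = Q1[i-1] + yi*ui;
    Q2[i] = Q2[i-1] + yi*ui*ui;
    yty += yi * yi;
  }

  int best_k1 = -1, best_k2 = -1;
  double best_sse = datum::inf;
  vec beta(6);
  for (int k1 = min_seg; k1 <= L - 2 * min_seg; ++k1) {
    for (int k2 = k1 + min_seg; k2 <= L - min_seg; ++k2) {
      double bdotr;
      if (!solve_pair(P0, P1, P2, P3, P4, Q0, Q1, Q2, L, k1, k2, beta, bdotr))
        continue;
      const double sse = yty - bdotr;   // y'y - b'X'y at the LS solution
      if (sse < best_sse - 1e-12) {     // strict improvement; ties keep first
        best_sse = sse;
        best_k1 = k1;
        best_k2 = k2;
      }
    }
  }
  if (best_k1 < 0) Rcpp::stop("no admissible knot pair could be fit");

  // QR refit of the winner for accurate coefficients and SSE
  const double t1 = (double)best_k1 / L, t2 = (double)best_k2 / L;
  mat X(L, 6);
  for (int i = 0; i < L; ++i) {
    const double ui = u[i];
    const double h1 = std::max(t1 - ui, 0.0), h2 = std::max(ui - t2, 0.0);
    X(i,0) = 1; X(i,1) = ui; X(i,2) = h1; X(i,3) = h1*h1;
    X(i,4) = h2; X(i,5) = h2*h2;
  }
  vec bfit = solve(X, y);
  vec resid = y - X * bfit;
  return Rcpp::List::create(
    Rcpp::Named("k1") = best_k1,
    Rcpp::Named("k2") = best_k2,
    Rcpp::Named("beta") = Rcpp::NumericVector(bfit.begin(), bfit.end()),
    Rcpp::Named("sse") = dot(resid, resid));
}
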