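// Sequential selective-scan (S6) recurrence.
//
// Per channel d with hidden state h[d,] of size N:
//   abar_t = exp(delta[t,d] * A[d,])          (A <= 0 so abar in (0,1])
//   h      = abar_t * h + delta[t,d] * B[t,] * x[t,d]
//   y[t,d] = dot(C[t,], h[d,]) + Dskip[d] * x[t,d]
//
// The backward pass replays the recurrence in reverse using the hidden
// states and discretized transitions stored by the forward pass. Plain
// loops: L*D*N stays small and the sequential dependence rules out
// vectorising over t anyway.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List sscan_fwd(NumericMatrix x, NumericMatrix delta, NumericMatrix B,
               NumericMatrix Cc, NumericMatrix A, NumericVector Dskip) {
  const int L = x.nrow(), D = x.ncol(), N = A.ncol();
  NumericMatrix y(L, D);
  NumericVector Hs(static_cast<R_xlen_t>(L) * D * N);
  NumericVector Ab(static_cast<R_xlen_t>(L) * D * N);
  std::vector<double> h(static_cast<size_t>(D) * N, 0.0);
  double* hs = REAL(Hs);
  double* ab = REAL(Ab);
  for (int t = 0; t < L; ++t) {
    for (int d = 0; d < D; ++d) {
      const double dt = delta(t, d), xv = x(t, d);
      double acc = 0.0;
      double* hd = &h[static_cast<size_t>(d) * N];
      double* hst = hs + (static_cast<R_xlen_t>(t) * D + d) * N;
      double* abt = ab + (static_cast<R_xlen_t>(t) * D + d) * N;
      for (int n = 0; n < N; ++n) {
        const double abar = std::exp(dt * A(d, n));
        hd[n] = abar * hd[n] + dt * B(t, n) * xv;
        acc += Cc(t, n) * hd[n];
        hst[n] = hd[n];
        abt[n] = abar;
      }
      y(t, d) = acc + Dskip[d] * xv;
    }
  }
  return List::create(_["y"] = y, _["H"] = Hs, _["Ab"] = Ab);
}

// [[Rcpp::export]]
List sscan_bwd(NumericMatrix dy, NumericMatrix x, NumericMatrix delta,
               NumericMatrix B, NumericMatrix Cc, NumericMatrix A,
               NumericVector Dskip, NumericVector Hs, NumericVector Ab) {
  const int L = x.nrow(), D = x.ncol(), N = A.ncol();
  NumericMatrix dx(L, D), ddelta(L, D), dB(L, N), dC(L, N), dA(D, N);
  NumericVector dDskip(D);
  std::vector<double> dh(static_cast<size_t>(D) * N, 0.0);
  const double* hs = REAL(Hs);
  const double* ab = REAL(Ab);
  for (int t = L - 1; t >= 0; --t) {
    for (int d = 0; d < D; ++d) {
      const double dt = delta(t, d), xv = x(t, d), dyv = dy(t, d);
      double* dhd = &dh[static_cast<size_t>(d) * N];
      const double* hst = hs + (static_cast<R_xlen_t>(t) * D + d) * N;
      const double* abt = ab + (static_cast<R_xlen_t>(t) * D + d) * N;
      const double* hpr =
          (t > 0) ? hs + (static_cast<R_xlen_t>(t - 1) * D + d) * N : nullptr;
      double ddel = 0.0, dxv = Dskip[d] * dyv;
      dDskip[d] += dyv * xv;
      for (int n = 0; n < N; ++n) {
        dC(t, n) += dyv * hst[n];
        double g = dhd[n] + dyv * Cc(t, n); // total dL/dh_t
        const double hprev = hpr ? hpr[n] : 0.0;
        const double abar = abt[n];
        ddel += g * (abar * A(d, n) * hprev + B(t, n) * xv);
        dA(d, n) += g * abar * dt * hprev;
        dB(t, n) += g * dt * xv;
        dxv += g * dt * B(t, n);
        dhd[n] = g * abar; // becomes dL/dh_{t-1}
      }
      ddelta(t, d) = ddel;
      dx(t, d) = dxv;
    }
  }
  return List::create(_["dx"] = dx, _["ddelta"] = ddelta, _["dB"] = dB,
                      _["dC"] = dC, _["dA"] = dA, _["dDskip"] = dDskip);
}
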