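#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Right-hand side of the truncated coagulation-fragmentation system.
//
// Species: C (unsilicified cells), S (precursor), A[1..N] (j-mers).
// Silicification:  C + S <-> A1           (kp1 / kn1)
// Coagulation:     Ai + Aj <-> A(i+j)     (kp(i,j) / kn(i,j)), i + j <= N
//
// Conventions that make cell mass C + sum(j * A_j) exactly conserved:
//  - formation of A_j sums unordered pairs (i, j-i), i = 1..floor(j/2);
//  - the self channel A_j + A_j contributes a factor 2 to the loss of A_j,
//    one factor from the pair-loss sum (partner m = j) and one from the
//    phi-gated term, active only when 2j <= N;
//  - fragmentation of A_k into (i, k-i) proceeds at kn(i, k-i) * A_k per
//    unordered channel.
//
// kp, kn are N x N symmetric tables (1-based sizes at 0-based indices),
// stored column-major.

static void rhs_core(int N, double C, double S, const double *A,
                     double kp1, double kn1,
                     const double *kp, const double *kn,
                     bool s_dynamic, double *out) {
#define KP(i, j) kp[(i) - 1 + ((j) - 1) * N]
#define KN(i, j) kn[(i) - 1 + ((j) - 1) * N]
  const double silic = kp1 * C * S - kn1 * A[0];
  out[0] = -silic;
  out[1] = s_dynamic ? -silic : 0.0;

  // dA1: silicification, dimerization (explicit factor 2), and pairing
  // with every larger species that still fits under the truncation.
  double dA1 = silic;
  if (N >= 2) {
    dA1 += -2.0 * KP(1, 1) * A[0] * A[0] + 2.0 * KN(1, 1) * A[1];
    for (int j = 3; j <= N; ++j) { // partner size j-1 = 2..N-1
      dA1 += -KP(j - 1, 1) * A[j - 2] * A[0] + KN(j - 1, 1) * A[j - 1];
    }
  }
  out[2] = dA1;

  for (int j = 2; j <= N - 1; ++j) {
    double d = 0.0;
    const double Aj = A[j - 1];
    for (int i = 1; i <= j / 2; ++i) { // floor(j/2): unordered pairs once
      d += KP(i, j - i) * A[i - 1] * A[j - i - 1] - KN(i, j - i) * Aj;
    }
    for (int m = 1; m <= N - j; ++m) {
      d += -KP(m, j) * A[m - 1] * Aj + KN(m, j) * A[m + j - 1];
    }
    if (2 * j <= N) { // phi(j) = 1
      d += -KP(j, j) * Aj * Aj + KN(j, j) * A[2 * j - 1];
    }
    out[j + 1] = d;
  }

  if (N >= 2) {
    double dN = 0.0;
    for (int i = 1; i <= N / 2; ++i) {
      dN += KP(i, N - i) * A[i - 1] * A[N - i - 1] - KN(i, N - i) * A[N - 1];
    }
    out[N + 1] = dN;
  }
#undef KP
#undef KN
}

// [[Rcpp::export]]
NumericVector rhs_cpp(double C, double S, NumericVector A,
                      double kp1, double kn1,
                      NumericMatrix kp, NumericMatrix kn,
                      bool s_dynamic) {
  const int N = A.size();
  if (kp.nrow() != N || kp.ncol() != N || kn.nrow() != N || kn.ncol() != N)
    stop("rate tables must be N x N");
  NumericVector out(N + 2);
  rhs_core(N, C, S, A.begin(), kp1, kn1, kp.begin(), kn.begin(),
           s_dynamic, out.begin());
  return out;
}

// ---- deSolve compiled-model interface -------------------------------------
// Parameters are staged from R with rhs_set_params() immediately before the
// solver call; rhs_deriv() is then passed to deSolve by symbol name so no R
// closure is evaluated per step.

static int g_N = 0;
static double g_kp1 = 0, g_kn1 = 0;
static bool g_dyn = false;
static std::vector<double> g_kp, g_kn;

// [[Rcpp::export]]
void rhs_set_params(double kp1, double kn1, NumericMatrix kp,
                    NumericMatrix kn, bool s_dynamic) {
  if (kp.nrow() != kp.ncol() || kn.nrow() != kp.nrow() ||
      kn.ncol() != kp.nrow())
    stop("rate tables must be square and of equal size");
  g_N = kp.nrow();
  g_kp1 = kp1;
  g_kn1 = kn1;
  g_dyn = s_dynamic;
  g_kp.assign(kp.begin(), kp.end());
  g_kn.assign(kn.begin(), kn.end());
}

extern "C" void rhs_deriv(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip) {
  (void) t; (void) yout; (void) ip;
  if (*neq != g_N + 2) Rf_error("rhs_deriv: state length mismatch");
  rhs_core(g_N, y[0], y[1], y + 2, g_kp1, g_kn1,
           g_kp.data(), g_kn.data(), g_dyn, ydot);
}

// deSolve resolves "rhs_deriv" by dynamic symbol lookup, which the generated
// registration turns off; turn it back on at load time.
// [[Rcpp::init]]
void silicoag_enable_symbol_lookup(DllInfo *dll) {
  R_useDynamicSymbols(dll, TRUE);
}
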