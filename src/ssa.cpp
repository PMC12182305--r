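#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) stochastic simulation of the silicification /
// coagulation-fragmentation network at integer copy number.
//
// Propensities are chosen so the large-volume mean matches the deterministic
// right-hand side in rhs.cpp:
//   C + S -> A1          a = (kp1/Omega) nC nS   (or kp1 * S0 * nC, constant S)
//   A1 -> C + S          a = kn1 * nA1
//   Ai + Aj -> A(i+j)    a = (kp(i,j)/Omega) ni nj            (i < j)
//   Aj + Aj -> A(2j)     a = (kp(j,j)/Omega) nj (nj - 1)      (mean loss 2 kp Aj^2)
//   A(i+j) -> Ai + Aj    a = kn(i,j) n(i+j)  per unordered channel (i <= j)
//
// Uses R's RNG stream, so results are reproducible under set.seed().
// Returns a (length(times) x (N + 2)) matrix of counts (C, S, A1..AN)
// sampled on the requested grid.

// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerVector init_counts, // C, S, A1..AN
                          NumericVector times,
                          double kp1, double kn1,
                          NumericMatrix kp, NumericMatrix kn,
                          double omega, bool s_dynamic, double S0) {
  const int N = init_counts.size() - 2;
  const int nt = times.size();
  IntegerMatrix out(nt, N + 2);

  long nC = init_counts[0];
  long nS = init_counts[1];
  std::vector<long> nA(N);
  for (int j = 0; j < N; ++j) nA[j] = init_counts[j + 2];

  // enumerate coagulation/fragmentation channels (i <= j, i + j <= N)
  std::vector<int> ci, cj;
  for (int i = 1; i <= N; ++i)
    for (int j = i; i + j <= N; ++j) { ci.push_back(i); cj.push_back(j); }
  const int npairs = (int) ci.size();
  std::vector<double> a(2 + 2 * npairs);

  RNGScope scope;
  double t = 0.0;
  int k = 0;
  while (k < nt && times[k] <= t) {
    out(k, 0) = (int) nC; out(k, 1) = (int) nS;
    for (int j = 0; j < N; ++j) out(k, j + 2) = (int) nA[j];
    ++k;
  }

  while (k < nt) {
    a[0] = s_dynamic ? (kp1 / omega) * nC * nS : kp1 * S0 * nC;
    a[1] = kn1 * nA[0];
    double a0 = a[0] + a[1];
    for (int c = 0; c < npairs; ++c) {
      const int i = ci[c], j = cj[c];
      double ac;
      if (i == j) ac = (kp(i - 1, j - 1) / omega) * nA[i - 1] * (nA[i - 1] - 1);
      else        ac = (kp(i - 1, j - 1) / omega) * nA[i - 1] * nA[j - 1];
      if (ac < 0) ac = 0;
      a[2 + c] = ac;
      double af = kn(i - 1, j - 1) * nA[i + j - 1];
      a[2 + npairs + c] = af;
      a0 += ac + af;
    }

    if (a0 <= 0) break; // absorbed: remaining grid points hold current state

    t += exp_rand() / a0;
    while (k < nt && times[k] <= t) {
      out(k, 0) = (int) nC; out(k, 1) = (int) nS;
      for (int j = 0; j < N; ++j) out(k, j + 2) = (int) nA[j];
      ++k;
    }
    if (k >= nt) break;

    double u = unif_rand() * a0;
    int ch = -1;
    double acc = 0.0;
    for (size_t c = 0; c < a.size(); ++c) {
      acc += a[c];
      if (u <= acc) { ch = (int) c; break; }
    }
    if (ch < 0) ch = (int) a.size() - 1; // guard against roundoff

    if (ch == 0) {                       // silicification
      --nC; ++nA[0]; if (s_dynamic) --nS;
    } else if (ch == 1) {                // reverse silicification
      --nA[0]; ++nC; if (s_dynamic) ++nS;
    } else if (ch < 2 + npairs) {        // coagulation
      const int c = ch - 2, i = ci[c], j = cj[c];
      nA[i - 1] -= 1; nA[j - 1] -= 1; nA[i + j - 1] += 1;
      if (i + j > N) stop("coagulation channel exceeded truncation");
    } else {                             // fragmentation
      const int c = ch - 2 - npairs, i = ci[c], j = cj[c];
      nA[i + j - 1] -= 1; nA[i - 1] += 1; nA[j - 1] += 1;
    }
  }

  // fill any remaining grid points (absorbing state)
  while (k < nt) {
    out(k, 0) = (int) nC; out(k, 1) = (int) nS;
    for (int j = 0; j < N; ++j) out(k, j + 2) = (int) nA[j];
    ++k;
  }
  return out;
}
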