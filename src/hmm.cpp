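#include <Rcpp.h>
using namespace Rcpp;

// Single-hit local profile-HMM scoring (Viterbi / forward), plan7-like but
// without the multi-hit J state.  Architecture:
//   S -> N (self-loop, background emission) -> B -> M_k (uniform-ish entry)
//   M_k -> {M_{k+1}, I_k, D_{k+1}, E};  I_k -> {M_{k+1}, I_k};
//   D_k -> {M_{k+1}, D_{k+1}};  D_L -> E (log prob tDLE);
//   E -> C (prob 1); C self-loops with background emission; C -> T.
// All transition vectors are length L in log space with impossible moves at
// -Inf (e.g. tMI[L], tMM[L], tMD[L]); entries are indexed by source node.
// Returns the raw natural-log probability log P(seq, best-path | model)
// (Viterbi) or log P(seq | model) (forward).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".hmm_score_dp")]]
double hmm_score_dp(IntegerVector x, NumericMatrix lme, NumericVector lie,
                    NumericVector tMM, NumericVector tMI, NumericVector tMD,
                    NumericVector tME, NumericVector tIM, NumericVector tII,
                    NumericVector tDM, NumericVector tDD, NumericVector tBM,
                    double tNN, double tNB, double tCC, double tCT,
                    double tDLE, bool forward) {
  const int n = x.size(), L = lme.nrow();
  std::vector<double> M(L + 1, NEG_INF), I(L + 1, NEG_INF), D(L + 1, NEG_INF);
  std::vector<double> Mp(L + 1), Ip(L + 1), Dp(L + 1);

  double N = 0.0;                 // log prob of being in N, 0 residues emitted
  double B = N + tNB;
  double C = NEG_INF;

  // i = 0: no residues emitted; D states unreachable (no B->D entry)
  double result0 = NEG_INF;       // empty sequences are excluded upstream

  for (int i = 1; i <= n; ++i) {
    const int xi = x[i - 1] - 1;  // 0..20 (20 = X)
    Mp = M; Ip = I; Dp = D;
    double Bp = B;

    N = N + tNN + lie[xi];
    B = N + tNB;

    double E = NEG_INF;
    for (int k = 1; k <= L; ++k) {
      double m = Bp + tBM[k - 1];
      if (k > 1) {
        double fromM = Mp[k - 1] + tMM[k - 2];
        double fromI = Ip[k - 1] + tIM[k - 2];
        double fromD = Dp[k - 1] + tDM[k - 2];
        if (forward) { m = lse2(m, fromM); m = lse2(m, fromI); m = lse2(m, fromD); }
        else { m = std::max(m, std::max(fromM, std::max(fromI, fromD))); }
      }
      M[k] = m + lme(k - 1, xi);

      double iv = NEG_INF;
      {
        double fromM = Mp[k] + tMI[k - 1];
        double fromI = Ip[k] + tII[k - 1];
        iv = forward ? lse2(fromM, fromI) : std::max(fromM, fromI);
      }
      I[k] = (iv == NEG_INF) ? NEG_INF : iv + lie[xi];

      if (k > 1) {
        double fromM = M[k - 1] + tMD[k - 2];
        double fromD = D[k - 1] + tDD[k - 2];
        D[k] = forward ? lse2(fromM, fromD) : std::max(fromM, fromD);
      } else {
        D[k] = NEG_INF;
      }

      double toE = M[k] + tME[k - 1];
      E = forward ? lse2(E, toE) : std::max(E, toE);
    }
    double toE = D[L] + tDLE;
    E = forward ? lse2(E, toE) : std::max(E, toE);

    double stay = (C == NEG_INF) ? NEG_INF : C + tCC + lie[xi];
    C = forward ? lse2(E, stay) : std::max(E, stay);
  }

  if (n == 0) return result0;
  return C + tCT;
}
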