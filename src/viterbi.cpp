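#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Glocal profile alignment: global over the profile (all L match states
// must be visited or deleted), local over the sequence (free start/end).
// Scores are log-odds bits; insert states emit at background (0 bits).
// seq is 0-based encoded (A=0..T=3, other=4; code 4 emits 0 bits).
// emis is an L x 4 matrix of match-state emission log-odds.
// Returns the best score and the 0-based half-open window [start, end)
// of the placement on the sequence.
// [[Rcpp::export]]
List cpp_viterbi_glocal(IntegerVector seq, NumericMatrix emis,
                        double ins_open, double ins_ext,
                        double del_open, double del_ext) {
  const int n = seq.size();
  const int L = emis.nrow();
  const double NEG = -1e30;
  if (n == 0 || L == 0)
    return List::create(_["score"] = NEG, _["start"] = 0, _["end"] = 0);

  // rolling rows over profile position j; index i = 1..n sequence chars
  std::vector<double> VMp(n + 1, NEG), VIp(n + 1, NEG), VDp(n + 1, NEG);
  std::vector<double> VM(n + 1), VI(n + 1), VD(n + 1);
  std::vector<int> SMp(n + 1, 0), SIp(n + 1, 0), SDp(n + 1, 0);
  std::vector<int> SM(n + 1), SI(n + 1), SD(n + 1);

  double best = NEG; int best_start = 0, best_end = 0;

  for (int j = 1; j <= L; ++j) {
    VM[0] = NEG; VI[0] = NEG; VD[0] = NEG;
    SM[0] = SI[0] = SD[0] = 0;
    for (int i = 1; i <= n; ++i) {
      const int c = seq[i - 1];
      const double e = (c < 4) ? emis(j - 1, c) : 0.0;
      if (j == 1) {
        VM[i] = e;                 // free start before seq position i
        SM[i] = i;
        VD[i] = del_open;          // profile starts with a deleted match
        SD[i] = i + 1;
      } else {
        double v = VMp[i - 1]; int s = SMp[i - 1];
        if (VIp[i - 1] > v) { v = VIp[i - 1]; s = SIp[i - 1]; }
        if (VDp[i - 1] > v) { v = VDp[i - 1]; s = SDp[i - 1]; }
        VM[i] = (v <= NEG / 2) ? NEG : v + e;
        SM[i] = s;
        double d0 = (VMp[i] <= NEG / 2) ? NEG : VMp[i] + del_open;
        double d1 = (VDp[i] <= NEG / 2) ? NEG : VDp[i] + del_ext;
        if (d0 >= d1) { VD[i] = d0; SD[i] = SMp[i]; }
        else          { VD[i] = d1; SD[i] = SDp[i]; }
      }
      double i0 = (VM[i - 1] <= NEG / 2) ? NEG : VM[i - 1] + ins_open;
      double i1 = (VI[i - 1] <= NEG / 2) ? NEG : VI[i - 1] + ins_ext;
      if (i0 >= i1) { VI[i] = i0; SI[i] = SM[i - 1]; }
      else          { VI[i] = i1; SI[i] = SI[i - 1]; }
      if (j == L) {
        if (VM[i] > best) { best = VM[i]; best_start = SM[i]; best_end = i; }
        if (VD[i] > best) { best = VD[i]; best_start = SD[i]; best_end = i; }
      }
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
    std::swap(SM, SMp); std::swap(SI, SIp); std::swap(SD, SDp);
  }

  // convert to 0-based half-open: first consumed char is best_start (1-based)
  return List::create(_["score"] = best,
                      _["start"] = best_start - 1,
                      _["end"] = best_end);
}
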