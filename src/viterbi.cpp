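#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman style) Viterbi alignment of a protein sequence to a
// profile of match emission log-odds (bits).  Insertions emit from the
// background (log-odds 0); gap penalties are position-specific and derived
// in R from the profile's transition probabilities, normalized so that the
// pure match-match path carries no transition cost.  The returned bit score
// is the best-scoring local path (>= 0).
//
// lodds: model_length x 20 match emission log-odds
// seq:   0-based residue indices, -1 for unknown residues (scored 0)
// [[Rcpp::export(name = ".viterbi_local_cpp")]]
double viterbi_local_cpp(NumericMatrix lodds,
                         NumericVector ins_open, NumericVector ins_ext,
                         NumericVector del_open, NumericVector del_ext,
                         IntegerVector seq) {
  const int M = lodds.nrow(), L = seq.size();
  const double NEG = -1e30;
  std::vector<double> Mp(M + 1, NEG), Ip(M + 1, NEG), Dp(M + 1, NEG);
  std::vector<double> Mc(M + 1, NEG), Ic(M + 1, NEG), Dc(M + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= L; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    int a = seq[i - 1];
    for (int j = 1; j <= M; ++j) {
      double e = (a >= 0) ? lodds(j - 1, a) : 0.0;
      double diag = 0.0;                       // free local start
      if (Mp[j - 1] > diag) diag = Mp[j - 1];
      if (Ip[j - 1] > diag) diag = Ip[j - 1];
      if (Dp[j - 1] > diag) diag = Dp[j - 1];
      Mc[j] = e + diag;
      if (Mc[j] > best) best = Mc[j];
      // insert: emits residue i between model positions j and j+1
      Ic[j] = std::max(Mp[j] - ins_open[j - 1], Ip[j] - ins_ext[j - 1]);
      // delete: skips model position j without emitting (same row)
      Dc[j] = std::max(Mc[j - 1] - del_open[j - 1], Dc[j - 1] - del_ext[j - 1]);
    }
    Mp.swap(Mc);
    Ip.swap(Ic);
    Dp.swap(Dc);
  }
  return best;
}

// Batch scorer: many pre-encoded sequences against one profile.
// [[Rcpp::export(name = ".viterbi_batch_cpp")]]
NumericVector viterbi_batch_cpp(NumericMatrix lodds,
                                NumericVector ins_open, NumericVector ins_ext,
                                NumericVector del_open, NumericVector del_ext,
                                List seqs) {
  NumericVector out(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) {
    IntegerVector s = seqs[k];
    out[k] = viterbi_local_cpp(lodds, ins_open, ins_ext, del_open, del_ext, s);
  }
  return out;
}
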