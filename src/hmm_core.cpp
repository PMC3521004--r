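#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM dynamic programming in bits (log2).
//
// Local ("free flanking") semantics: a scoring path enters the model at any
// match state (uniform entry probability 1/K), traverses match/insert/delete
// states under the core transition probabilities, and leaves from any match
// state (uniform exit 1/K).  Residues outside the aligned interval are free:
// they contribute 0 bits.  Insert states emit the background distribution, so
// their emission log-odds are 0; delete states are silent.  Paths start and
// end on a match state.
//
// Inputs are log2-scaled: lmE is K x 26 match emission log-odds indexed by
// (state, residue code); lt* are core transition log2 probabilities with
// lt**[k] the transition out of state k (k = 1..K-1 used).  seq is a 0-based
// integer code vector.

static const double NEG = -1e300;

static inline double lse2(double a, double b) {
  if (a == NEG || a == R_NegInf) return b;
  if (b == NEG || b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(NumericMatrix lmE,
                     NumericVector ltMM, NumericVector ltMI, NumericVector ltMD,
                     NumericVector ltIM, NumericVector ltII,
                     NumericVector ltDM, NumericVector ltDD,
                     IntegerVector seq) {
  const int K = lmE.nrow(), L = seq.size();
  const double lent = -std::log2((double)K);
  NumericMatrix VM(L + 1, K + 1), VI(L + 1, K + 1), VD(L + 1, K + 1);
  // backpointers: 0 entry, 1 from M, 2 from I, 3 from D
  IntegerMatrix bM(L + 1, K + 1), bI(L + 1, K + 1), bD(L + 1, K + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  double best = NEG; int bi = -1, bk = -1;
  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    for (int k = 1; k <= K; ++k) {
      double e = lmE(k - 1, a);
      // M: tie-break preference M > I > D, entry last (so internal paths win ties
      // consistently); strict > keeps the first listed option.
      double v = lent; int who = 0;             // fresh local entry
      if (k > 1) {
        double fM = VM(i - 1, k - 1) + ltMM[k - 2];
        double fI = VI(i - 1, k - 1) + ltIM[k - 2];
        double fD = VD(i - 1, k - 1) + ltDM[k - 2];
        if (fM > v) { v = fM; who = 1; }
        if (fI > v) { v = fI; who = 2; }
        if (fD > v) { v = fD; who = 3; }
      }
      VM(i, k) = v + e; bM(i, k) = who;
      // I_k exists for k < K
      if (k < K) {
        double fM = VM(i - 1, k) + ltMI[k - 1];
        double fI = VI(i - 1, k) + ltII[k - 1];
        if (fM >= fI) { VI(i, k) = fM; bI(i, k) = 1; }
        else          { VI(i, k) = fI; bI(i, k) = 2; }
      }
      // D_k exists for k >= 2 (entered from M_{k-1} or D_{k-1})
      if (k > 1) {
        double fM = VM(i, k - 1) + ltMD[k - 2];
        double fD = VD(i, k - 1) + ltDD[k - 2];
        if (fM >= fD) { VD(i, k) = fM; bD(i, k) = 1; }
        else          { VD(i, k) = fD; bD(i, k) = 3; }
      }
      double tot = VM(i, k) + lent;             // uniform exit
      if (tot > best) { best = tot; bi = i; bk = k; }
    }
  }
  // traceback from (bi, bk) in state M
  int i = bi, k = bk, st = 1; // 1=M, 2=I, 3=D
  int startRes = bi, mstart = bk;
  std::vector<int> states, residues, cols;
  while (true) {
    states.push_back(st); residues.push_back(i); cols.push_back(k);
    if (st == 1) {
      int who = bM(i, k);
      startRes = i; mstart = k;
      if (who == 0) break;
      --i; --k; st = who;
    } else if (st == 2) {
      int who = bI(i, k);
      --i; st = who;
    } else {
      int who = bD(i, k);
      --k; st = who;
    }
  }
  std::reverse(states.begin(), states.end());
  return List::create(
    _["score"] = best,
    _["start"] = startRes - 1,   // 0-based inclusive
    _["end"] = bi,               // 0-based half-open
    _["model_start"] = mstart,
    _["model_end"] = bk,
    _["states"] = wrap(states));
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix lmE,
                       NumericVector ltMM, NumericVector ltMI, NumericVector ltMD,
                       NumericVector ltIM, NumericVector ltII,
                       NumericVector ltDM, NumericVector ltDD,
                       IntegerVector seq) {
  const int K = lmE.nrow(), L = seq.size();
  const double lent = -std::log2((double)K);
  NumericMatrix FM(L + 1, K + 1), FI(L + 1, K + 1), FD(L + 1, K + 1);
  std::fill(FM.begin(), FM.end(), NEG);
  std::fill(FI.begin(), FI.end(), NEG);
  std::fill(FD.begin(), FD.end(), NEG);
  double tot = NEG;
  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    for (int k = 1; k <= K; ++k) {
      double e = lmE(k - 1, a);
      double v = lent; // entry
      if (k > 1) {
        v = lse2(v, FM(i - 1, k - 1) + ltMM[k - 2]);
        v = lse2(v, FI(i - 1, k - 1) + ltIM[k - 2]);
        v = lse2(v, FD(i - 1, k - 1) + ltDM[k - 2]);
      }
      FM(i, k) = v + e;
      if (k < K)
        FI(i, k) = lse2(FM(i - 1, k) + ltMI[k - 1], FI(i - 1, k) + ltII[k - 1]);
      if (k > 1)
        FD(i, k) = lse2(FM(i, k - 1) + ltMD[k - 2], FD(i, k - 1) + ltDD[k - 2]);
      tot = lse2(tot, FM(i, k) + lent);
    }
  }
  return tot;
}

// Score-only batch Viterbi: rolling rows, no traceback.  Used by search and
// decoy calibration where only the bit score is needed.

// [[Rcpp::export(name = ".hmm_score_batch_cpp")]]
NumericVector hmm_score_batch_cpp(NumericMatrix lmE,
                                  NumericVector ltMM, NumericVector ltMI,
                                  NumericVector ltMD, NumericVector ltIM,
                                  NumericVector ltII, NumericVector ltDM,
                                  NumericVector ltDD, List seqs) {
  const int K = lmE.nrow();
  const double lent = -std::log2((double)K);
  const int nseq = seqs.size();
  NumericVector out(nseq);
  std::vector<double> pM(K + 1), pI(K + 1), pD(K + 1),
                      cM(K + 1), cI(K + 1), cD(K + 1);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector seq = seqs[s];
    const int L = seq.size();
    std::fill(pM.begin(), pM.end(), NEG);
    std::fill(pI.begin(), pI.end(), NEG);
    std::fill(pD.begin(), pD.end(), NEG);
    double best = NEG;
    for (int i = 1; i <= L; ++i) {
      int a = seq[i - 1];
      cM[0] = cI[0] = cD[0] = NEG;
      for (int k = 1; k <= K; ++k) {
        double v = lent;
        if (k > 1) {
          double fM = pM[k - 1] + ltMM[k - 2];
          double fI = pI[k - 1] + ltIM[k - 2];
          double fD = pD[k - 1] + ltDM[k - 2];
          if (fM > v) v = fM;
          if (fI > v) v = fI;
          if (fD > v) v = fD;
        }
        cM[k] = v + lmE(k - 1, a);
        cI[k] = (k < K) ? std::max(pM[k] + ltMI[k - 1], pI[k] + ltII[k - 1])
                        : NEG;
        cD[k] = (k > 1) ? std::max(cM[k - 1] + ltMD[k - 2],
                                   cD[k - 1] + ltDD[k - 2])
                        : NEG;
        double tot = cM[k] + lent;
        if (tot > best) best = tot;
      }
      std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
    }
    out[s] = best;
  }
  return out;
}
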