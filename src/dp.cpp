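// Dynamic-programming kernels for pairwise profile-HMM alignment.
//
// Pair states: MM (match-match), MI (query match vs template insert),
// IM (query insert vs template match), DG (query delete vs gap),
// GD (gap vs template delete). MI/DG advance the query index i,
// IM/GD advance the template index j.
//
// Transition matrices come in as log2 probabilities, one row per profile
// column, columns ordered MM, MI, MD, IM, II, DM, DD. The match-score
// matrix S is the full augmented log2-odds score (amino-acid + structural
// terms + shift). Local mode allows a path to start and end at any cell;
// global mode pins the first matched pair to (1,1) and the last to
// (Lq, Lt).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum Tr { tMM = 0, tMI = 1, tMD = 2, tIM = 3, tII = 4, tDM = 5, tDD = 6 };

// log2(2^a + 2^b), safe for -Inf
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export(name = ".viterbi_dp")]]
List viterbi_dp(NumericMatrix S, NumericMatrix qtr, NumericMatrix ttr,
                bool local) {
  const int Lq = S.nrow(), Lt = S.ncol();
  NumericMatrix MM(Lq + 1, Lt + 1), MI(Lq + 1, Lt + 1), IM(Lq + 1, Lt + 1),
      DG(Lq + 1, Lt + 1), GD(Lq + 1, Lt + 1);
  IntegerMatrix bMM(Lq + 1, Lt + 1), bMI(Lq + 1, Lt + 1), bIM(Lq + 1, Lt + 1),
      bDG(Lq + 1, Lt + 1), bGD(Lq + 1, Lt + 1);
  std::fill(MM.begin(), MM.end(), NEG_INF);
  std::fill(MI.begin(), MI.end(), NEG_INF);
  std::fill(IM.begin(), IM.end(), NEG_INF);
  std::fill(DG.begin(), DG.end(), NEG_INF);
  std::fill(GD.begin(), GD.end(), NEG_INF);

  for (int i = 1; i <= Lq; ++i) {
    for (int j = 1; j <= Lt; ++j) {
      // ---- MM: candidates in tie-break priority MM > MI > IM > DG > GD > start
      double best = NEG_INF;
      int arg = -1;
      if (i >= 2 && j >= 2) {
        double c;
        c = MM(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tMM);
        if (c > best) { best = c; arg = 1; }
        c = MI(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tIM);
        if (c > best) { best = c; arg = 2; }
        c = IM(i - 1, j - 1) + qtr(i - 2, tIM) + ttr(j - 2, tMM);
        if (c > best) { best = c; arg = 3; }
        c = DG(i - 1, j - 1) + qtr(i - 2, tDM) + ttr(j - 2, tMM);
        if (c > best) { best = c; arg = 4; }
        c = GD(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tDM);
        if (c > best) { best = c; arg = 5; }
      }
      if (local || (i == 1 && j == 1)) {
        if (0.0 > best) { best = 0.0; arg = 0; }
      }
      if (arg >= 0) {
        MM(i, j) = S(i - 1, j - 1) + best;
        bMM(i, j) = arg;
      }
      // ---- MI / DG (advance i; need a predecessor row)
      if (i >= 2) {
        double fromM = MM(i - 1, j) + qtr(i - 2, tMM) + ttr(j - 1, tMI);
        double ext   = MI(i - 1, j) + qtr(i - 2, tMM) + ttr(j - 1, tII);
        if (fromM >= ext) { MI(i, j) = fromM; bMI(i, j) = 1; }
        else              { MI(i, j) = ext;   bMI(i, j) = 2; }
        fromM = MM(i - 1, j) + qtr(i - 2, tMD);
        ext   = DG(i - 1, j) + qtr(i - 2, tDD);
        if (fromM >= ext) { DG(i, j) = fromM; bDG(i, j) = 1; }
        else              { DG(i, j) = ext;   bDG(i, j) = 4; }
      }
      // ---- IM / GD (advance j)
      if (j >= 2) {
        double fromM = MM(i, j - 1) + ttr(j - 2, tMM) + qtr(i - 1, tMI);
        double ext   = IM(i, j - 1) + ttr(j - 2, tMM) + qtr(i - 1, tII);
        if (fromM >= ext) { IM(i, j) = fromM; bIM(i, j) = 1; }
        else              { IM(i, j) = ext;   bIM(i, j) = 3; }
        fromM = MM(i, j - 1) + ttr(j - 2, tMD);
        ext   = GD(i, j - 1) + ttr(j - 2, tDD);
        if (fromM >= ext) { GD(i, j) = fromM; bGD(i, j) = 1; }
        else              { GD(i, j) = ext;   bGD(i, j) = 5; }
      }
    }
  }

  // ---- choose the end cell
  double score;
  int ei = 0, ej = 0;
  if (local) {
    score = 0.0;  // empty alignment allowed
    for (int i = 1; i <= Lq; ++i)
      for (int j = 1; j <= Lt; ++j)
        if (MM(i, j) > score) { score = MM(i, j); ei = i; ej = j; }
  } else {
    score = MM(Lq, Lt);
    ei = Lq; ej = Lt;
  }

  // ---- traceback (codes: 1 MM, 2 MI, 3 IM, 4 DG, 5 GD)
  std::vector<int> qi, tj, st;
  if (ei > 0 && score > NEG_INF) {
    int i = ei, j = ej, state = 1;
    while (true) {
      if (state == 1) {
        qi.push_back(i); tj.push_back(j); st.push_back(1);
        int prev = bMM(i, j);
        if (prev == 0) break;
        state = prev; --i; --j;
      } else if (state == 2) {
        qi.push_back(i); tj.push_back(0); st.push_back(2);
        state = bMI(i, j); --i;
      } else if (state == 4) {
        qi.push_back(i); tj.push_back(0); st.push_back(4);
        state = bDG(i, j); --i;
      } else if (state == 3) {
        qi.push_back(0); tj.push_back(j); st.push_back(3);
        state = bIM(i, j); --j;
      } else {  // 5 = GD
        qi.push_back(0); tj.push_back(j); st.push_back(5);
        state = bGD(i, j); --j;
      }
    }
  }
  const int n = (int)qi.size();
  IntegerVector outQ(n), outT(n), outS(n);
  for (int k = 0; k < n; ++k) {  // reverse into forward order
    outQ[k] = qi[n - 1 - k];
    outT[k] = tj[n - 1 - k];
    outS[k] = st[n - 1 - k];
  }
  return List::create(_["score"] = score, _["qpos"] = outQ, _["tpos"] = outT,
                      _["state"] = outS,
                      _["S_MM"] = MM, _["S_MI"] = MI, _["S_IM"] = IM,
                      _["S_DG"] = DG, _["S_GD"] = GD);
}

// Forward-Backward over the same five-state pair HMM, in log2 space.
// start(i,j) = p_min except 1 at (1,1); end(i,j) = p_min except 1 at
// (Lq,Lt) -- so p_min = 1 gives the local model (paths may start and end
// anywhere), p_min = 0 the global model.
// [[Rcpp::export(name = ".forward_backward_dp")]]
List forward_backward_dp(NumericMatrix S, NumericMatrix qtr,
                         NumericMatrix ttr, double p_min) {
  const int Lq = S.nrow(), Lt = S.ncol();
  const double lp_min = p_min > 0 ? std::log2(p_min) : NEG_INF;
  NumericMatrix fMM(Lq + 1, Lt + 1), fMI(Lq + 1, Lt + 1), fIM(Lq + 1, Lt + 1),
      fDG(Lq + 1, Lt + 1), fGD(Lq + 1, Lt + 1);
  std::fill(fMM.begin(), fMM.end(), NEG_INF);
  std::fill(fMI.begin(), fMI.end(), NEG_INF);
  std::fill(fIM.begin(), fIM.end(), NEG_INF);
  std::fill(fDG.begin(), fDG.end(), NEG_INF);
  std::fill(fGD.begin(), fGD.end(), NEG_INF);

  for (int i = 1; i <= Lq; ++i) {
    for (int j = 1; j <= Lt; ++j) {
      double acc = (i == 1 && j == 1) ? 0.0 : lp_min;  // start weight
      if (i >= 2 && j >= 2) {
        acc = lse2(acc, fMM(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tMM));
        acc = lse2(acc, fMI(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tIM));
        acc = lse2(acc, fIM(i - 1, j - 1) + qtr(i - 2, tIM) + ttr(j - 2, tMM));
        acc = lse2(acc, fDG(i - 1, j - 1) + qtr(i - 2, tDM) + ttr(j - 2, tMM));
        acc = lse2(acc, fGD(i - 1, j - 1) + qtr(i - 2, tMM) + ttr(j - 2, tDM));
      }
      fMM(i, j) = S(i - 1, j - 1) + acc;
      if (i >= 2) {
        fMI(i, j) = lse2(fMM(i - 1, j) + qtr(i - 2, tMM) + ttr(j - 1, tMI),
                         fMI(i - 1, j) + qtr(i - 2, tMM) + ttr(j - 1, tII));
        fDG(i, j) = lse2(fMM(i - 1, j) + qtr(i - 2, tMD),
                         fDG(i - 1, j) + qtr(i - 2, tDD));
      }
      if (j >= 2) {
        fIM(i, j) = lse2(fMM(i, j - 1) + ttr(j - 2, tMM) + qtr(i - 1, tMI),
                         fIM(i, j - 1) + ttr(j - 2, tMM) + qtr(i - 1, tII));
        fGD(i, j) = lse2(fMM(i, j - 1) + ttr(j - 2, tMD),
                         fGD(i, j - 1) + ttr(j - 2, tDD));
      }
    }
  }

  NumericMatrix bMM(Lq + 2, Lt + 2), bMI(Lq + 2, Lt + 2), bIM(Lq + 2, Lt + 2),
      bDG(Lq + 2, Lt + 2), bGD(Lq + 2, Lt + 2);
  std::fill(bMM.begin(), bMM.end(), NEG_INF);
  std::fill(bMI.begin(), bMI.end(), NEG_INF);
  std::fill(bIM.begin(), bIM.end(), NEG_INF);
  std::fill(bDG.begin(), bDG.end(), NEG_INF);
  std::fill(bGD.begin(), bGD.end(), NEG_INF);

  for (int i = Lq; i >= 1; --i) {
    for (int j = Lt; j >= 1; --j) {
      double nextMM = (i < Lq && j < Lt)
          ? S(i, j) + bMM(i + 1, j + 1) : NEG_INF;  // S at (i+1,j+1), 0-based
      double acc = (i == Lq && j == Lt) ? 0.0 : lp_min;  // end weight
      acc = lse2(acc, nextMM + qtr(i - 1, tMM) + ttr(j - 1, tMM));
      if (i < Lq)
        acc = lse2(acc, bMI(i + 1, j) + qtr(i - 1, tMM) + ttr(j - 1, tMI));
      if (i < Lq)
        acc = lse2(acc, bDG(i + 1, j) + qtr(i - 1, tMD));
      if (j < Lt)
        acc = lse2(acc, bIM(i, j + 1) + ttr(j - 1, tMM) + qtr(i - 1, tMI));
      if (j < Lt)
        acc = lse2(acc, bGD(i, j + 1) + ttr(j - 1, tMD));
      bMM(i, j) = acc;

      bMI(i, j) = lse2(nextMM + qtr(i - 1, tMM) + ttr(j - 1, tIM),
                       i < Lq ? bMI(i + 1, j) + qtr(i - 1, tMM) + ttr(j - 1, tII)
                              : NEG_INF);
      bDG(i, j) = lse2(nextMM + qtr(i - 1, tDM) + ttr(j - 1, tMM),
                       i < Lq ? bDG(i + 1, j) + qtr(i - 1, tDD) : NEG_INF);
      bIM(i, j) = lse2(nextMM + qtr(i - 1, tIM) + ttr(j - 1, tMM),
                       j < Lt ? bIM(i, j + 1) + ttr(j - 1, tMM) + qtr(i - 1, tII)
                              : NEG_INF);
      bGD(i, j) = lse2(nextMM + qtr(i - 1, tMM) + ttr(j - 1, tDM),
                       j < Lt ? bGD(i, j + 1) + ttr(j - 1, tDD) : NEG_INF);
    }
  }

  // total partition from both directions
  double logZf = NEG_INF, logZb = NEG_INF;
  if (p_min > 0) {
    for (int i = 1; i <= Lq; ++i)
      for (int j = 1; j <= Lt; ++j) {
        double endw = (i == Lq && j == Lt) ? 0.0 : lp_min;
        double startw = (i == 1 && j == 1) ? 0.0 : lp_min;
        logZf = lse2(logZf, fMM(i, j) + endw);
        logZb = lse2(logZb, S(i - 1, j - 1) + bMM(i, j) + startw);
      }
  } else {
    logZf = fMM(Lq, Lt);
    logZb = S(0, 0) + bMM(1, 1);
  }

  NumericMatrix post(Lq, Lt);
  for (int i = 1; i <= Lq; ++i)
    for (int j = 1; j <= Lt; ++j) {
      double lp = fMM(i, j) + bMM(i, j) - logZf;
      post(i - 1, j - 1) = lp == NEG_INF ? 0.0 : std::exp2(lp);
    }

  NumericMatrix FMMo(Lq, Lt), BMMo(Lq, Lt);
  for (int i = 0; i < Lq; ++i)
    for (int j = 0; j < Lt; ++j) {
      FMMo(i, j) = fMM(i + 1, j + 1);
      BMMo(i, j) = bMM(i + 1, j + 1);
    }
  return List::create(_["posterior"] = post, _["logZ_forward"] = logZf,
                      _["logZ_backward"] = logZb, _["logF_MM"] = FMMo,
                      _["logB_MM"] = BMMo);
}
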