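#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b), safe for -Inf
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// Local Viterbi over a profile HMM in log2 (bit) space.
//
// lodds: L x M matrix of match-emission log-odds (bits) for each residue i
//        against model position j.  Insert emissions are scored against the
//        background and therefore contribute 0 bits.
// trans: M x 7 matrix of log2 transition probabilities out of position j,
//        columns (MM, MI, MD, IM, II, DM, DD).
// entry: log2 of the begin->Mj probability (uniform 1/M).
//
// Path score = sum of emission log-odds + sum of transition log2 probs +
// entry; exit after any match state is free.  Returns the maximal score,
// its envelope (1-based, inclusive) and the match/delete path, with ties
// broken toward the smaller envelope start, then smaller envelope end.
// [[Rcpp::export]]
List viterbi_local_cpp(NumericMatrix lodds, NumericMatrix trans, double entry) {
  const int L = lodds.nrow(), M = lodds.ncol();
  // DP matrices indexed [i][j], i = 1..L, j = 1..M (0 row/col unused)
  std::vector<std::vector<double> > VM(L + 1, std::vector<double>(M + 1, NEG_INF));
  std::vector<std::vector<double> > VI(L + 1, std::vector<double>(M + 1, NEG_INF));
  std::vector<std::vector<double> > VD(L + 1, std::vector<double>(M + 1, NEG_INF));
  std::vector<std::vector<int> > SM(L + 1, std::vector<int>(M + 1, 0));
  std::vector<std::vector<int> > SI(L + 1, std::vector<int>(M + 1, 0));
  std::vector<std::vector<int> > SD(L + 1, std::vector<int>(M + 1, 0));
  std::vector<std::vector<signed char> > PM(L + 1, std::vector<signed char>(M + 1, -1));
  std::vector<std::vector<signed char> > PI(L + 1, std::vector<signed char>(M + 1, -1));
  std::vector<std::vector<signed char> > PD(L + 1, std::vector<signed char>(M + 1, -1));

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      // --- match state ---
      double best = entry; int bstart = i; signed char bptr = 0;
      if (j > 1 && i > 1) {
        double c = VM[i - 1][j - 1] + trans(j - 2, 0);
        if (c > best || (c == best && c != NEG_INF && SM[i - 1][j - 1] < bstart)) {
          best = c; bstart = SM[i - 1][j - 1]; bptr = 1;
        }
        c = VI[i - 1][j - 1] + trans(j - 2, 3);
        if (c > best || (c == best && c != NEG_INF && SI[i - 1][j - 1] < bstart)) {
          best = c; bstart = SI[i - 1][j - 1]; bptr = 2;
        }
        c = VD[i - 1][j - 1] + trans(j - 2, 5);
        if (c > best || (c == best && c != NEG_INF && SD[i - 1][j - 1] < bstart)) {
          best = c; bstart = SD[i - 1][j - 1]; bptr = 3;
        }
      }
      VM[i][j] = lodds(i - 1, j - 1) + best;
      SM[i][j] = bstart;
      PM[i][j] = bptr;

      // --- insert state (exists between match states, j = 1..M-1) ---
      if (j < M && i > 1) {
        double cM = VM[i - 1][j] + trans(j - 1, 1);
        double cI = VI[i - 1][j] + trans(j - 1, 4);
        if (cM >= cI) { VI[i][j] = cM; SI[i][j] = SM[i - 1][j]; PI[i][j] = 1; }
        else          { VI[i][j] = cI; SI[i][j] = SI[i - 1][j]; PI[i][j] = 2; }
        if (cM == cI && SI[i - 1][j] < SM[i - 1][j]) {
          VI[i][j] = cI; SI[i][j] = SI[i - 1][j]; PI[i][j] = 2;
        }
      }

      // --- delete state (silent, same i) ---
      if (j > 1) {
        double cM = VM[i][j - 1] + trans(j - 2, 2);
        double cD = VD[i][j - 1] + trans(j - 2, 6);
        if (cM >= cD) { VD[i][j] = cM; SD[i][j] = SM[i][j - 1]; PD[i][j] = 1; }
        else          { VD[i][j] = cD; SD[i][j] = SD[i][j - 1]; PD[i][j] = 3; }
        if (cM == cD && cM != NEG_INF && SD[i][j - 1] < SM[i][j - 1]) {
          VD[i][j] = cD; SD[i][j] = SD[i][j - 1]; PD[i][j] = 3;
        }
      }
    }
  }

  // best cell: max VM; ties -> smaller env_from, then smaller env_to
  double best = NEG_INF; int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      double v = VM[i][j];
      if (v == NEG_INF) continue;
      if (v > best ||
          (v == best && (SM[i][j] < SM[bi][bj] ||
                         (SM[i][j] == SM[bi][bj] && i < bi)))) {
        best = v; bi = i; bj = j;
      }
    }
  }

  IntegerVector path(M, 0);
  int env_from = NA_INTEGER, env_to = NA_INTEGER;
  if (bi > 0) {
    env_from = SM[bi][bj];
    env_to = bi;
    // traceback
    int i = bi, j = bj, state = 0; // 0=M, 1=I, 2=D
    while (true) {
      if (state == 0) {
        path[j - 1] = i;
        signed char p = PM[i][j];
        if (p == 0) break;
        if (p == 1) { --i; --j; state = 0; }
        else if (p == 2) { --i; --j; state = 1; }
        else { --i; --j; state = 2; }
      } else if (state == 1) {
        signed char p = PI[i][j];
        if (p == 1) { --i; state = 0; } else { --i; state = 1; }
      } else {
        path[j - 1] = -1;
        signed char p = PD[i][j];
        if (p == 1) { --j; state = 0; } else { --j; state = 2; }
      }
    }
  }

  return List::create(_["score"] = best, _["env_from"] = env_from,
                      _["env_to"] = env_to, _["path"] = path);
}

// Forward (log-sum-exp) score over the same local path space as
// viterbi_local_cpp; returns total log2-odds summed over all paths.
// [[Rcpp::export]]
double forward_local_cpp(NumericMatrix lodds, NumericMatrix trans, double entry) {
  const int L = lodds.nrow(), M = lodds.ncol();
  std::vector<std::vector<double> > FM(L + 1, std::vector<double>(M + 1, NEG_INF));
  std::vector<std::vector<double> > FI(L + 1, std::vector<double>(M + 1, NEG_INF));
  std::vector<std::vector<double> > FD(L + 1, std::vector<double>(M + 1, NEG_INF));
  double total = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      double acc = entry;
      if (j > 1 && i > 1) {
        acc = lse2(acc, FM[i - 1][j - 1] + trans(j - 2, 0));
        acc = lse2(acc, FI[i - 1][j - 1] + trans(j - 2, 3));
        acc = lse2(acc, FD[i - 1][j - 1] + trans(j - 2, 5));
      }
      FM[i][j] = lodds(i - 1, j - 1) + acc;
      if (j < M && i > 1) {
        FI[i][j] = lse2(FM[i - 1][j] + trans(j - 1, 1),
                        FI[i - 1][j] + trans(j - 1, 4));
      }
      if (j > 1) {
        FD[i][j] = lse2(FM[i][j - 1] + trans(j - 2, 2),
                        FD[i][j - 1] + trans(j - 2, 6));
      }
      total = lse2(total, FM[i][j]);
    }
  }
  return total;
}

// Local (Smith-Waterman) alignment with affine gap costs over a
// precomputed column-pair score matrix S (n x m, bits).  gap_open and
// gap_extend are positive costs in bits; a gap of length k costs
// gap_open + k * gap_extend.  Returns the maximal score and the number of
// alignment columns (pairs + gaps) on the optimal local path.
// [[Rcpp::export]]
List sw_affine_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  std::fill(E.begin(), E.end(), NEG_INF);
  std::fill(F.begin(), F.end(), NEG_INF);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = std::max(0.0, std::max(diag, std::max(E(i, j), F(i, j))));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback to count alignment columns
  int cols = 0, pairs = 0;
  if (best > 0.0) {
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (gap in rows), 2 = F (gap in cols)
    while (i > 0 && j > 0 && !(state == 0 && H(i, j) == 0.0)) {
      if (state == 0) {
        if (H(i, j) == H(i - 1, j - 1) + S(i - 1, j - 1)) {
          ++cols; ++pairs; --i; --j;
        } else if (H(i, j) == E(i, j)) {
          state = 1;
        } else if (H(i, j) == F(i, j)) {
          state = 2;
        } else {
          break; // H == 0 handled by loop condition
        }
      } else if (state == 1) {
        ++cols;
        if (E(i, j) == E(i, j - 1) - gap_extend) { --j; }
        else { --j; state = 0; }
      } else {
        ++cols;
        if (F(i, j) == F(i - 1, j) - gap_extend) { --i; }
        else { --i; state = 0; }
      }
    }
  }
  return List::create(_["score"] = best, _["aligned_len"] = cols,
                      _["aligned_pairs"] = pairs);
}
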