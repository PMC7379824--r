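// Dynamic programming over the local profile-HMM topology.
//
// States (0-based internally): match M_j (j = 0..L-1), insert I_j between
// M_j and M_{j+1} (j = 0..L-2), delete D_j covering match column j
// (reachable for j = 1..L-1). Free local entry B -> M_j and exit
// M_j -> E; D_{L-1} exits with probability 1. Flanking residues are
// emitted by the null model and contribute zero log-odds, so the score of
// a hit is the sum of transition log-probabilities and emission log-odds
// along the path, maximised (Viterbi) or log-summed (forward) over all
// start positions, entry states and paths. All scores are in bits
// (log base 2).
//
// Sequence codes: 1..20 residues, 21 unknown (log-odds 0 is expected in
// that column of the emission log-odds matrices), 22 masked (-Inf).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log2_add(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log2(1.0 + std::exp2(b - a));
}

// Tie-break preference when scores are equal: match > delete > insert >
// entry. Implemented by evaluating candidates in that order with a strict
// improvement test.
struct Best {
  double score;
  int ptr;
  Best() : score(NEG_INF), ptr(-1) {}
  inline void consider(double s, int p) {
    if (s > score) { score = s; ptr = p; }
  }
};

// Pointer codes: 0 = entry (B), 1 = from M, 2 = from D, 3 = from I.

// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix mlo, NumericMatrix ilo,
                 NumericVector entry, NumericVector lmm, NumericVector lmi,
                 NumericVector lmd, NumericVector lme, NumericVector lim,
                 NumericVector lii, NumericVector ldm, NumericVector ldd,
                 IntegerVector seq) {
  const int L = mlo.nrow();
  const int n = seq.size();

  std::vector<double> VM((n + 1) * L, NEG_INF), VI((n + 1) * L, NEG_INF),
      VD((n + 1) * L, NEG_INF);
  std::vector<signed char> PM((n + 1) * L, -1), PI((n + 1) * L, -1),
      PD((n + 1) * L, -1);
#define IDX(i, j) ((i) * L + (j))

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1] - 1;  // 0-based emission column
    for (int j = 0; j < L; ++j) {
      Best bm;
      if (j > 0) {
        bm.consider(VM[IDX(i - 1, j - 1)] + lmm[j - 1], 1);
        bm.consider(VD[IDX(i - 1, j - 1)] + ldm[j - 1], 2);
        bm.consider(VI[IDX(i - 1, j - 1)] + lim[j - 1], 3);
      }
      bm.consider(entry[j], 0);
      double e = mlo(j, x);
      VM[IDX(i, j)] = (bm.score == NEG_INF || e == NEG_INF)
                          ? NEG_INF : bm.score + e;
      PM[IDX(i, j)] = (signed char)bm.ptr;

      Best bi;
      bi.consider(VM[IDX(i - 1, j)] + lmi[j], 1);
      bi.consider(VI[IDX(i - 1, j)] + lii[j], 3);
      double ei = ilo(j, x);
      VI[IDX(i, j)] = (bi.score == NEG_INF || ei == NEG_INF)
                          ? NEG_INF : bi.score + ei;
      PI[IDX(i, j)] = (signed char)bi.ptr;
    }
    // deletes consume no residue: fill row i left to right after M
    for (int j = 1; j < L; ++j) {
      Best bd;
      bd.consider(VM[IDX(i, j - 1)] + lmd[j - 1], 1);
      bd.consider(VD[IDX(i, j - 1)] + ldd[j - 1], 2);
      VD[IDX(i, j)] = bd.score;
      PD[IDX(i, j)] = (signed char)bd.ptr;
    }
  }

  // end state: from any M_j (cost lme[j]) or from D_{L-1} (free)
  double best = NEG_INF;
  int bi_end = -1, bj_end = -1, btype = -1;  // btype 1 = M, 2 = D
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j < L; ++j) {
      double s = VM[IDX(i, j)] + lme[j];
      if (s > best) { best = s; bi_end = i; bj_end = j; btype = 1; }
    }
    if (L > 1) {
      double s = VD[IDX(i, L - 1)];
      if (s > best) { best = s; bi_end = i; bj_end = L - 1; btype = 2; }
    }
  }

  if (best == NEG_INF) {
    return List::create(_["bit_score"] = NEG_INF,
                        _["path"] = IntegerMatrix(0, 3),
                        _["env_start"] = NA_INTEGER,
                        _["env_end"] = NA_INTEGER);
  }

  // traceback
  std::vector<int> st_type, st_j, st_pos;  // type 1=M 2=I 3=D
  int i = bi_end, j = bj_end, type = btype == 1 ? 1 : 3;
  while (true) {
    int ptr;
    if (type == 1) {  // M_j emitted seq[i-1]
      st_type.push_back(1); st_j.push_back(j + 1); st_pos.push_back(i);
      ptr = PM[IDX(i, j)];
      if (ptr == 0) break;
      if (ptr == 1) { type = 1; --i; --j; }
      else if (ptr == 2) { type = 3; --i; --j; }
      else { type = 2; --i; --j; }
    } else if (type == 2) {  // I_j emitted seq[i-1]
      st_type.push_back(2); st_j.push_back(j + 1); st_pos.push_back(i);
      ptr = PI[IDX(i, j)];
      --i;
      type = (ptr == 1) ? 1 : 2;
    } else {  // D_j, no emission
      st_type.push_back(3); st_j.push_back(j + 1); st_pos.push_back(0);
      ptr = PD[IDX(i, j)];
      --j;
      type = (ptr == 1) ? 1 : 3;
    }
  }

  const int m = (int)st_type.size();
  IntegerMatrix path(m, 3);
  int env_start = n, env_end = 0;
  for (int k = 0; k < m; ++k) {
    path(k, 0) = st_type[m - 1 - k];
    path(k, 1) = st_j[m - 1 - k];
    path(k, 2) = st_pos[m - 1 - k];
    if (st_pos[m - 1 - k] > 0) {
      if (st_pos[m - 1 - k] < env_start) env_start = st_pos[m - 1 - k];
      if (st_pos[m - 1 - k] > env_end) env_end = st_pos[m - 1 - k];
    }
  }
  colnames(path) = CharacterVector::create("state", "profile_index", "seq_pos");

  return List::create(_["bit_score"] = best,
                      _["path"] = path,
                      _["env_start"] = env_start - 1,  // 0-based half-open
                      _["env_end"] = env_end);
#undef IDX
}

// [[Rcpp::export]]
double cpp_forward(NumericMatrix mlo, NumericMatrix ilo,
                   NumericVector entry, NumericVector lmm, NumericVector lmi,
                   NumericVector lmd, NumericVector lme, NumericVector lim,
                   NumericVector lii, NumericVector ldm, NumericVector ldd,
                   IntegerVector seq) {
  const int L = mlo.nrow();
  const int n = seq.size();
  std::vector<double> FMprev(L, NEG_INF), FIprev(L, NEG_INF),
      FDprev(L, NEG_INF), FM(L), FI(L), FD(L);
  double total = NEG_INF;

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1] - 1;
    for (int j = 0; j < L; ++j) {
      double acc = entry[j];
      if (j > 0) {
        acc = log2_add(acc, FMprev[j - 1] + lmm[j - 1]);
        acc = log2_add(acc, FDprev[j - 1] + ldm[j - 1]);
        acc = log2_add(acc, FIprev[j - 1] + lim[j - 1]);
      }
      double e = mlo(j, x);
      FM[j] = (acc == NEG_INF || e == NEG_INF) ? NEG_INF : acc + e;

      double acci = log2_add(FMprev[j] + lmi[j], FIprev[j] + lii[j]);
      double ei = ilo(j, x);
      FI[j] = (acci == NEG_INF || ei == NEG_INF) ? NEG_INF : acci + ei;
    }
    FD[0] = NEG_INF;
    for (int j = 1; j < L; ++j) {
      FD[j] = log2_add(FM[j - 1] + lmd[j - 1], FD[j - 1] + ldd[j - 1]);
    }
    for (int j = 0; j < L; ++j) total = log2_add(total, FM[j] + lme[j]);
    if (L > 1) total = log2_add(total, FD[L - 1]);
    std::swap(FM, FMprev); std::swap(FI, FIprev); std::swap(FD, FDprev);
  }
  return total;
}
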