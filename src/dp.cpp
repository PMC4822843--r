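#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a > b) return a + std::log1p(std::exp(b - a));
  return b + std::log1p(std::exp(a - b));
}

// Forward log-odds (nats) of a uni-local profile HMM against a sequence.
// States M_k, I_k (k=1..L-1), D_k. Entry B->M_k with log_entry[k]; exit
// M_k->E with log_exit[k]. Flanking residues are scored by the null model
// (contribute 0 to the log-odds), and the domain may start after any
// prefix, so entry is available before every position. Insert states emit
// background (log-odds 0). No I<->D transitions.
// em_lo: L x 20 matrix of log(match emission / background).
// seq: 0-based residue indices.
// [[Rcpp::export]]
double forward_logodds_cpp(NumericMatrix em_lo,
                           NumericVector log_entry, NumericVector log_exit,
                           NumericVector lmm, NumericVector lmi,
                           NumericVector lmd, NumericVector lim,
                           NumericVector lii, NumericVector ldm,
                           NumericVector ldd, IntegerVector seq) {
  int L = em_lo.nrow(), n = seq.size();
  if (n == 0) return NEG_INF;
  std::vector<double> M(L, NEG_INF), I(L, NEG_INF), D(L, NEG_INF);
  std::vector<double> Mp(L), Ip(L), Dp(L);
  double total = NEG_INF;
  for (int i = 0; i < n; ++i) {
    Mp = M; Ip = I; Dp = D;
    int x = seq[i];
    for (int k = 0; k < L; ++k) {
      double acc = log_entry[k];  // fresh entry at this position
      if (i > 0 && k > 0) {
        acc = lse2(acc, Mp[k - 1] + lmm[k - 1]);
        acc = lse2(acc, Ip[k - 1] + lim[k - 1]);
        acc = lse2(acc, Dp[k - 1] + ldm[k - 1]);
      }
      M[k] = em_lo(k, x) + acc;
    }
    for (int k = 0; k < L - 1; ++k) {
      double acc = NEG_INF;
      if (i > 0) {
        acc = lse2(Mp[k] + lmi[k], Ip[k] + lii[k]);
      }
      I[k] = acc;
    }
    if (L > 0) I[L - 1] = NEG_INF;
    for (int k = 0; k < L; ++k) {
      double acc = NEG_INF;
      if (k > 0) {
        acc = lse2(M[k - 1] + lmd[k - 1], D[k - 1] + ldd[k - 1]);
      }
      D[k] = acc;
    }
    for (int k = 0; k < L; ++k)
      total = lse2(total, M[k] + log_exit[k]);
  }
  return total;
}

// Viterbi (max) version; returns best log-odds and the sequence span of
// emitted match/insert residues [start, end] (1-based) plus model span.
// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix em_lo,
                 NumericVector log_entry, NumericVector log_exit,
                 NumericVector lmm, NumericVector lmi,
                 NumericVector lmd, NumericVector lim,
                 NumericVector lii, NumericVector ldm,
                 NumericVector ldd, IntegerVector seq) {
  int L = em_lo.nrow(), n = seq.size();
  if (n == 0)
    return List::create(_["score"] = NEG_INF, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER, _["k_start"] = NA_INTEGER,
                        _["k_end"] = NA_INTEGER);
  // track start position (sequence index of entry) per cell
  std::vector<double> M(L, NEG_INF), I(L, NEG_INF), D(L, NEG_INF);
  std::vector<double> Mp(L), Ip(L), Dp(L);
  std::vector<int> Ms(L, -1), Is(L, -1), Ds(L, -1), Mk(L, -1), Ik(L, -1), Dk(L, -1);
  std::vector<int> Msp(L), Isp(L), Dsp(L), Mkp(L), Ikp(L), Dkp(L);
  double best = NEG_INF; int b_start = -1, b_end = -1, b_kstart = -1, b_kend = -1;
  for (int i = 0; i < n; ++i) {
    Mp = M; Ip = I; Dp = D; Msp = Ms; Isp = Is; Dsp = Ds;
    Mkp = Mk; Ikp = Ik; Dkp = Dk;
    int x = seq[i];
    for (int k = 0; k < L; ++k) {
      double v = log_entry[k]; int src = 0; // 0=entry,1=M,2=I,3=D
      if (i > 0 && k > 0) {
        double vm = Mp[k - 1] + lmm[k - 1];
        double vi = Ip[k - 1] + lim[k - 1];
        double vd = Dp[k - 1] + ldm[k - 1];
        if (vm > v) { v = vm; src = 1; }
        if (vi > v) { v = vi; src = 2; }
        if (vd > v) { v = vd; src = 3; }
      }
      M[k] = em_lo(k, x) + v;
      if (src == 0) { Ms[k] = i; Mk[k] = k; }
      else if (src == 1) { Ms[k] = Msp[k - 1]; Mk[k] = Mkp[k - 1]; }
      else if (src == 2) { Ms[k] = Isp[k - 1]; Mk[k] = Ikp[k - 1]; }
      else { Ms[k] = Dsp[k - 1]; Mk[k] = Dkp[k - 1]; }
    }
    for (int k = 0; k < L - 1; ++k) {
      double v = NEG_INF; int src = 1;
      if (i > 0) {
        double vm = Mp[k] + lmi[k];
        double vi = Ip[k] + lii[k];
        if (vm >= vi) { v = vm; src = 1; } else { v = vi; src = 2; }
      }
      I[k] = v;
      if (src == 1) { Is[k] = Msp[k]; Ik[k] = Mkp[k]; }
      else { Is[k] = Isp[k]; Ik[k] = Ikp[k]; }
    }
    if (L > 0) { I[L - 1] = NEG_INF; Is[L - 1] = -1; Ik[L - 1] = -1; }
    for (int k = 0; k < L; ++k) {
      double v = NEG_INF; int src = 1;
      if (k > 0) {
        double vm = M[k - 1] + lmd[k - 1];
        double vd = D[k - 1] + ldd[k - 1];
        if (vm >= vd) { v = vm; src = 1; } else { v = vd; src = 3; }
      }
      D[k] = v;
      if (src == 1 && k > 0) { Ds[k] = Ms[k - 1]; Dk[k] = Mk[k - 1]; }
      else if (k > 0) { Ds[k] = Ds[k - 1]; Dk[k] = Dk[k - 1]; }
    }
    for (int k = 0; k < L; ++k) {
      double v = M[k] + log_exit[k];
      if (v > best) {
        best = v; b_start = Ms[k] + 1; b_end = i + 1;
        b_kstart = Mk[k] + 1; b_kend = k + 1;
      }
    }
  }
  return List::create(_["score"] = best, _["start"] = b_start,
                      _["end"] = b_end, _["k_start"] = b_kstart,
                      _["k_end"] = b_kend);
}

// Local affine-gap alignment (Gotoh) on a precomputed column-score matrix.
// Used for profile-profile comparison. Returns best score and 1-based
// aligned ranges on both axes.
// [[Rcpp::export]]
List local_dp_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix Hs(n + 1, m + 1), Ht(n + 1, m + 1); // start coords
  std::fill(E.begin(), E.end(), NEG_INF);
  std::fill(F.begin(), F.end(), NEG_INF);
  double best = 0; int bi = 0, bj = 0, bsi = 0, bsj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = std::max({0.0, diag, E(i, j), F(i, j)});
      H(i, j) = h;
      if (h == 0.0) { Hs(i, j) = i; Ht(i, j) = j; }
      else if (h == diag) {
        Hs(i, j) = (H(i - 1, j - 1) == 0.0) ? i - 1 : Hs(i - 1, j - 1);
        Ht(i, j) = (H(i - 1, j - 1) == 0.0) ? j - 1 : Ht(i - 1, j - 1);
        if (Hs(i, j) == i - 1 && H(i - 1, j - 1) == 0.0) {
          Hs(i, j) = i - 1; Ht(i, j) = j - 1;
        }
      } else if (h == E(i, j)) { Hs(i, j) = Hs(i, j - 1); Ht(i, j) = Ht(i, j - 1); }
      else { Hs(i, j) = Hs(i - 1, j); Ht(i, j) = Ht(i - 1, j); }
      if (h > best) { best = h; bi = i; bj = j; bsi = Hs(i, j); bsj = Ht(i, j); }
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = bsi + 1, _["a_end"] = bi,
                      _["b_start"] = bsj + 1, _["b_end"] = bj);
}

// Global affine-gap alignment (Gotoh) on a column-score matrix, with full
// traceback. Returns two integer vectors giving, for each alignment
// column, the 1-based source column on each axis (0 = gap). Used for
// progressive profile-profile merging of multiple alignments.
// [[Rcpp::export]]
List global_dp_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  std::fill(E.begin(), E.end(), NEG_INF);
  std::fill(F.begin(), F.end(), NEG_INF);
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -gap_open - gap_extend * (j - 1);
    H(0, j) = E(0, j);
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -gap_open - gap_extend * (i - 1);
    H(i, 0) = F(i, 0);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      H(i, j) = std::max({diag, E(i, j), F(i, j)});
    }
  }
  // traceback
  std::vector<int> ai, bj;
  int i = n, j = m;
  int state = 0; // 0 = in H
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 && H(i, j) == H(i - 1, j - 1) + S(i - 1, j - 1)) {
        ai.push_back(i); bj.push_back(j); --i; --j;
      } else if (j > 0 && H(i, j) == E(i, j)) {
        state = 1;
      } else if (i > 0 && H(i, j) == F(i, j)) {
        state = 2;
      } else if (j > 0) { state = 1; } else { state = 2; }
    } else if (state == 1) { // in E: gap in a, consume b column
      ai.push_back(0); bj.push_back(j);
      if (j > 1 && E(i, j) == E(i, j - 1) - gap_extend) { --j; }
      else { --j; state = 0; }
    } else { // in F: gap in b, consume a column
      ai.push_back(i); bj.push_back(0);
      if (i > 1 && F(i, j) == F(i - 1, j) - gap_extend) { --i; }
      else { --i; state = 0; }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["score"] = H(n, m),
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bj.begin(), bj.end()));
}
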