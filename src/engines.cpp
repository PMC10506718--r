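#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Residue encoding: index into the supplied alphabet; -1 if absent ('X' etc.,
// which callers map to the matrix's last row/column).
static inline std::vector<int> encode(const std::string &s, const std::string &alpha) {
  std::vector<int> out(s.size(), -1);
  int map[256];
  for (int i = 0; i < 256; ++i) map[i] = -1;
  for (size_t i = 0; i < alpha.size(); ++i) map[(unsigned char)alpha[i]] = (int)i;
  for (size_t i = 0; i < s.size(); ++i) out[i] = map[(unsigned char)s[i]];
  return out;
}

static const double NEG = -1e12;

// Smith-Waterman with affine gaps (a gap of length k costs open + k * ext)
// and full traceback. Deterministic tie-breaks: best cell = highest score,
// ties -> smallest (row, col); traceback prefers match, then gap in the
// second sequence, then gap in the first; zero-scoring prefixes are not
// extended (shortest optimal alignment).
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  std::string alpha, int gap_open, int gap_ext) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1);
  }
  std::vector<int> ea = encode(a, alpha), eb = encode(b, alpha);
  int xi = sub.nrow() - 1;
  for (int i = 0; i < n; ++i) if (ea[i] < 0) ea[i] = xi;
  for (int j = 0; j < m; ++j) if (eb[j] < 0) eb[j] = xi;
  int go = gap_open + gap_ext, ge = gap_ext;
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, 0.0)),
      Ix(n + 1, std::vector<double>(m + 1, NEG)),
      Iy(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (double)sub(ea[i - 1], eb[j - 1]);
      double diag = 0.0;
      if (M[i - 1][j - 1] > diag) diag = M[i - 1][j - 1];
      if (Ix[i - 1][j - 1] > diag) diag = Ix[i - 1][j - 1];
      if (Iy[i - 1][j - 1] > diag) diag = Iy[i - 1][j - 1];
      M[i][j] = diag + s;
      Ix[i][j] = std::max(M[i - 1][j] - go, Ix[i - 1][j] - ge);
      Iy[i][j] = std::max(M[i][j - 1] - go, Iy[i][j - 1] - ge);
      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1);
  }
  int i = bi, j = bj, state = 0; // 0=M, 1=Ix, 2=Iy
  int a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      a_start = i; b_start = j;
      double s = (double)sub(ea[i - 1], eb[j - 1]);
      double need = M[i][j] - s;
      if (need <= 0.0) break; // fresh local start
      if (M[i - 1][j - 1] == need) state = 0;
      else if (Ix[i - 1][j - 1] == need) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (M[i - 1][j] - go == Ix[i][j]) state = 0;
      --i;
    } else {
      if (M[i][j - 1] - go == Iy[i][j]) state = 0;
      --j;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = bi,
                      _["b_start"] = b_start, _["b_end"] = bj);
}

static double sw_score_pair(const std::vector<int> &ea, const std::vector<int> &eb,
                            const int *submat, int nr, int go, int ge) {
  const int INEG = -(1 << 28);
  int n = (int)ea.size(), m = (int)eb.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<int> Mp(m + 1, 0), Mc(m + 1, 0);
  std::vector<int> Ixp(m + 1, INEG), Ixc(m + 1, INEG);
  std::vector<int> Iyp(m + 1, INEG), Iyc(m + 1, INEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = 0; Ixc[0] = INEG; Iyc[0] = INEG;
    const int *scol = submat + (size_t)ea[i - 1]; // row of sub, strided by nr
    for (int j = 1; j <= m; ++j) {
      int s = scol[(size_t)eb[j - 1] * nr];
      int diag = 0;
      if (Mp[j - 1] > diag) diag = Mp[j - 1];
      if (Ixp[j - 1] > diag) diag = Ixp[j - 1];
      if (Iyp[j - 1] > diag) diag = Iyp[j - 1];
      Mc[j] = diag + s;
      Ixc[j] = std::max(Mp[j] - go, Ixp[j] - ge);
      Iyc[j] = std::max(Mc[j - 1] - go, Iyc[j - 1] - ge);
      if (Mc[j] > best) best = Mc[j];
    }
    std::swap(Mp, Mc);
    std::swap(Ixp, Ixc);
    std::swap(Iyp, Iyc);
  }
  return (double)best;
}

// Score-only Smith-Waterman of one query against many targets.
// [[Rcpp::export(name = ".sw_scores_cpp")]]
NumericVector sw_scores_cpp(std::string a, CharacterVector bs, IntegerMatrix sub,
                            std::string alpha, int gap_open, int gap_ext) {
  std::vector<int> ea = encode(a, alpha);
  int xi = sub.nrow() - 1;
  for (size_t i = 0; i < ea.size(); ++i) if (ea[i] < 0) ea[i] = xi;
  int go = gap_open + gap_ext, ge = gap_ext;
  NumericVector out(bs.size());
  const int *submat = &sub(0, 0);
  for (int k = 0; k < bs.size(); ++k) {
    std::string b = as<std::string>(bs[k]);
    std::vector<int> eb = encode(b, alpha);
    for (size_t i = 0; i < eb.size(); ++i) if (eb[i] < 0) eb[i] = xi;
    out[k] = sw_score_pair(ea, eb, submat, sub.nrow(), go, ge);
  }
  return out;
}

// Local alignment of one sequence against a profile of M match states.
// emissions: M x 20 log2-odds matrix; 'X' residues void the cell (cannot be
// scored). Linear penalties (bits) per inserted residue / skipped state.
// Returns the best local score (floor 0) with target and state intervals.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(std::string seq, NumericMatrix emissions,
                       std::string alpha, double ins_pen, double del_pen) {
  int L = (int)seq.size(), M = emissions.nrow();
  std::vector<int> es = encode(seq, alpha);
  if (L == 0 || M == 0) {
    return List::create(_["score"] = 0.0, _["t_start"] = 0, _["t_end"] = -1,
                        _["q_start"] = 0, _["q_end"] = -1);
  }
  std::vector<std::vector<double> > S(L + 1, std::vector<double>(M + 1, NEG)),
      I(L + 1, std::vector<double>(M + 1, NEG)),
      D(L + 1, std::vector<double>(M + 1, NEG));
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      double e = (es[i - 1] < 0) ? NEG : emissions(j - 1, es[i - 1]);
      if (e > NEG / 2) {
        double prev = 0.0;
        if (S[i - 1][j - 1] > prev) prev = S[i - 1][j - 1];
        if (I[i - 1][j - 1] > prev) prev = I[i - 1][j - 1];
        if (D[i - 1][j - 1] > prev) prev = D[i - 1][j - 1];
        S[i][j] = prev + e;
      }
      I[i][j] = std::max(S[i - 1][j], I[i - 1][j]) - ins_pen;
      D[i][j] = std::max(S[i][j - 1], D[i][j - 1]) - del_pen;
      if (S[i][j] > best + 1e-12) { best = S[i][j]; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0.0) {
    return List::create(_["score"] = 0.0, _["t_start"] = 0, _["t_end"] = -1,
                        _["q_start"] = 0, _["q_end"] = -1);
  }
  int i = bi, j = bj, state = 0; // 0=S, 1=I, 2=D
  int t_start = bi, q_start = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      t_start = i; q_start = j;
      double e = emissions(j - 1, es[i - 1]);
      double need = S[i][j] - e;
      if (need <= 1e-9) break; // fresh local start
      if (std::fabs(S[i - 1][j - 1] - need) < 1e-9) state = 0;
      else if (std::fabs(I[i - 1][j - 1] - need) < 1e-9) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      if (std::fabs(S[i - 1][j] - (I[i][j] + ins_pen)) < 1e-9) state = 0;
      --i;
    } else {
      if (std::fabs(S[i][j - 1] - (D[i][j] + del_pen)) < 1e-9) state = 0;
      --j;
    }
  }
  return List::create(_["score"] = best,
                      _["t_start"] = t_start, _["t_end"] = bi,
                      _["q_start"] = q_start, _["q_end"] = bj);
}

// Score-only profile scan over many targets.
// [[Rcpp::export(name = ".profile_scores_cpp")]]
NumericVector profile_scores_cpp(CharacterVector seqs, NumericMatrix emissions,
                                 std::string alpha, double ins_pen, double del_pen) {
  int M = emissions.nrow();
  NumericVector out(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) {
    std::string seq = as<std::string>(seqs[k]);
    int L = (int)seq.size();
    std::vector<int> es = encode(seq, alpha);
    std::vector<double> Sp(M + 1, NEG), Sc(M + 1, NEG);
    std::vector<double> Ip(M + 1, NEG), Ic(M + 1, NEG);
    std::vector<double> Dp(M + 1, NEG), Dc(M + 1, NEG);
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      Sc[0] = NEG; Ic[0] = NEG; Dc[0] = NEG;
      for (int j = 1; j <= M; ++j) {
        double e = (es[i - 1] < 0) ? NEG : emissions(j - 1, es[i - 1]);
        if (e > NEG / 2) {
          double prev = 0.0;
          if (Sp[j - 1] > prev) prev = Sp[j - 1];
          if (Ip[j - 1] > prev) prev = Ip[j - 1];
          if (Dp[j - 1] > prev) prev = Dp[j - 1];
          Sc[j] = prev + e;
        } else {
          Sc[j] = NEG;
        }
        Ic[j] = std::max(Sp[j], Ip[j]) - ins_pen;
        Dc[j] = std::max(Sc[j - 1], Dc[j - 1]) - del_pen;
        if (Sc[j] > best) best = Sc[j];
      }
      std::swap(Sp, Sc);
      std::swap(Ip, Ic);
      std::swap(Dp, Dc);
    }
    out[k] = best;
  }
  return out;
}
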