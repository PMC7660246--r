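#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap alignment kernels.
//
// Conventions shared by every routine here:
//  * sequences arrive as 0-based integer codes (R does the encoding);
//  * a gap of length L costs gap_open + L * gap_extend (BLAST convention),
//    so the transition that opens a gap costs gap_open + gap_extend;
//  * rows index the query `a`, columns the subject `b`;
//  * tie-breaks are deterministic: diagonal, then up (gap in subject),
//    then left (gap in query); the local traceback starts at the
//    first maximal cell in row-major scan order.

static const int NEG_INF = INT_MIN / 4;

// Score-only local (Smith-Waterman) alignment, linear memory.
// H rolls row by row; E (gap in query, leftward) is per-cell within the
// current row; F (gap in subject, downward) is kept per column.
static int sw_score(const int* a, int la, const int* b, int lb,
                    const int* sub, int ncode, int go, int ge) {
  std::vector<int> H((size_t)lb + 1, 0), Fcol((size_t)lb + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    const int* srow = sub + (size_t)a[i - 1] * ncode;
    int diag = 0;        // H[i-1][j-1], starts at H[i-1][0] = 0
    int hleft = 0;       // H[i][j-1], column 0 of a local alignment is 0
    int ecur = NEG_INF;  // E[i][j-1] rolled forward
    for (int j = 1; j <= lb; ++j) {
      ecur = std::max(ecur - ge, hleft - go - ge);
      int up = H[j];     // H[i-1][j]
      int f = std::max(Fcol[j] - ge, up - go - ge);
      Fcol[j] = f;
      int h = diag + srow[b[j - 1]];
      if (ecur > h) h = ecur;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = up;
      H[j] = h;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_score_pairs(List seqs_a, List seqs_b,
                              IntegerVector ai, IntegerVector bi,
                              IntegerMatrix sub, int gap_open, int gap_extend) {
  int n = ai.size();
  if (bi.size() != n) stop("ai and bi must have equal length");
  int ncode = sub.ncol();
  std::vector<const int*> pa(seqs_a.size()), pb(seqs_b.size());
  std::vector<int> la(seqs_a.size()), lb(seqs_b.size());
  std::vector<IntegerVector> keep_a(seqs_a.size()), keep_b(seqs_b.size());
  for (int i = 0; i < seqs_a.size(); ++i) {
    keep_a[i] = seqs_a[i]; pa[i] = INTEGER(keep_a[i]); la[i] = keep_a[i].size();
  }
  for (int i = 0; i < seqs_b.size(); ++i) {
    keep_b[i] = seqs_b[i]; pb[i] = INTEGER(keep_b[i]); lb[i] = keep_b[i].size();
  }
  // IntegerMatrix is column-major; transpose into row-major for cache-friendly rows
  std::vector<int> srm((size_t)ncode * ncode);
  for (int r = 0; r < ncode; ++r)
    for (int c = 0; c < ncode; ++c)
      srm[(size_t)r * ncode + c] = sub(r, c);
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int i = ai[k] - 1, j = bi[k] - 1;
    if (i < 0 || i >= (int)pa.size() || j < 0 || j >= (int)pb.size())
      stop("pair index out of range");
    out[k] = sw_score(pa[i], la[i], pb[j], lb[j], srm.data(), ncode,
                      gap_open, gap_extend);
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full local alignment with traceback and summary statistics.
// match_ok[code] == 0 marks ambiguity codes that never count as identities.
// [[Rcpp::export]]
List cpp_align_pair(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                    int gap_open, int gap_extend, IntegerVector match_ok) {
  int la = a.size(), lb = b.size();
  int ncode = sub.ncol();
  int go = gap_open, ge = gap_extend;
  size_t W = (size_t)lb + 1;
  std::vector<int> H((size_t)(la + 1) * W, 0), E((size_t)(la + 1) * W, NEG_INF),
      F((size_t)(la + 1) * W, NEG_INF);
  // trace codes: tH 0=origin 1=diag 2=from F(up) 3=from E(left);
  // tE/tF: 1=open(from H) 0=extend
  std::vector<unsigned char> tH((size_t)(la + 1) * W, 0),
      tE((size_t)(la + 1) * W, 0), tF((size_t)(la + 1) * W, 0);
  int best = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= la; ++i) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= lb; ++j) {
      int e_open = H[row + j - 1] - go - ge, e_ext = E[row + j - 1] - ge;
      if (e_open >= e_ext) { E[row + j] = e_open; tE[row + j] = 1; }
      else                 { E[row + j] = e_ext;  tE[row + j] = 0; }
      int f_open = H[prow + j] - go - ge, f_ext = F[prow + j] - ge;
      if (f_open >= f_ext) { F[row + j] = f_open; tF[row + j] = 1; }
      else                 { F[row + j] = f_ext;  tF[row + j] = 0; }
      int d = H[prow + j - 1] + sub(a[i - 1], b[j - 1]);
      int h = d; unsigned char t = 1;
      if (F[row + j] > h) { h = F[row + j]; t = 2; }
      if (E[row + j] > h) { h = E[row + j]; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[row + j] = h; tH[row + j] = t;
      if (h > best) { best = h; bi_ = i; bj_ = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  // traceback
  int i = bi_, j = bj_;
  long matches = 0, mismatches = 0, cols = 0, gapopens = 0, gapcols = 0;
  int state = 0; // 0 = in H
  int qend = bi_, send = bj_, qstart = bi_, sstart = bj_;
  while (true) {
    size_t idx = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1] && match_ok[a[i - 1]]) ++matches; else ++mismatches;
        qstart = i; sstart = j;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // F: gap in subject, consume a[i]
      ++cols; ++gapcols;
      qstart = i;
      if (tF[idx] == 1) { state = 0; ++gapopens; }
      --i;
    } else { // E: gap in query, consume b[j]
      ++cols; ++gapcols;
      sstart = j;
      if (tE[idx] == 1) { state = 0; ++gapopens; }
      --j;
    }
    if (i < 0 || j < 0) break;
  }
  return List::create(
      _["score"] = best, _["matches"] = (double)matches,
      _["mismatches"] = (double)mismatches, _["aligned_cols"] = (double)cols,
      _["gapopens"] = (double)gapopens, _["gapcols"] = (double)gapcols,
      _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send);
}

// Candidate pairs sharing >= min_shared distinct k-mers, over 0-based
// integer-coded sequences.  Exact words only; the shared-k-mer relation is
// symmetric.  Returns a 2-column matrix of (ai, bi), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_pairs(List enc_a, List enc_b, int k, int alpha,
                             int min_shared) {
  int na = enc_a.size(), nb = enc_b.size();
  auto words_of = [&](IntegerVector s) {
    std::vector<long long> w;
    int n = s.size();
    if (n >= k) {
      w.reserve(n - k + 1);
      for (int i = 0; i + k <= n; ++i) {
        long long h = 0;
        for (int t = 0; t < k; ++t) h = h * alpha + s[i + t];
        w.push_back(h);
      }
      std::sort(w.begin(), w.end());
      w.erase(std::unique(w.begin(), w.end()), w.end());
    }
    return w;
  };
  // flat sorted (word, owner) table for b
  std::vector<std::pair<long long, int>> tab;
  for (int j = 0; j < nb; ++j) {
    IntegerVector s = enc_b[j];
    for (long long h : words_of(s)) tab.push_back({h, j});
  }
  std::sort(tab.begin(), tab.end());
  std::vector<int> count(nb), touched;
  std::vector<int> out_a, out_b;
  for (int i = 0; i < na; ++i) {
    IntegerVector s = enc_a[i];
    touched.clear();
    for (long long h : words_of(s)) {
      auto lo = std::lower_bound(tab.begin(), tab.end(),
                                 std::make_pair(h, -1));
      for (auto it = lo; it != tab.end() && it->first == h; ++it) {
        if (count[it->second]++ == 0) touched.push_back(it->second);
      }
    }
    std::sort(touched.begin(), touched.end());
    for (int j : touched) {
      if (count[j] >= min_shared) { out_a.push_back(i + 1); out_b.push_back(j + 1); }
      count[j] = 0;
    }
  }
  IntegerMatrix out(out_a.size(), 2);
  for (size_t r = 0; r < out_a.size(); ++r) {
    out(r, 0) = out_a[r];
    out(r, 1) = out_b[r];
  }
  return out;
}

// Global (Needleman-Wunsch) affine alignment over a precomputed column-score
// matrix S (n1 x n2), used for profile-profile alignment in the progressive
// MSA.  Returns a 2-column matrix of 1-based row/column indices per alignment
// column, 0 marking a gap.
// [[Rcpp::export]]
IntegerMatrix cpp_nw_profile(NumericMatrix S, double gap_open, double gap_extend) {
  int n1 = S.nrow(), n2 = S.ncol();
  double go = gap_open, ge = gap_extend;
  const double NINF = -1e300;
  size_t W = (size_t)n2 + 1;
  std::vector<double> H((size_t)(n1 + 1) * W, NINF), E((size_t)(n1 + 1) * W, NINF),
      F((size_t)(n1 + 1) * W, NINF);
  std::vector<unsigned char> tH((size_t)(n1 + 1) * W, 0),
      tE((size_t)(n1 + 1) * W, 0), tF((size_t)(n1 + 1) * W, 0);
  H[0] = 0.0;
  for (int j = 1; j <= n2; ++j) {
    E[j] = -go - j * ge; H[j] = E[j]; tH[j] = 3; tE[j] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= n1; ++i) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    F[row] = -go - i * ge; H[row] = F[row]; tH[row] = 2; tF[row] = (i == 1) ? 1 : 0;
    for (int j = 1; j <= n2; ++j) {
      double e_open = H[row + j - 1] - go - ge, e_ext = E[row + j - 1] - ge;
      if (e_open >= e_ext) { E[row + j] = e_open; tE[row + j] = 1; }
      else                 { E[row + j] = e_ext;  tE[row + j] = 0; }
      double f_open = H[prow + j] - go - ge, f_ext = F[prow + j] - ge;
      if (f_open >= f_ext) { F[row + j] = f_open; tF[row + j] = 1; }
      else                 { F[row + j] = f_ext;  tF[row + j] = 0; }
      double d = H[prow + j - 1] + S(i - 1, j - 1);
      double h = d; unsigned char t = 1;
      if (F[row + j] > h) { h = F[row + j]; t = 2; }
      if (E[row + j] > h) { h = E[row + j]; t = 3; }
      H[row + j] = h; tH[row + j] = t;
    }
  }
  // traceback from (n1, n2)
  std::vector<int> ra, rb;
  int i = n1, j = n2, state = 0;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = tH[idx];
      if (t == 1) { ra.push_back(i); rb.push_back(j); --i; --j; }
      else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ra.push_back(i); rb.push_back(0);
      if (tF[idx] == 1) state = 0;
      --i;
    } else {
      ra.push_back(0); rb.push_back(j);
      if (tE[idx] == 1) state = 0;
      --j;
    }
  }
  int n = ra.size();
  IntegerMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    out(k, 0) = ra[n - 1 - k];
    out(k, 1) = rb[n - 1 - k];
  }
  return out;
}
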