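#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Nucleotide encoding: A=0 C=1 G=2 T=3, anything else (IUPAC ambiguity,
// gap) = 4.  Code-4 symbols score as mismatches and are excluded from the
// compared-site counts downstream.
static inline int enc_base(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

static std::vector<int> enc_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

static const int NEG = INT_MIN / 4;

// Workspace for Gotoh global alignment with traceback.  A gap of length L
// costs open + L * ext (both negative), i.e. the first gap character costs
// open + ext.  Tie-break: diagonal (M) over up (gap in b) over left (gap in
// a), applied both in the M recurrence and at the terminal state choice.
struct GotohWS {
  std::vector<int> M, X, Y;            // (n+1) x (m+1) row-major
  std::vector<unsigned char> tM, tX, tY;
  void resize(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tM.resize(cells); tX.resize(cells); tY.resize(cells);
    }
  }
};

struct AlnCounts {
  int score;
  int n_compared, n_ts, n_tv;
  std::string aligned_a, aligned_b;
};

static inline bool is_transition(int x, int y) {
  return (x == 0 && y == 2) || (x == 2 && y == 0) ||
         (x == 1 && y == 3) || (x == 3 && y == 1);
}

static AlnCounts gotoh_global(const std::string& sa, const std::string& sb,
                              const std::vector<int>& a, const std::vector<int>& b,
                              int match, int mismatch, int open, int ext,
                              GotohWS& ws, bool build_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)(m + 1);
  ws.resize((size_t)(n + 1) * W);
  int* M = ws.M.data(); int* X = ws.X.data(); int* Y = ws.Y.data();
  unsigned char* tM = ws.tM.data();
  unsigned char* tX = ws.tX.data();
  unsigned char* tY = ws.tY.data();

  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    size_t k = (size_t)j;
    M[k] = NEG; X[k] = NEG;
    Y[k] = open + ext * j;
    tY[k] = (j == 1) ? 0 : 1;          // 0 = opened from M, 1 = extended
  }
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W, rp = (size_t)(i - 1) * W;
    M[r] = NEG; Y[r] = NEG;
    X[r] = open + ext * i;
    tX[r] = (i == 1) ? 0 : 1;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1];
      const int s = (ai == bj && ai < 4) ? match : mismatch;
      // M from diagonal of M/X/Y (prefer M, then X, then Y)
      int best = M[rp + j - 1]; unsigned char t = 0;
      if (X[rp + j - 1] > best) { best = X[rp + j - 1]; t = 1; }
      if (Y[rp + j - 1] > best) { best = Y[rp + j - 1]; t = 2; }
      M[r + j] = (best <= NEG / 2) ? NEG : best + s;
      tM[r + j] = t;
      // X: gap in b, consume a_i ("up")
      int v0 = M[rp + j] <= NEG / 2 ? NEG : M[rp + j] + open + ext;
      int v1 = X[rp + j] <= NEG / 2 ? NEG : X[rp + j] + ext;
      if (v0 >= v1) { X[r + j] = v0; tX[r + j] = 0; }
      else          { X[r + j] = v1; tX[r + j] = 1; }
      // Y: gap in a, consume b_j ("left")
      v0 = M[r + j - 1] <= NEG / 2 ? NEG : M[r + j - 1] + open + ext;
      v1 = Y[r + j - 1] <= NEG / 2 ? NEG : Y[r + j - 1] + ext;
      if (v0 >= v1) { Y[r + j] = v0; tY[r + j] = 0; }
      else          { Y[r + j] = v1; tY[r + j] = 1; }
    }
  }

  size_t end = (size_t)n * W + m;
  int state = 0, score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  AlnCounts out; out.score = score;
  out.n_compared = 0; out.n_ts = 0; out.n_tv = 0;
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t k = (size_t)i * W + j;
    if (state == 0) {
      int x = a[i - 1], y = b[j - 1];
      if (x < 4 && y < 4) {
        out.n_compared++;
        if (x != y) { if (is_transition(x, y)) out.n_ts++; else out.n_tv++; }
      }
      if (build_strings) { ra.push_back(sa[i - 1]); rb.push_back(sb[j - 1]); }
      state = tM[k];
      --i; --j;
    } else if (state == 1) {
      if (build_strings) { ra.push_back(sa[i - 1]); rb.push_back('-'); }
      state = (tX[k] == 0) ? 0 : 1;
      --i;
    } else {
      if (build_strings) { ra.push_back('-'); rb.push_back(sb[j - 1]); }
      state = (tY[k] == 0) ? 0 : 2;
      --j;
    }
  }
  if (build_strings) {
    out.aligned_a.assign(ra.rbegin(), ra.rend());
    out.aligned_b.assign(rb.rbegin(), rb.rend());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_ext) {
  GotohWS ws;
  AlnCounts r = gotoh_global(a, b, enc_seq(a), enc_seq(b),
                             match, mismatch, gap_open, gap_ext, ws, true);
  return List::create(_["score"] = r.score,
                      _["aligned_a"] = r.aligned_a,
                      _["aligned_b"] = r.aligned_b,
                      _["n_compared"] = r.n_compared,
                      _["n_transitions"] = r.n_ts,
                      _["n_transversions"] = r.n_tv);
}

// All unordered pairs: global alignment, return count matrices from which
// p and K2P distances are derived in R.
// [[Rcpp::export]]
List cpp_pair_counts(CharacterVector seqs,
                     int match, int mismatch, int gap_open, int gap_ext) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  std::vector<std::vector<int> > es(n);
  for (int i = 0; i < n; ++i) {
    ss[i] = as<std::string>(seqs[i]);
    es[i] = enc_seq(ss[i]);
  }
  IntegerMatrix ncomp(n, n), nts(n, n), ntv(n, n), score(n, n);
  GotohWS ws;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      AlnCounts r = gotoh_global(ss[i], ss[j], es[i], es[j],
                                 match, mismatch, gap_open, gap_ext, ws, false);
      ncomp(i, j) = ncomp(j, i) = r.n_compared;
      nts(i, j) = nts(j, i) = r.n_ts;
      ntv(i, j) = ntv(j, i) = r.n_tv;
      score(i, j) = score(j, i) = r.score;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_compared"] = ncomp,
                      _["n_transitions"] = nts,
                      _["n_transversions"] = ntv,
                      _["score"] = score);
}

// Smith-Waterman local alignment score (score only, affine gaps with the
// same open + L*ext convention).
static int sw_score(const std::vector<int>& a, const std::vector<int>& b,
                    int match, int mismatch, int open, int ext,
                    std::vector<int>& H, std::vector<int>& F) {
  const int m = (int)b.size();
  H.assign(m + 1, 0);            // rolling row of H
  F.assign(m + 1, NEG);          // vertical gap state, per column
  int best = 0;
  for (size_t i = 1; i <= a.size(); ++i) {
    int diag = 0, E = NEG;       // H[i-1][j-1]; E = horizontal gap state
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (ai == b[j - 1] && ai < 4) ? match : mismatch;
      E = std::max(H[j - 1] + open + ext, E <= NEG / 2 ? NEG : E + ext);
      F[j] = std::max(H[j] + open + ext,
                      F[j] <= NEG / 2 ? NEG : F[j] + ext);
      int h = diag + s;
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_score_matrix(CharacterVector seqs,
                                     int match, int mismatch,
                                     int gap_open, int gap_ext) {
  const int n = seqs.size();
  std::vector<std::vector<int> > es(n);
  for (int i = 0; i < n; ++i) es[i] = enc_seq(as<std::string>(seqs[i]));
  IntegerMatrix sc(n, n);
  std::vector<int> H, E;
  for (int i = 0; i < n; ++i) {
    sc(i, i) = 0;
    for (int j = i + 1; j < n; ++j) {
      int s = sw_score(es[i], es[j], match, mismatch, gap_open, gap_ext, H, E);
      sc(i, j) = sc(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return sc;
}

// [[Rcpp::export]]
IntegerVector cpp_local_scores_query(std::string query, CharacterVector refs,
                                     int match, int mismatch,
                                     int gap_open, int gap_ext) {
  std::vector<int> q = enc_seq(query);
  IntegerVector out(refs.size());
  std::vector<int> H, E;
  for (int i = 0; i < refs.size(); ++i) {
    std::vector<int> r = enc_seq(as<std::string>(refs[i]));
    out[i] = sw_score(q, r, match, mismatch, gap_open, gap_ext, H, E);
  }
  return out;
}
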