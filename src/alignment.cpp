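#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else -1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Global affine-gap alignment (Gotoh). Scores: match > 0, mismatch < 0 given
// as magnitudes by the caller; a gap of length k costs gap_open + k*gap_extend.
// Traceback tie-break: diagonal (match/substitution) preferred over gap in b,
// preferred over gap in a, so the result is deterministic.
// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const double NEG = -1e18;
  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) {
    ea[i] = enc(a[i]);
    if (ea[i] < 0) stop("non-ACGT character in sequence a");
  }
  for (int j = 0; j < m; ++j) {
    eb[j] = enc(b[j]);
    if (eb[j] < 0) stop("non-ACGT character in sequence b");
  }
  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback state per matrix: which predecessor matrix fed the cell
  std::vector<uint8_t> tM((n + 1) * W, 0), tX((n + 1) * W, 0), tY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) { X[i * W] = -gap_open - i * gap_extend; tX[i * W] = 1; }
  for (int j = 1; j <= m; ++j) { Y[j] = -gap_open - j * gap_extend; tY[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = (ea[i - 1] == eb[j - 1]) ? match : -mismatch;
      // M: ties prefer predecessor M, then X, then Y
      double best = M[d]; uint8_t st = 0;
      if (X[d] > best) { best = X[d]; st = 1; }
      if (Y[d] > best) { best = Y[d]; st = 2; }
      M[c] = best + s; tM[c] = st;
      // X: gap in b (consume a[i-1])
      double fromM = M[u] - gap_open - gap_extend, ext = X[u] - gap_extend;
      if (fromM >= ext) { X[c] = fromM; tX[c] = 0; } else { X[c] = ext; tX[c] = 1; }
      // Y: gap in a (consume b[j-1])
      double fromM2 = M[l] - gap_open - gap_extend, ext2 = Y[l] - gap_extend;
      if (fromM2 >= ext2) { Y[c] = fromM2; tY[c] = 0; } else { Y[c] = ext2; tY[c] = 2; }
    }
  }
  const size_t e = n * W + m;
  double score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (state == 0) {
      uint8_t prev = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      uint8_t prev = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      uint8_t prev = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// Seed-and-extend ungapped local homology search of each query against one
// subject sequence. Returns 0-based half-open subject coordinates. Extension
// uses +1/-2 scoring with an X-drop, trimmed to the maximal-scoring extent;
// identity is computed over that extent. Per-diagonal coverage bookkeeping
// prevents re-extending seeds inside an already-extended segment.
// [[Rcpp::export]]
DataFrame seed_extend_cpp(std::string subject, CharacterVector queries,
                          int word_size, double min_identity, int min_length,
                          double xdrop) {
  const int S = (int) subject.size();
  std::vector<int> es(S);
  for (int i = 0; i < S; ++i) es[i] = enc(subject[i]);
  const int k = word_size;
  if (k < 4 || k > 31) stop("word_size must be in [4, 31]");

  // index subject k-mers
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(S > 0 ? (size_t) S : 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int run = 0;
  for (int i = 0; i < S; ++i) {
    if (es[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) es[i]) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }

  std::vector<int> out_q, out_s, out_e, out_len;
  std::vector<double> out_id;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int Q = (int) q.size();
    if (Q < k) continue;
    std::vector<int> eq(Q);
    for (int i = 0; i < Q; ++i) {
      eq[i] = enc(q[i]);
      if (eq[i] < 0) stop("non-ACGT character in query");
    }
    // diagonal -> subject end already covered by an extension
    std::unordered_map<long long, int> covered;
    uint64_t qkey = 0; int qrun = 0;
    for (int qp = 0; qp < Q; ++qp) {
      qkey = ((qkey << 2) | (uint64_t) eq[qp]) & mask;
      if (++qrun < k) continue;
      const int q0 = qp - k + 1;
      auto it = idx.find(qkey);
      if (it == idx.end()) continue;
      for (int sp : it->second) {
        const long long diag = (long long) sp - (long long) q0;
        auto cv = covered.find(diag);
        if (cv != covered.end() && sp < cv->second) continue;
        // extend right from end of seed
        int qr = q0 + k, sr = sp + k;
        double sc = 0, bestsc = 0;
        int best_qr = qr, best_sr = sr;
        while (qr < Q && sr < S && es[sr] >= 0) {
          sc += (eq[qr] == es[sr]) ? 1.0 : -2.0;
          ++qr; ++sr;
          if (sc > bestsc) { bestsc = sc; best_qr = qr; best_sr = sr; }
          if (sc < bestsc - xdrop) break;
        }
        // extend left from start of seed
        int ql = q0, sl = sp;
        sc = 0; bestsc = 0;
        int best_ql = ql, best_sl = sl;
        while (ql > 0 && sl > 0 && es[sl - 1] >= 0) {
          --ql; --sl;
          sc += (eq[ql] == es[sl]) ? 1.0 : -2.0;
          if (sc > bestsc) { bestsc = sc; best_ql = ql; best_sl = sl; }
          if (sc < bestsc - xdrop) break;
        }
        const int len = best_sr - best_sl;
        covered[diag] = best_sr;
        if (len < min_length) continue;
        int matches = 0;
        for (int t = 0; t < len; ++t)
          if (eq[best_ql + t] == es[best_sl + t]) ++matches;
        const double ident = (double) matches / (double) len;
        if (ident < min_identity) continue;
        out_q.push_back(qi + 1);
        out_s.push_back(best_sl);
        out_e.push_back(best_sr);
        out_len.push_back(len);
        out_id.push_back(ident);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["start"] = out_s,
                           _["end"] = out_e, _["aligned_length"] = out_len,
                           _["identity"] = out_id);
}
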