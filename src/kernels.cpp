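#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 U=3, anything else (N and ambiguity codes)=4.
// Code 4 never matches and never pairs.
static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default:  return 4;
  }
}

static inline double pair_weight(int a, int b, double w_gc, double w_au,
                                 double w_gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return w_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return w_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return w_gu;
  return R_PosInf;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_idx(s[i]);
  return v;
}

// Semi-global alignment of a short query against every substring of a
// database sequence: the query is consumed in full, the matched substring
// has free ends.  D[i][j] = minimum unit-cost edit distance (substitutions
// + single-nucleotide indels) between query[1..i] and some database
// substring ending at position j.  Returns the per-end best-edit vector
// plus one traced-back hit for every end position within max_edits.
// Hit coordinates are 1-based inclusive on the scanned strand.
// [[Rcpp::export(name = ".scan_kernel")]]
List scan_kernel(std::string db, std::string query, int max_edits) {
  const std::vector<int> d = encode(db);
  const std::vector<int> q = encode(query);
  const int n = (int)d.size(), m = (int)q.size();

  // full DP matrix kept for traceback; m is tiny (<= 24)
  std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1));
  for (int j = 0; j <= n; ++j) D[0][j] = 0;
  for (int i = 1; i <= m; ++i) {
    D[i][0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = (q[i - 1] == d[j - 1] && q[i - 1] != 4) ? 0 : 1;
      int best = D[i - 1][j - 1] + sub;
      if (D[i - 1][j] + 1 < best) best = D[i - 1][j] + 1;
      if (D[i][j - 1] + 1 < best) best = D[i][j - 1] + 1;
      D[i][j] = best;
    }
  }

  IntegerVector end_edits(n);
  for (int j = 1; j <= n; ++j) end_edits[j - 1] = D[m][j];

  std::vector<int> hs, he, hed, hsub, hgap;
  for (int j = 1; j <= n; ++j) {
    if (D[m][j] > max_edits) continue;
    // traceback, preferring diagonal moves (fewest gaps, deterministic)
    int i = m, jj = j, subs = 0, gaps = 0;
    while (i > 0) {
      int sub = (jj > 0 && q[i - 1] == d[jj - 1] && q[i - 1] != 4) ? 0 : 1;
      if (jj > 0 && D[i][jj] == D[i - 1][jj - 1] + sub) {
        subs += sub; --i; --jj;
      } else if (D[i][jj] == D[i - 1][jj] + 1) {
        ++gaps; --i;
      } else {
        ++gaps; --jj;
      }
    }
    hs.push_back(jj + 1);
    he.push_back(j);
    hed.push_back(D[m][j]);
    hsub.push_back(subs);
    hgap.push_back(gaps);
  }

  return List::create(
      _["end_edits"] = end_edits,
      _["hits"] = DataFrame::create(
          _["start"] = wrap(hs), _["end"] = wrap(he),
          _["edit_total"] = wrap(hed), _["substitutions"] = wrap(hsub),
          _["gaps"] = wrap(hgap)));
}

// Base-pair-weighted nested-structure folding (Nussinov-style dynamic
// programme minimising the sum of pair weights).  Hairpin loops span at
// least min_loop unpaired bases.  Deterministic traceback: at equal
// energy the leftmost position is paired, with the smallest partner.
// Returns 1-based partner vector (0 = unpaired) and the model energy.
// [[Rcpp::export(name = ".fold_kernel")]]
List fold_kernel(std::string seq, int min_loop, double w_gc, double w_au,
                 double w_gu) {
  const std::vector<int> s = encode(seq);
  const int n = (int)s.size();
  // M[i][j], 0-based inclusive interval; j < i means empty (energy 0)
  std::vector<std::vector<double>> M(n, std::vector<double>(n, 0.0));

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      double best = M[i + 1][j];  // i unpaired (i+1 <= j holds here)
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = pair_weight(s[i], s[k], w_gc, w_au, w_gu);
        if (!R_FINITE(w)) continue;
        double cand = w + (k - 1 >= i + 1 ? M[i + 1][k - 1] : 0.0) +
                      (k + 1 <= j ? M[k + 1][j] : 0.0);
        if (cand < best) best = cand;
      }
      M[i][j] = best;
    }
  }

  IntegerVector pairing(n, 0);
  std::vector<std::pair<int, int>> stack;
  if (n > 1) stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double w = pair_weight(s[i], s[k], w_gc, w_au, w_gu);
      if (!R_FINITE(w)) continue;
      double cand = w + (k - 1 >= i + 1 ? M[i + 1][k - 1] : 0.0) +
                    (k + 1 <= j ? M[k + 1][j] : 0.0);
      if (cand == M[i][j]) {
        pairing[i] = k + 1;
        pairing[k] = i + 1;
        if (k - 1 >= i + 1) stack.push_back({i + 1, k - 1});
        if (k + 1 <= j) stack.push_back({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }

  double energy = (n > 1) ? M[0][n - 1] : 0.0;
  return List::create(_["pairing"] = pairing, _["energy"] = energy);
}
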