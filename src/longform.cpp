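#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Edit distance primitives
// ---------------------------------------------------------------------------

static int lev_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = lev_one(sa, sb);
  }
  return out;
}

// Best approximate occurrence of `pattern` inside `text` (semi-global:
// pattern aligned end-to-end, substring of text free at both ends).
// Returns c(distance, start, end), start/end 0-based half-open in text.
// Ties broken by smallest start, then smallest end.
// [[Rcpp::export]]
IntegerVector cpp_edit_locate(std::string pattern, std::string text) {
  const int n = pattern.size(), m = text.size();
  if (n == 0) return IntegerVector::create(0, 0, 0);
  // D[i][j]: min edits aligning pattern[0..i) to text[?..j); free start in text.
  // Track start index of the window achieving the optimum.
  std::vector<int> prev(m + 1), cur(m + 1), sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int del = prev[j] + 1;      // pattern base unmatched
      int ins = cur[j - 1] + 1;   // extra text base inside window
      int best = sub, sb = sprev[j - 1];
      if (del < best || (del == best && sprev[j] < sb)) { best = del; sb = sprev[j]; }
      if (ins < best || (ins == best && scur[j - 1] < sb)) { best = ins; sb = scur[j - 1]; }
      cur[j] = best; scur[j] = sb;
    }
    std::swap(prev, cur); std::swap(sprev, scur);
  }
  int bestd = prev[0], bj = 0, bs = sprev[0];
  for (int j = 1; j <= m; ++j) {
    if (prev[j] < bestd ||
        (prev[j] == bestd && (sprev[j] < bs || (sprev[j] == bs && j < bj)))) {
      bestd = prev[j]; bj = j; bs = sprev[j];
    }
  }
  return IntegerVector::create(bestd, bs, bj);
}

// Smith-Waterman local alignment, linear gap penalty.
// Returns c(score, a_start, a_end, b_start, b_end) 0-based half-open.
// [[Rcpp::export]]
IntegerVector cpp_smith_waterman(std::string a, std::string b,
                                 int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = H[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = H[i - 1][j] + gap;
      int left = H[i][j - 1] + gap;
      int h = std::max(0, std::max(diag, std::max(up, left)));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback for span
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[i][j] > 0) {
    int h = H[i][j];
    int diag = H[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
    if (h == diag) { --i; --j; }
    else if (h == H[i - 1][j] + gap) { --i; }
    else if (h == H[i][j - 1] + gap) { --j; }
    else break; // h == 0
  }
  return IntegerVector::create(best, i, bi, j, bj);
}

// ---------------------------------------------------------------------------
// Read mutation with colinearity map
// ---------------------------------------------------------------------------

// Applies per-base substitutions / insertions / deletions to `seq` using R's
// RNG. Returns the mutated sequence plus a run map: colinear runs
// (orig_start, new_start, length) that break at every indel, so ground-truth
// alignment blocks can be derived exactly.
// [[Rcpp::export]]
List cpp_mutate_read(std::string seq, double p_sub, double p_ins, double p_del) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = seq.size();
  std::string out;
  out.reserve(n + 8);
  std::vector<int> r_orig, r_new, r_len;
  int run_orig = -1, run_new = -1, run_len = 0;
  int nsub = 0;
  for (int i = 0; i < n; ++i) {
    // insertion before base i
    while (unif_rand() < p_ins) {
      if (run_len > 0) {
        r_orig.push_back(run_orig); r_new.push_back(run_new); r_len.push_back(run_len);
        run_len = 0;
      }
      out.push_back(BASES[(int)(unif_rand() * 4) & 3]);
    }
    if (unif_rand() < p_del) {
      if (run_len > 0) {
        r_orig.push_back(run_orig); r_new.push_back(run_new); r_len.push_back(run_len);
        run_len = 0;
      }
      continue;
    }
    char base = seq[i];
    if (unif_rand() < p_sub) {
      char nb = base;
      while (nb == base) nb = BASES[(int)(unif_rand() * 4) & 3];
      base = nb;
      ++nsub;
    }
    if (run_len == 0) { run_orig = i; run_new = out.size(); }
    out.push_back(base);
    ++run_len;
  }
  if (run_len > 0) {
    r_orig.push_back(run_orig); r_new.push_back(run_new); r_len.push_back(run_len);
  }
  IntegerMatrix map(r_orig.size(), 3);
  for (size_t k = 0; k < r_orig.size(); ++k) {
    map(k, 0) = r_orig[k]; map(k, 1) = r_new[k]; map(k, 2) = r_len[k];
  }
  colnames(map) = CharacterVector::create("orig_start", "new_start", "length");
  return List::create(_["seq"] = out, _["map"] = map, _["n_sub"] = nsub);
}

// ---------------------------------------------------------------------------
// Partial-order alignment consensus
// ---------------------------------------------------------------------------

struct PoaGraph {
  std::vector<char> base;
  std::vector<std::vector<int>> preds;          // predecessor node ids
  std::vector<std::vector<int>> pred_w;         // traversal counts per pred edge
  std::vector<int> start_w, end_w;              // virtual source/sink edge weights

  int add_node(char b) {
    base.push_back(b);
    preds.emplace_back();
    pred_w.emplace_back();
    start_w.push_back(0);
    end_w.push_back(0);
    return (int)base.size() - 1;
  }
  void add_edge(int from, int to) {
    for (size_t k = 0; k < preds[to].size(); ++k) {
      if (preds[to][k] == from) { ++pred_w[to][k]; return; }
    }
    preds[to].push_back(from);
    pred_w[to].push_back(1);
  }
  size_t size() const { return base.size(); }

  // Kahn topological order
  std::vector<int> topo() const {
    const int n = size();
    std::vector<int> indeg(n, 0), order;
    std::vector<std::vector<int>> succ(n);
    for (int v = 0; v < n; ++v)
      for (int p : preds[v]) { succ[p].push_back(v); ++indeg[v]; }
    std::vector<int> q;
    for (int v = 0; v < n; ++v) if (indeg[v] == 0) q.push_back(v);
    // deterministic: process smallest id first
    std::sort(q.begin(), q.end());
    while (!q.empty()) {
      int v = q.front(); q.erase(q.begin());
      order.push_back(v);
      for (int u : succ[v]) if (--indeg[u] == 0) {
        auto it = std::lower_bound(q.begin(), q.end(), u);
        q.insert(it, u);
      }
    }
    return order;
  }
};

// Fitting alignment of seq to graph (all of seq aligned; graph prefix/suffix
// free), then thread the read into the graph.
static void poa_add_read(PoaGraph& g, const std::string& seq,
                         int match, int mismatch, int gap) {
  const int m = seq.size();
  if (m == 0) return;
  if (g.size() == 0) {
    int prev = -1;
    for (int j = 0; j < m; ++j) {
      int v = g.add_node(seq[j]);
      if (prev >= 0) g.add_edge(prev, v);
      prev = v;
    }
    ++g.start_w[0];
    ++g.end_w[g.size() - 1];
    return;
  }
  std::vector<int> order = g.topo();
  const int n = order.size();
  std::vector<int> rank(g.size());
  for (int i = 0; i < n; ++i) rank[order[i]] = i;

  const int NEG = -1000000000;
  const size_t W = m + 1;
  // S[i*W+j]: best score aligning seq[0..j) with a path ending at node
  // order[i] (node consumed). j over 0..m.
  std::vector<int> Sf(n * W, NEG);
  // move code: 1 = diag, 2 = node skip (up), 3 = seq insertion (left)
  std::vector<signed char> mvf(n * W, -1);
  std::vector<int> prf(n * W, -2); // pred rank
  auto S = [&](int i, int j) -> int& { return Sf[i * W + j]; };
  auto mv = [&](int i, int j) -> signed char& { return mvf[i * W + j]; };
  auto pr = [&](int i, int j) -> int& { return prf[i * W + j]; };

  for (int i = 0; i < n; ++i) {
    int v = order[i];
    S(i, 0) = 0; mv(i, 0) = 2; pr(i, 0) = -1; // free graph prefix
    for (int j = 1; j <= m; ++j) {
      int s = (g.base[v] == seq[j - 1]) ? match : mismatch;
      int best = NEG, bmv = -1, bpr = -2;
      for (int p : g.preds[v]) {
        int rp = rank[p];
        int cand = S(rp, j - 1) + s;
        if (cand > best) { best = cand; bmv = 1; bpr = rp; }
        int skip = S(rp, j) + gap;
        if (skip > best) { best = skip; bmv = 2; bpr = rp; }
      }
      // read may start at any node (fitting: free graph prefix)
      if (j == 1) {
        int cand = 0 + s;
        if (cand > best) { best = cand; bmv = 1; bpr = -1; }
      }
      int ins = S(i, j - 1) + gap;
      if (ins > best) { best = ins; bmv = 3; bpr = i; }
      S(i, j) = best; mv(i, j) = bmv; pr(i, j) = bpr;
    }
  }
  // best end: max over nodes at j == m (free graph suffix)
  int bi = 0;
  for (int i = 1; i < n; ++i) if (S(i, m) > S(bi, m)) bi = i;

  // traceback -> for each seq pos, the node it maps to (or -1 => new node)
  std::vector<int> map_node(m, -1);
  int i = bi, j = m;
  while (j > 0) {
    int code = mv(i, j);
    if (code == 1) {
      int v = order[i];
      map_node[j - 1] = (g.base[v] == seq[j - 1]) ? v : -1;
      int p = pr(i, j);
      --j;
      if (p == -1) break; // read start
      i = p;
    } else if (code == 2) {
      i = pr(i, j);
      if (i < 0) break;
    } else { // 3: seq insertion
      map_node[j - 1] = -1;
      --j;
    }
  }
  // thread read
  int prev = -1;
  for (int k = 0; k < m; ++k) {
    int v = map_node[k];
    if (v < 0) v = g.add_node(seq[k]);
    if (prev >= 0) g.add_edge(prev, v);
    prev = v;
    if (k == 0) ++g.start_w[v];
  }
  ++g.end_w[prev];
}

static std::string poa_heaviest_path(const PoaGraph& g) {
  const int n = g.size();
  if (n == 0) return "";
  std::vector<int> order = g.topo();
  // successors with weights
  std::vector<std::vector<std::pair<int,int>>> succ(n); // (to, w)
  for (int v = 0; v < n; ++v)
    for (size_t k = 0; k < g.preds[v].size(); ++k)
      succ[g.preds[v][k]].push_back(std::make_pair(v, g.pred_w[v][k]));
  // W[v] = best weight from v to sink (including edge v->sink = end_w[v])
  std::vector<long long> W(n, 0);
  std::vector<int> nxt(n, -1);
  for (int idx = n - 1; idx >= 0; --idx) {
    int v = order[idx];
    long long best = g.end_w[v];
    int bn = -1; // -1 = stop at sink; on ties the shorter (lexicographically
                 // smaller) path wins, so a tie with the sink keeps bn = -1
    for (auto& e : succ[v]) {
      long long cand = (long long)e.second + W[e.first];
      bool take = cand > best;
      if (!take && cand == best && bn >= 0) {
        take = g.base[e.first] < g.base[bn] ||
               (g.base[e.first] == g.base[bn] && e.first < bn);
      }
      if (take) { best = cand; bn = e.first; }
    }
    W[v] = best; nxt[v] = bn;
  }
  // start: best source edge
  long long best = -1; int bv = -1;
  for (int v = 0; v < n; ++v) {
    if (g.start_w[v] == 0) continue;
    long long cand = (long long)g.start_w[v] + W[v];
    if (cand > best ||
        (cand == best && bv >= 0 &&
         (g.base[v] < g.base[bv] || (g.base[v] == g.base[bv] && v < bv)))) {
      best = cand; bv = v;
    }
  }
  std::string out;
  for (int v = bv; v >= 0; v = nxt[v]) out.push_back(g.base[v]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_poa_consensus(std::vector<std::string> seqs,
                              int match, int mismatch, int gap) {
  PoaGraph g;
  for (const auto& s : seqs) poa_add_read(g, s, match, mismatch, gap);
  return poa_heaviest_path(g);
}

// ---------------------------------------------------------------------------
// Batched preprocessing scans
// ---------------------------------------------------------------------------

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      case 'a': c = 't'; break; case 'c': c = 'g'; break;
      case 'g': c = 'c'; break; case 't': c = 'a'; break;
      default: c = 'N';
    }
  }
  return out;
}

// score-only Smith-Waterman with two rolling rows (no traceback)
static int sw_score_only(const std::string& a, const std::string& b,
                         int match, int mismatch, int gap,
                         std::vector<int>& prev, std::vector<int>& cur) {
  const int n = a.size(), m = b.size();
  if ((int)prev.size() < m + 1) { prev.resize(m + 1); cur.resize(m + 1); }
  std::fill(prev.begin(), prev.begin() + m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int h = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      int up = prev[j] + gap;
      if (up > h) h = up;
      int left = cur[j - 1] + gap;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

// true when pattern and text share an exact k-mer (the seed requirement of a
// tiled aligner: without a seed the local alignment is never scored)
static bool has_seed(const std::string& pattern, const std::string& text,
                     int k) {
  if ((int)pattern.size() < k) return false;
  for (size_t i = 0; i + k <= pattern.size(); ++i) {
    if (text.find(pattern.substr(i, k)) != std::string::npos) return true;
  }
  return false;
}

// Local-alignment scores of every index against the terminal windows of every
// read (both read orientations), gated by an exact 11-mer seed as in a tiled
// aligner. Returns, per read: the best-scoring index, its score, the number
// of indexes reaching min_score, and the trim coordinates of the best match
// on the forward read.
// [[Rcpp::export]]
List cpp_demux_scan(CharacterVector reads, CharacterVector indexes,
                    int match, int mismatch, int gap,
                    int window, int min_score, int seed_len = 11) {
  const int nr = reads.size(), ni = indexes.size();
  std::vector<std::string> idx(ni), idx_rc(ni);
  for (int k = 0; k < ni; ++k) {
    idx[k] = as<std::string>(indexes[k]);
    idx_rc[k] = revcomp_str(idx[k]);
  }
  IntegerVector best_idx(nr), best_score(nr), n_hits(nr);
  IntegerVector trim_start(nr), trim_end(nr);
  std::vector<int> r1, r2; // rolling DP rows, reused across calls
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    int len = s.size();
    int w = std::min(window, len);
    std::string head = s.substr(0, w);
    std::string tail = s.substr(len - w);
    int bscore = 0, bidx = -1, hits = 0, bwhere = 0, brc = 0;
    for (int k = 0; k < ni; ++k) {
      int sc = 0, where = 0, rc = 0;
      int v;
      if (has_seed(idx[k], head, seed_len)) {
        v = sw_score_only(idx[k], head, match, mismatch, gap, r1, r2);
        if (v > sc) { sc = v; where = 0; rc = 0; }
      }
      if (has_seed(idx_rc[k], head, seed_len)) {
        v = sw_score_only(idx_rc[k], head, match, mismatch, gap, r1, r2);
        if (v > sc) { sc = v; where = 0; rc = 1; }
      }
      if (has_seed(idx[k], tail, seed_len)) {
        v = sw_score_only(idx[k], tail, match, mismatch, gap, r1, r2);
        if (v > sc) { sc = v; where = 1; rc = 0; }
      }
      if (has_seed(idx_rc[k], tail, seed_len)) {
        v = sw_score_only(idx_rc[k], tail, match, mismatch, gap, r1, r2);
        if (v > sc) { sc = v; where = 1; rc = 1; }
      }
      if (sc >= min_score) ++hits;
      if (sc > bscore) { bscore = sc; bidx = k; bwhere = where; brc = rc; }
    }
    int bts = 0, bte = 0;
    if (bidx >= 0) {
      // full alignment once, for the winning combination only
      const std::string& pat = brc ? idx_rc[bidx] : idx[bidx];
      IntegerVector hit = cpp_smith_waterman(
        pat, bwhere == 0 ? head : tail, match, mismatch, gap);
      if (bwhere == 0) { bts = hit[3]; bte = hit[4]; }
      else { bts = len - w + hit[3]; bte = len - w + hit[4]; }
    }
    best_idx[r] = bidx + 1; // 1-based, 0 = none
    best_score[r] = bscore;
    n_hits[r] = hits;
    trim_start[r] = bts; trim_end[r] = bte;
  }
  return List::create(_["best_index"] = best_idx, _["best_score"] = best_score,
                      _["n_hits"] = n_hits, _["trim_start"] = trim_start,
                      _["trim_end"] = trim_end);
}

// Scan both read orientations for a 5' adaptor in the head window and a 3'
// adaptor in the tail window; pick the orientation with more adaptors found
// (tie: lower total distance, then forward). Coordinates returned are on the
// chosen orientation's sequence, 0-based half-open.
// [[Rcpp::export]]
List cpp_adaptor_scan(CharacterVector reads, std::string adaptor5,
                      std::string adaptor3, int window, int max_dist) {
  const int nr = reads.size();
  IntegerVector orient(nr), d5(nr), s5(nr), e5(nr), d3(nr), s3(nr), e3(nr);
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp_str(fwd);
    int len = fwd.size();
    int w = std::min(window, len);
    int bestor = 0;
    int bd5[2], bs5[2], be5[2], bd3[2], bs3[2], be3[2];
    for (int o = 0; o < 2; ++o) {
      const std::string& s = (o == 0) ? fwd : rev;
      IntegerVector h = cpp_edit_locate(adaptor5, s.substr(0, w));
      IntegerVector t = cpp_edit_locate(adaptor3, s.substr(len - w));
      bd5[o] = h[0]; bs5[o] = h[1]; be5[o] = h[2];
      bd3[o] = t[0]; bs3[o] = t[1] + len - w; be3[o] = t[2] + len - w;
    }
    int f0 = (bd5[0] <= max_dist) + (bd3[0] <= max_dist);
    int f1 = (bd5[1] <= max_dist) + (bd3[1] <= max_dist);
    if (f1 > f0 || (f1 == f0 && bd5[1] + bd3[1] < bd5[0] + bd3[0])) bestor = 1;
    orient[r] = bestor;
    d5[r] = bd5[bestor]; s5[r] = bs5[bestor]; e5[r] = be5[bestor];
    d3[r] = bd3[bestor]; s3[r] = bs3[bestor]; e3[r] = be3[bestor];
  }
  return List::create(_["orient"] = orient, _["d5"] = d5, _["s5"] = s5,
                      _["e5"] = e5, _["d3"] = d3, _["s3"] = s3, _["e3"] = e3);
}
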