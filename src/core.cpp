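#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

struct Ops {
  // run-length encoded edit script relative to (query, target)
  std::string ops;  // one char per base-level operation: = X I D
};

static std::string rle_cigar(const std::string &ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

static const int BIG = 1 << 28;

static int parse_int(const std::string &s, size_t from, size_t to) {
  int v = 0;
  for (size_t k = from; k < to; ++k) v = v * 10 + (s[k] - '0');
  return v;
}

// Banded global (Needleman-Wunsch, unit costs) between a and b.
// Band is centered on the proportional diagonal. band <= 0 => full DP.
// Returns per-base ops string; empty on failure (band exhausted -- cannot
// happen when band covers corners).
static bool banded_global(const std::string &a, const std::string &b,
                          int band, std::string &ops_out) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band <= 0) band = std::max(n, m);
  band = std::max(band, std::abs(n - m) + 1);
  const int W = 2 * band + 1;
  std::vector<int> lo(n + 1), cur(W), prev(W);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  for (int i = 0; i <= n; ++i) {
    int center = (n == 0) ? 0 : (int)(((long long)i * m) / n);
    lo[i] = std::max(0, center - band);
  }
  // row 0
  for (int w = 0; w < W; ++w) {
    int j = lo[0] + w;
    prev[w] = (j <= m) ? j : BIG;
    if (j <= m) tb[w] = 3;  // left (D)
  }
  for (int i = 1; i <= n; ++i) {
    for (int w = 0; w < W; ++w) cur[w] = BIG;
    int jlo = lo[i], jhi = std::min(m, lo[i] + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - jlo;
      int best = BIG; uint8_t move = 0;
      // diag first: ties prefer (mis)matches for consistent indel placement
      if (j >= 1) {
        int wd = j - 1 - lo[i - 1];
        if (wd >= 0 && wd < W && prev[wd] < BIG) {
          int v = prev[wd] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (v < best) { best = v; move = 1; }
        }
      }
      // up: (i-1, j)
      int wp = j - lo[i - 1];
      if (wp >= 0 && wp < W && prev[wp] < BIG) {
        int v = prev[wp] + 1;
        if (v < best) { best = v; move = 2; }
      }
      // left: (i, j-1)
      if (j >= 1) {
        int wl = j - 1 - jlo;
        if (wl >= 0 && cur[wl] < BIG) {
          int v = cur[wl] + 1;
          if (v < best) { best = v; move = 3; }
        }
      }
      cur[w] = best;
      tb[(size_t)i * W + w] = move;
    }
    std::swap(cur, prev);
  }
  // traceback from (n, m)
  int wm = m - lo[n];
  if (wm < 0 || wm >= W || prev[wm] >= BIG) return false;
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t move = tb[(size_t)i * W + (j - lo[i])];
    if (move == 1) { ops += (a[i - 1] == b[j - 1]) ? '=' : 'X'; --i; --j; }
    else if (move == 2) { ops += 'I'; --i; }
    else if (move == 3) { ops += 'D'; --j; }
    else return false;
  }
  std::reverse(ops.begin(), ops.end());
  ops_out = ops;
  return true;
}

struct AlnStats { int nmatch, nmis, nins, ndel, alen, qlen, tlen; };

static AlnStats ops_stats(const std::string &ops, size_t from, size_t to) {
  AlnStats s = {0, 0, 0, 0, 0, 0, 0};
  for (size_t k = from; k < to; ++k) {
    switch (ops[k]) {
      case '=': ++s.nmatch; ++s.qlen; ++s.tlen; break;
      case 'X': ++s.nmis; ++s.qlen; ++s.tlen; break;
      case 'I': ++s.nins; ++s.qlen; break;
      case 'D': ++s.ndel; ++s.tlen; break;
    }
  }
  s.alen = (int)(to - from);
  return s;
}

// Best-scoring contiguous sub-path of a global alignment (match +1, else -2);
// extracts the local core from a global path. Returns [from, to) into ops.
static bool kadane_trim(const std::string &ops, size_t &from, size_t &to) {
  long best = 0, run = 0; size_t run_start = 0; best = -1; from = to = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    long sc = (ops[k] == '=') ? 1 : -2;
    if (run <= 0) { run = sc; run_start = k; }
    else run += sc;
    if (run > best) { best = run; from = run_start; to = k + 1; }
  }
  // trim non-match edges (kadane already ends on '=' by optimality)
  while (from < to && ops[from] != '=') ++from;
  while (to > from && ops[to - 1] != '=') --to;
  return best > 0 && to > from;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, int band) {
  std::string ops;
  if (!banded_global(a, b, band, ops)) return List::create(Named("ok") = false);
  AlnStats s = ops_stats(ops, 0, ops.size());
  return List::create(
    Named("ok") = true, Named("cigar") = rle_cigar(ops),
    Named("nmatch") = s.nmatch, Named("alen") = s.alen,
    Named("edit") = s.nmis + s.nins + s.ndel,
    Named("qbeg") = 0, Named("qend") = (int)a.size(),
    Named("tbeg") = 0, Named("tend") = (int)b.size());
}

// Semi-global ("infix"): all of a aligned, free ends on b. Full DP.
// [[Rcpp::export]]
List cpp_align_infix(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) prev[j] = 0;  // free start in target
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int best = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      uint8_t move = 1;
      if (prev[j] + 1 < best) { best = prev[j] + 1; move = 2; }
      if (cur[j - 1] + 1 < best) { best = cur[j - 1] + 1; move = 3; }
      cur[j] = best; tb[(size_t)i * (m + 1) + j] = move;
    }
    std::swap(prev, cur);
  }
  int jbest = 0;
  for (int j = 1; j <= m; ++j) if (prev[j] < prev[jbest]) jbest = j;
  std::string ops;
  int i = n, j = jbest;
  while (i > 0) {
    uint8_t move = tb[(size_t)i * (m + 1) + j];
    if (move == 1) { ops += (a[i - 1] == b[j - 1]) ? '=' : 'X'; --i; --j; }
    else if (move == 2) { ops += 'I'; --i; }
    else { ops += 'D'; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  AlnStats s = ops_stats(ops, 0, ops.size());
  return List::create(
    Named("ok") = true, Named("cigar") = rle_cigar(ops),
    Named("nmatch") = s.nmatch, Named("alen") = s.alen,
    Named("edit") = prev[jbest],
    Named("qbeg") = 0, Named("qend") = n,
    Named("tbeg") = j, Named("tend") = jbest);
}

// ---------------------------------------------------------------------------
// Seed-and-extend local alignment (forward strand only; wrapper handles '-')
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
               case 'T': return 3; default: return -1; }
}

// [[Rcpp::export]]
List cpp_align_local(std::string a, std::string b, int k, int min_len,
                     double max_err, int min_seeds, int max_occ) {
  const int n = (int)a.size(), m = (int)b.size();
  List out;
  if (n < k || m < k) return out;
  // index b k-mers
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve(m);
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int j = 0; j < m; ++j) {
    int c = base_code(b[j]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask; ++valid;
    if (valid >= k) idx[key].push_back(j - k + 1);
  }
  // seeds
  std::vector<std::pair<int,int> > seeds;  // (diag, posA)
  key = 0; valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(a[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask; ++valid;
    if (valid >= k) {
      auto it = idx.find(key);
      if (it != idx.end() && (int)it->second.size() <= max_occ) {
        int pa = i - k + 1;
        for (int pb : it->second) seeds.push_back({pa - pb, pa});
      }
    }
  }
  if (seeds.empty()) return out;
  std::sort(seeds.begin(), seeds.end());
  const int diag_tol = 100, posa_gap = 3000;
  // cluster by diagonal, then by position
  std::vector<std::pair<size_t,size_t> > dgroups;
  size_t s0 = 0;
  for (size_t s = 1; s <= seeds.size(); ++s) {
    if (s == seeds.size() || seeds[s].first - seeds[s - 1].first > diag_tol) {
      dgroups.push_back({s0, s}); s0 = s;
    }
  }
  for (auto &g : dgroups) {
    std::vector<std::pair<int,int> > grp(seeds.begin() + g.first,
                                         seeds.begin() + g.second);
    std::sort(grp.begin(), grp.end(),
              [](const std::pair<int,int> &x, const std::pair<int,int> &y) {
                return x.second < y.second; });
    size_t c0 = 0;
    for (size_t s = 1; s <= grp.size(); ++s) {
      if (s == grp.size() || grp[s].second - grp[s - 1].second > posa_gap) {
        if ((int)(s - c0) >= min_seeds) {
          int aLo = grp[c0].second, aHi = grp[s - 1].second + k;
          int dmin = grp[c0].first, dmax = grp[c0].first;
          for (size_t t = c0; t < s; ++t) {
            dmin = std::min(dmin, grp[t].first);
            dmax = std::max(dmax, grp[t].first);
          }
          int bLo = aLo - dmax, bHi = aHi - dmin;
          // extension beyond the outermost seeds: enough to absorb the
          // unseeded flanks at the stated error ceiling. Both sequences are
          // padded by identical amounts so the proportional DP diagonal
          // stays aligned with the seed diagonal.
          int pad = 300 + (int)(0.12 * (aHi - aLo));
          int padL = std::min(pad, std::min(aLo, std::max(0, bLo)));
          int padR = std::min(pad, std::min(n - aHi, m - std::max(0, bHi)));
          padR = std::max(padR, 0);
          int a0 = aLo - padL, a1 = std::min(n, aHi + padR);
          int b0 = std::max(0, bLo - padL), b1 = std::min(m, bHi + padR);
          // indel drift between seeds is bounded by the seed diagonal
          // spread; the band needs that plus slack for the padding
          int band = (dmax - dmin) + std::max(192, pad / 2) + 64;
          std::string sub_a = a.substr(a0, a1 - a0);
          std::string sub_b = b.substr(b0, b1 - b0);
          std::string ops;
          if (banded_global(sub_a, sub_b, band, ops)) {
            size_t from, to;
            if (kadane_trim(ops, from, to)) {
              AlnStats pre = ops_stats(ops, 0, from);
              AlnStats s2 = ops_stats(ops, from, to);
              double err = (double)(s2.nmis + s2.nins + s2.ndel) / s2.alen;
              if (s2.alen >= min_len && err <= max_err) {
                out.push_back(List::create(
                  Named("qbeg") = a0 + pre.qlen,
                  Named("qend") = a0 + pre.qlen + s2.qlen,
                  Named("tbeg") = b0 + pre.tlen,
                  Named("tend") = b0 + pre.tlen + s2.tlen,
                  Named("nmatch") = s2.nmatch, Named("alen") = s2.alen,
                  Named("cigar") = rle_cigar(ops.substr(from, to - from))));
              }
            }
          }
        }
        c0 = s;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Low-complexity (SDUST-style triplet score) masking
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_dust(std::string seq, int window, double threshold) {
  const int n = (int)seq.size();
  std::vector<std::pair<int,int> > hits;
  if (n >= 3) {
    std::vector<int> tri(n - 2, -1);
    for (int i = 0; i + 2 < n; ++i) {
      int c0 = base_code(seq[i]), c1 = base_code(seq[i + 1]),
          c2 = base_code(seq[i + 2]);
      if (c0 >= 0 && c1 >= 0 && c2 >= 0) tri[i] = (c0 << 4) | (c1 << 2) | c2;
    }
    int ntri = (int)tri.size();
    std::vector<int> cnt(64, 0);
    long long pairs = 0;  // sum over t of c_t*(c_t-1)/2
    int wtri = std::max(1, window - 2);
    int lo = 0;
    for (int hi = 0; hi < ntri; ++hi) {
      int t = tri[hi];
      if (t >= 0) { pairs += cnt[t]; cnt[t]++; }
      if (hi - lo + 1 > wtri) {
        int u = tri[lo];
        if (u >= 0) { cnt[u]--; pairs -= cnt[u]; }
        ++lo;
      }
      int len = hi - lo + 1;
      if (len >= std::min(wtri, ntri)) {
        double denom = std::max(1, len - 1);
        if ((double)pairs / denom > threshold)
          hits.push_back({lo, hi + 3});  // mask window incl. trailing bases
      }
    }
  }
  // merge
  std::vector<std::pair<int,int> > merged;
  for (auto &h : hits) {
    if (!merged.empty() && h.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, h.second);
    else merged.push_back(h);
  }
  IntegerMatrix res((int)merged.size(), 2);
  for (int i = 0; i < (int)merged.size(); ++i) {
    res(i, 0) = merged[i].first; res(i, 1) = merged[i].second;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Tandem-repeat masking: self-match at period p <= max_period, windowed
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_tandem(std::string seq, int max_period, int min_len,
                         double min_frac) {
  const int n = (int)seq.size();
  std::vector<std::pair<int,int> > hits;
  for (int p = 1; p <= max_period && p < n; ++p) {
    int len = n - p;
    if (len < min_len) break;
    // windowed fraction of positions with seq[i] == seq[i+p]
    int wsum = 0;
    for (int i = 0; i < len; ++i) {
      wsum += (seq[i] == seq[i + p]) ? 1 : 0;
      if (i >= min_len) wsum -= (seq[i - min_len] == seq[i - min_len + p]) ? 1 : 0;
      if (i >= min_len - 1 && wsum >= min_frac * min_len) {
        hits.push_back({i - min_len + 1, i + 1 + p});
      }
    }
  }
  std::sort(hits.begin(), hits.end());
  std::vector<std::pair<int,int> > merged;
  for (auto &h : hits) {
    if (!merged.empty() && h.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, h.second);
    else merged.push_back(h);
  }
  IntegerMatrix res((int)merged.size(), 2);
  for (int i = 0; i < (int)merged.size(); ++i) {
    res(i, 0) = merged[i].first; res(i, 1) = merged[i].second;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Column-voting consensus over reference-read coordinates
// ---------------------------------------------------------------------------

static bool expand_cigar(const std::string &cigar, std::string &ops) {
  size_t i = 0;
  while (i < cigar.size()) {
    size_t j = i;
    while (j < cigar.size() && isdigit(cigar[j])) ++j;
    if (j == i || j >= cigar.size()) return false;
    int len = parse_int(cigar, i, j);
    char op = cigar[j];
    if (op == 'M') op = '=';  // treated as match-ish; callers use =/X
    ops.append(len, op);
    i = j + 1;
  }
  return true;
}

// reads[0] must be the reference read aligned to itself (identity cigar).
// tbeg[r]: start of read r's alignment on the reference read; cigar relative
// to (query = read r sequence as given, target = reference read).
// [[Rcpp::export]]
std::string cpp_consensus(int ref_len, CharacterVector seqs,
                          IntegerVector tbegs, IntegerVector qbegs,
                          CharacterVector cigars, int window, int step) {
  const int R = seqs.size();
  // per-read column strings over [tbeg, tend)
  std::vector<int> tb(R), te(R);
  std::vector<std::vector<std::string> > cols(R);
  for (int r = 0; r < R; ++r) {
    std::string seq = as<std::string>(seqs[r]);
    std::string ops; expand_cigar(as<std::string>(cigars[r]), ops);
    int t = tbegs[r], q = qbegs[r];
    tb[r] = t;
    std::vector<std::string> c;
    for (char op : ops) {
      if (op == '=' || op == 'X') { c.push_back(std::string(1, seq[q])); ++q; ++t; }
      else if (op == 'D') { c.push_back(""); ++t; }
      else if (op == 'I') {
        if (!c.empty()) c.back() += seq[q];
        ++q;  // leading insertions dropped
      }
    }
    te[r] = t;
    cols[r] = std::move(c);
  }
  auto col_at = [&](int r, int pos) -> const std::string * {
    if (pos < tb[r] || pos >= te[r]) return nullptr;
    return &cols[r][pos - tb[r]];
  };
  std::string consensus;
  consensus.reserve(ref_len + ref_len / 10);
  // plurality consensus per position; tie -> reference read (r = 0)
  auto plurality = [&](int pos) -> std::string {
    std::vector<std::pair<std::string,int> > counts;
    for (int r = 0; r < R; ++r) {
      const std::string *s = col_at(r, pos);
      if (!s) continue;
      bool found = false;
      for (auto &cv : counts) if (cv.first == *s) { cv.second++; found = true; break; }
      if (!found) counts.push_back({*s, 1});
    }
    if (counts.empty()) return "";
    int best = 0;
    for (int i = 1; i < (int)counts.size(); ++i)
      if (counts[i].second > counts[best].second) best = i;
    // tie-break toward the reference read's column, else lexicographic
    const std::string *ref = col_at(0, pos);
    for (int i = 0; i < (int)counts.size(); ++i) {
      if (counts[i].second == counts[best].second && i != best) {
        if (ref && counts[i].first == *ref) { best = i; }
        else if (!(ref && counts[best].first == *ref) &&
                 counts[i].first < counts[best].first) best = i;
      }
    }
    return counts[best].first;
  };
  for (int s = 0; s < ref_len; s += step) {
    int wend = std::min(s + window, ref_len);
    int own_end = (s + step >= ref_len || wend == ref_len) ? ref_len
                                                          : std::min(s + step, ref_len);
    // exact-match window voting among fully covering reads
    int ncov = 0, winner = -1;
    std::vector<std::string> wstr(R);
    std::vector<bool> covers(R, false);
    for (int r = 0; r < R; ++r) {
      if (tb[r] <= s && te[r] >= wend) {
        covers[r] = true; ++ncov;
        std::string w;
        for (int p = s; p < wend; ++p) w += cols[r][p - tb[r]];
        wstr[r] = w;
      }
    }
    if (ncov >= 2) {
      for (int r = 0; r < R && winner < 0; ++r) {
        if (!covers[r]) continue;
        int cnt = 0;
        for (int r2 = 0; r2 < R; ++r2)
          if (covers[r2] && wstr[r2] == wstr[r]) ++cnt;
        if (cnt * 2 > ncov) winner = r;
      }
    }
    for (int p = s; p < own_end; ++p) {
      if (winner >= 0) consensus += *col_at(winner, p);
      else consensus += plurality(p);
    }
    if (own_end == ref_len) break;
  }
  return consensus;
}

// ---------------------------------------------------------------------------
// CIGAR expansion helper for R-side projection
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cigar_runs(std::string cigar) {
  std::vector<int> lens; std::vector<std::string> ops;
  size_t i = 0;
  while (i < cigar.size()) {
    size_t j = i;
    while (j < cigar.size() && isdigit(cigar[j])) ++j;
    if (j == i || j >= cigar.size()) stop("malformed CIGAR: %s", cigar.c_str());
    lens.push_back(parse_int(cigar, i, j));
    ops.push_back(std::string(1, cigar[j]));
    i = j + 1;
  }
  return List::create(Named("op") = ops, Named("len") = lens);
}
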