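#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// Partial-order alignment consensus for a pile-up of co-oriented reads.
// Reads are integrated one by one into a DAG whose nodes carry base and
// support weight; matched bases fuse (per-column bookkeeping so recurring
// alternatives accumulate), and the consensus is the heaviest edge bundle.
// The read-to-graph alignment is banded around each node's running position
// estimate. Linear gap costs; scores favour indels over mismatches, fitting
// the indel-dominant long-read error profile.

namespace {

struct Poa {
  std::vector<char> base;
  std::vector<int> weight;
  std::vector<double> pos;                 // running mean read offset
  std::vector<std::vector<int> > preds;
  std::vector<int> col;                    // column id per node
  std::vector<std::vector<int> > columns;  // column id -> node ids
  std::unordered_map<uint64_t, int> ew;    // (pred<<32|node) -> edge weight

  int add_node(char b, double p, int column) {
    base.push_back(b);
    weight.push_back(1);
    pos.push_back(p);
    preds.push_back({});
    if (column < 0) {
      column = (int)columns.size();
      columns.push_back({});
    }
    col.push_back(column);
    columns[column].push_back((int)base.size() - 1);
    return (int)base.size() - 1;
  }

  void add_edge(int p, int v) {
    if (p < 0 || p == v) return;
    uint64_t key = ((uint64_t)p << 32) | (uint32_t)v;
    auto it = ew.find(key);
    if (it == ew.end()) {
      ew[key] = 1;
      preds[v].push_back(p);
    } else {
      it->second++;
    }
  }

  int edge_weight(int p, int v) const {
    auto it = ew.find(((uint64_t)p << 32) | (uint32_t)v);
    return it == ew.end() ? 0 : it->second;
  }

  std::vector<int> topo_order() const {
    int n = (int)base.size();
    std::vector<int> indeg(n, 0), order;
    std::vector<std::vector<int> > succs(n);
    for (int v = 0; v < n; ++v)
      for (int p : preds[v]) { succs[p].push_back(v); indeg[v]++; }
    std::vector<int> q;
    for (int v = 0; v < n; ++v) if (!indeg[v]) q.push_back(v);
    // stable order: lower node id first
    std::sort(q.begin(), q.end());
    order.reserve(n);
    size_t head = 0;
    while (head < q.size()) {
      int v = q[head++];
      order.push_back(v);
      for (int s : succs[v]) if (--indeg[s] == 0) q.push_back(s);
    }
    return order;
  }
};

const int NEG = -(1 << 28);
static int SC_MATCH = 2, SC_MISMATCH = -3, SC_GAP = -2;

}  // namespace

static void poa_seed(Poa &g, const std::string &seq) {
  int last = -1;
  for (size_t j = 0; j < seq.size(); ++j) {
    int v = g.add_node(seq[j], (double)j, -1);
    g.add_edge(last, v);
    last = v;
  }
}

static void poa_add(Poa &g, const std::string &seq, int band, int offset) {
  const int L = (int)seq.size();
  const int n = (int)g.base.size();
  std::vector<int> order = g.topo_order();
  // band window per node; `offset` is the estimated graph position of the
  // read's first base (nonzero for extension reads covering a sub-region)
  std::vector<int> jlo(n), jhi(n);
  for (int v = 0; v < n; ++v) {
    int c = (int)g.pos[v] - offset;
    jlo[v] = std::max(0, std::min(L, c - band));
    jhi[v] = std::min(L, std::max(0, c + band));
  }
  std::vector<std::vector<int> > S(n);
  std::vector<std::vector<uint8_t> > M(n);
  for (int v = 0; v < n; ++v) {
    S[v].assign(jhi[v] - jlo[v] + 1, NEG);
    M[v].assign(jhi[v] - jlo[v] + 1, 255);
  }
  auto sget = [&](int v, int j) -> int {
    if (j < jlo[v] || j > jhi[v]) return NEG;
    return S[v][j - jlo[v]];
  };
  // moves: 0..62 diag from preds[k]; 63 diag from virtual start;
  //        64+k del from preds[k]; 128 ins; 255 none
  for (int oi = 0; oi < n; ++oi) {
    int v = order[oi];
    for (int j = jlo[v]; j <= jhi[v]; ++j) {
      int best = NEG; uint8_t move = 255;
      if (j >= 1) {
        int sub = (g.base[v] == seq[j - 1]) ? SC_MATCH : SC_MISMATCH;
        // path start at v: leading j-1 read bases count as insertions
        int cand = sub + SC_GAP * (j - 1);
        if (cand > best) { best = cand; move = 63; }
        for (size_t k = 0; k < g.preds[v].size() && k < 62; ++k) {
          int p = g.preds[v][k];
          int s = sget(p, j - 1);
          if (s > NEG && s + sub > best) { best = s + sub; move = (uint8_t)k; }
        }
        // insertion: read base j-1 unaligned, stay at v
        int si = sget(v, j - 1);
        if (si > NEG && si + SC_GAP > best) { best = si + SC_GAP; move = 128; }
      }
      // deletion: consume v without read base
      for (size_t k = 0; k < g.preds[v].size() && k < 62; ++k) {
        int p = g.preds[v][k];
        int s = sget(p, j);
        if (s > NEG && s + SC_GAP > best) { best = s + SC_GAP; move = 64 + (uint8_t)k; }
      }
      if (j <= jhi[v] && j >= jlo[v]) {
        S[v][j - jlo[v]] = best;
        M[v][j - jlo[v]] = move;
      }
    }
  }
  // best end over all nodes at j = L (free graph suffix)
  int bestv = -1, bests = NEG;
  for (int v = 0; v < n; ++v) {
    int s = sget(v, L);
    if (s > bests) { bests = s; bestv = v; }
  }
  if (bestv < 0) return;  // band failure: read skipped
  // traceback: collect (type, node, readpos) from end to start
  struct Step { uint8_t type; int node; int j; };  // type 0 diag, 1 del, 2 ins
  std::vector<Step> steps;
  int v = bestv, j = L;
  while (v >= 0 && j >= 0) {
    uint8_t move = (j >= jlo[v] && j <= jhi[v]) ? M[v][j - jlo[v]] : 255;
    if (move == 255) break;
    if (move == 63) { steps.push_back({0, v, j - 1}); j -= 1; v = -1; break; }
    if (move < 62) {
      steps.push_back({0, v, j - 1});
      v = g.preds[v][move]; j -= 1;
    } else if (move >= 64 && move < 128) {
      steps.push_back({1, v, j});
      v = g.preds[v][move - 64];
    } else if (move == 128) {
      steps.push_back({2, v, j - 1});
      j -= 1;
    } else break;
  }
  std::reverse(steps.begin(), steps.end());
  int lead = steps.empty() ? L : steps.front().j;  // leading unaligned bases
  int last = -1;
  // leading read bases before the path start become a fresh chain
  for (int jj = 0; jj < lead; ++jj) {
    int nv = g.add_node(seq[jj], (double)(jj + offset), -1);
    g.add_edge(last, nv);
    last = nv;
  }
  int consumed = lead;
  for (auto &st : steps) {
    if (st.type == 1) continue;  // deletion: graph node skipped
    char b = seq[st.j];
    int u = -1;
    bool created = false;
    if (st.type == 0) {
      if (g.base[st.node] == b) {
        u = st.node;
      } else {
        // fuse with an existing alternative of this column, if any
        for (int cand : g.columns[g.col[st.node]])
          if (g.base[cand] == b && cand != last) { u = cand; break; }
        if (u < 0) { u = g.add_node(b, (double)(st.j + offset),
                                    g.col[st.node]);
                     created = true; }
      }
      if (!created) {
        g.weight[u]++;
        g.pos[u] += ((double)(st.j + offset) - g.pos[u]) / g.weight[u];
      }
    } else {  // insertion: new node between last and next
      u = g.add_node(b, (double)(st.j + offset), -1);
    }
    g.add_edge(last, u);
    last = u;
    consumed = st.j + 1;
  }
  // trailing unaligned read bases
  for (int jj = consumed; jj < L; ++jj) {
    int nv = g.add_node(seq[jj], (double)(jj + offset), -1);
    g.add_edge(last, nv);
    last = nv;
  }
}

static std::string poa_consensus_path(const Poa &g) {
  std::vector<int> order = g.topo_order();
  int n = (int)g.base.size();
  // choose, per node, the strongest incoming edge (ties: higher upstream
  // score, then lower id); score accumulates along chosen edges only.
  std::vector<long> dp(n, 0);
  std::vector<int> from(n, -1);
  long best = -1; int bestv = -1;
  for (int v : order) {
    int bw = 0; long bdp = -1; int bp = -1;
    for (int p : g.preds[v]) {
      int w = g.edge_weight(p, v);
      // ties: better-supported predecessor node (prunes weakly supported
      // insertion detours), then higher upstream score, then lower id
      bool take = w > bw;
      if (!take && w == bw && bp >= 0) {
        if (g.weight[p] != g.weight[bp]) take = g.weight[p] > g.weight[bp];
        else if (dp[p] != bdp) take = dp[p] > bdp;
        else take = p < bp;
      }
      if (take || bp < 0) { bw = w; bdp = dp[p]; bp = p; }
    }
    if (bp >= 0) { dp[v] = dp[bp] + bw; from[v] = bp; }
    if (dp[v] > best) { best = dp[v]; bestv = v; }
  }
  std::string out;
  int v = bestv;
  while (v >= 0) { out += g.base[v]; v = from[v]; }
  std::reverse(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
std::string cpp_poa_consensus(CharacterVector seqs, IntegerVector offsets,
                              int band_extra, int sc_match, int sc_mismatch,
                              int sc_gap) {
  SC_MATCH = sc_match; SC_MISMATCH = sc_mismatch; SC_GAP = sc_gap;
  Poa g;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (i == 0) poa_seed(g, s);
    else {
      int band = band_extra + (int)(0.1 * s.size());
      poa_add(g, s, band, offsets[i]);
    }
  }
  return poa_consensus_path(g);
}
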