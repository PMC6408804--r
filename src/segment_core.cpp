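#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Flat segment tree representation shared with the R side (all ids 1-based,
// 0 = absent):
//   node_low, node_high : Int(v), inclusive coordinates
//   left, right         : child ids
//   depth               : distance from root (root = 0)
//   root, height        : root id, max leaf depth
//   canon_ptr, canon_idx: CSR of canonical subsets I(v); canon_idx holds
//                         1-based rows of the input interval table, in
//                         insertion (= input) order per node
//   n_stored            : sum over nodes of |I(v)| (total attachments)

// [[Rcpp::export(name = ".st_build")]]
List st_build(IntegerVector low, IntegerVector high) {
  const int n = low.size();
  if (n == 0) {
    return List::create(
      _["node_low"] = IntegerVector(0), _["node_high"] = IntegerVector(0),
      _["left"] = IntegerVector(0), _["right"] = IntegerVector(0),
      _["depth"] = IntegerVector(0), _["root"] = 0, _["height"] = 0,
      _["n_leaves"] = 0, _["canon_ptr"] = IntegerVector::create(1),
      _["canon_idx"] = IntegerVector(0), _["n_stored"] = 0,
      _["n_intervals"] = 0);
  }

  // distinct endpoints
  std::vector<int> ep;
  ep.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    if (low[i] > high[i]) stop("interval with low > high");
    ep.push_back(low[i]);
    ep.push_back(high[i]);
  }
  std::sort(ep.begin(), ep.end());
  ep.erase(std::unique(ep.begin(), ep.end()), ep.end());
  const int m = (int) ep.size();

  // elementary intervals: [p_i,p_i] plus, when non-empty, (p_i,p_{i+1}) as
  // the integer range [p_i+1, p_{i+1}-1]
  std::vector<int> lo, hi, lc, rc;
  for (int i = 0; i < m; ++i) {
    lo.push_back(ep[i]); hi.push_back(ep[i]);
    lc.push_back(0); rc.push_back(0);
    if (i + 1 < m && ep[i + 1] > ep[i] + 1) {
      lo.push_back(ep[i] + 1); hi.push_back(ep[i + 1] - 1);
      lc.push_back(0); rc.push_back(0);
    }
  }
  const int n_leaves = (int) lo.size();

  // bottom-up pairing, left to right; a leftover node is promoted unchanged
  std::vector<int> cur(n_leaves);
  for (int i = 0; i < n_leaves; ++i) cur[i] = i + 1;  // 1-based ids
  while (cur.size() > 1) {
    std::vector<int> nxt;
    size_t i = 0;
    for (; i + 1 < cur.size(); i += 2) {
      int a = cur[i], b = cur[i + 1];
      lo.push_back(lo[a - 1]); hi.push_back(hi[b - 1]);
      lc.push_back(a); rc.push_back(b);
      nxt.push_back((int) lo.size());
    }
    if (i < cur.size()) nxt.push_back(cur[i]);
    cur = nxt;
  }
  const int root = cur[0];
  const int nn = (int) lo.size();

  // depths from root; height = max leaf depth
  std::vector<int> dep(nn, 0);
  {
    std::vector<int> st;
    st.push_back(root);
    dep[root - 1] = 0;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      if (lc[v - 1]) { dep[lc[v - 1] - 1] = dep[v - 1] + 1; st.push_back(lc[v - 1]); }
      if (rc[v - 1]) { dep[rc[v - 1] - 1] = dep[v - 1] + 1; st.push_back(rc[v - 1]); }
    }
  }
  int height = 0;
  for (int v = 0; v < nn; ++v)
    if (!lc[v] && dep[v] > height) height = dep[v];

  // insert intervals: attach at the highest nodes whose Int(v) the interval
  // fully contains; descend into overlapping children otherwise
  std::vector<int> pair_node, pair_iv;
  pair_node.reserve(2 * n);
  pair_iv.reserve(2 * n);
  std::vector<int> st;
  for (int k = 0; k < n; ++k) {
    const int l = low[k], h = high[k];
    st.clear();
    st.push_back(root);
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      if (l <= lo[v - 1] && hi[v - 1] <= h) {
        pair_node.push_back(v);
        pair_iv.push_back(k + 1);
      } else {
        // push right first so left is processed first (cosmetic; per-node
        // order is fixed by the outer input order anyway)
        int r = rc[v - 1], lft = lc[v - 1];
        if (r && lo[r - 1] <= h && l <= hi[r - 1]) st.push_back(r);
        if (lft && lo[lft - 1] <= h && l <= hi[lft - 1]) st.push_back(lft);
      }
    }
  }

  // CSR over nodes, preserving generation order within each node
  const int np = (int) pair_node.size();
  IntegerVector canon_ptr(nn + 1), canon_idx(np);
  std::vector<int> cnt(nn, 0);
  for (int i = 0; i < np; ++i) cnt[pair_node[i] - 1]++;
  canon_ptr[0] = 1;
  for (int v = 0; v < nn; ++v) canon_ptr[v + 1] = canon_ptr[v] + cnt[v];
  std::vector<int> fill(nn, 0);
  for (int i = 0; i < np; ++i) {
    int v = pair_node[i] - 1;
    canon_idx[canon_ptr[v] - 1 + fill[v]++] = pair_iv[i];
  }

  return List::create(
    _["node_low"] = IntegerVector(lo.begin(), lo.end()),
    _["node_high"] = IntegerVector(hi.begin(), hi.end()),
    _["left"] = IntegerVector(lc.begin(), lc.end()),
    _["right"] = IntegerVector(rc.begin(), rc.end()),
    _["depth"] = IntegerVector(dep.begin(), dep.end()),
    _["root"] = root, _["height"] = height, _["n_leaves"] = n_leaves,
    _["canon_ptr"] = canon_ptr, _["canon_idx"] = canon_idx,
    _["n_stored"] = np, _["n_intervals"] = n);
}

// stabbing queries: one root-to-leaf walk each; every interval in a visited
// node's canonical subset contains Int(v) and hence the query point
// [[Rcpp::export(name = ".st_query_points")]]
List st_query_points(List tree, IntegerVector q) {
  IntegerVector lo = tree["node_low"], hi = tree["node_high"];
  IntegerVector lc = tree["left"], rc = tree["right"];
  IntegerVector cp = tree["canon_ptr"], ci = tree["canon_idx"];
  const int root = tree["root"];
  const int nq = q.size();
  List hits(nq);
  IntegerVector visits(nq);
  for (int j = 0; j < nq; ++j) {
    std::vector<int> out;
    int vis = 0;
    if (root) {
      int v = root;
      const int x = q[j];
      if (x >= lo[v - 1] && x <= hi[v - 1]) {
        while (v) {
          ++vis;
          for (int t = cp[v - 1]; t < cp[v]; ++t) out.push_back(ci[t - 1]);
          int l = lc[v - 1], r = rc[v - 1];
          if (l && x >= lo[l - 1] && x <= hi[l - 1]) v = l;
          else if (r && x >= lo[r - 1] && x <= hi[r - 1]) v = r;
          else v = 0;
        }
      }
    }
    hits[j] = IntegerVector(out.begin(), out.end());
    visits[j] = vis;
  }
  return List::create(_["hits"] = hits, _["visits"] = visits);
}

// subtree interval query used by both the full tree (from = root) and the
// forest's short trees; results deduplicated per query via stamps
static void subtree_query(const int *lo, const int *hi, const int *lc,
                          const int *rc, const int *cp, const int *ci,
                          int from, int ql, int qh, int qstamp,
                          std::vector<int> &stamp, std::vector<int> &out,
                          int &visits) {
  std::vector<int> st;
  if (!from) return;
  if (!(lo[from - 1] <= qh && ql <= hi[from - 1])) return;
  st.push_back(from);
  while (!st.empty()) {
    int v = st.back(); st.pop_back();
    ++visits;
    for (int t = cp[v - 1]; t < cp[v]; ++t) {
      int g = ci[t - 1];
      if (stamp[g - 1] != qstamp) { stamp[g - 1] = qstamp; out.push_back(g); }
    }
    int l = lc[v - 1], r = rc[v - 1];
    if (r && lo[r - 1] <= qh && ql <= hi[r - 1]) st.push_back(r);
    if (l && lo[l - 1] <= qh && ql <= hi[l - 1]) st.push_back(l);
  }
}

// [[Rcpp::export(name = ".st_query_intervals")]]
List st_query_intervals(List tree, IntegerVector qlo, IntegerVector qhi) {
  IntegerVector lo = tree["node_low"], hi = tree["node_high"];
  IntegerVector lc = tree["left"], rc = tree["right"];
  IntegerVector cp = tree["canon_ptr"], ci = tree["canon_idx"];
  const int root = tree["root"];
  const int nint = tree["n_intervals"];
  const int nq = qlo.size();
  std::vector<int> stamp(nint, 0);
  std::vector<int> qid, iid;
  IntegerVector visits(nq);
  for (int j = 0; j < nq; ++j) {
    std::vector<int> out;
    int vis = 0;
    subtree_query(lo.begin(), hi.begin(), lc.begin(), rc.begin(),
                  cp.begin(), ci.begin(), root, qlo[j], qhi[j], j + 1,
                  stamp, out, vis);
    for (size_t t = 0; t < out.size(); ++t) { qid.push_back(j + 1); iid.push_back(out[t]); }
    visits[j] = vis;
  }
  return List::create(
    _["qid"] = IntegerVector(qid.begin(), qid.end()),
    _["iid"] = IntegerVector(iid.begin(), iid.end()),
    _["visits"] = visits);
}

// Convert a segment tree into the indexed forest. `cutoff` is decided on the
// R side (root-relative depth). Forest members are the nodes at the cut-off
// depth plus childless nodes above it, in left-to-right coordinate order.
// Attachments above the cut-off are relocated to every member in their
// node's subtree; relocation lists live in a CSR parallel to `members`.
// [[Rcpp::export(name = ".istf_build")]]
List istf_build(List tree, int cutoff, int preset) {
  IntegerVector lo = tree["node_low"], hi = tree["node_high"];
  IntegerVector lc = tree["left"], rc = tree["right"];
  IntegerVector dep = tree["depth"];
  IntegerVector cp = tree["canon_ptr"], ci = tree["canon_idx"];
  const int root = tree["root"];
  const int nn = lo.size();
  if (preset <= 0) stop("preset must be a positive integer");
  if (!root) {
    return List::create(
      _["cutoff"] = 0, _["members"] = IntegerVector(0),
      _["member_low"] = IntegerVector(0), _["member_high"] = IntegerVector(0),
      _["hidx"] = IntegerVector(0), _["bucket_idx"] = IntegerVector(0),
      _["bucket_start"] = IntegerVector(0), _["bucket_end"] = IntegerVector(0),
      _["bst_height"] = IntegerVector(0),
      _["reloc_ptr"] = IntegerVector::create(1),
      _["reloc_idx"] = IntegerVector(0),
      _["moved_attachments"] = 0, _["placed_copies"] = 0);
  }

  std::vector<char> is_member(nn, 0);
  std::vector<int> members;
  {
    // left-to-right DFS, stopping at members
    std::vector<int> st;
    st.push_back(root);
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      bool member = (dep[v - 1] == cutoff) ||
                    (dep[v - 1] < cutoff && lc[v - 1] == 0);
      if (member) {
        is_member[v - 1] = 1;
        members.push_back(v);
      } else {
        // right first so the left child pops first
        if (rc[v - 1]) st.push_back(rc[v - 1]);
        if (lc[v - 1]) st.push_back(lc[v - 1]);
      }
    }
  }
  const int nm = (int) members.size();
  std::vector<int> mpos(nn, 0);  // node id -> 1-based member position
  for (int i = 0; i < nm; ++i) mpos[members[i] - 1] = i + 1;

  // relocate attachments stored above the cut-off at internal non-members
  std::vector<std::vector<int> > reloc(nm);
  int moved = 0;
  long long placed = 0;
  // sources in (depth, low) order keeps receiving lists deterministic:
  // shallower donors first, ties left to right
  std::vector<int> sources;
  for (int v = 1; v <= nn; ++v)
    if (!is_member[v - 1] && dep[v - 1] < cutoff && cp[v] > cp[v - 1])
      sources.push_back(v);
  std::sort(sources.begin(), sources.end(), [&](int a, int b) {
    if (dep[a - 1] != dep[b - 1]) return dep[a - 1] < dep[b - 1];
    return lo[a - 1] < lo[b - 1];
  });
  std::vector<int> st, sub;
  for (size_t s = 0; s < sources.size(); ++s) {
    int v = sources[s];
    sub.clear();
    st.clear();
    st.push_back(v);
    while (!st.empty()) {
      int u = st.back(); st.pop_back();
      if (is_member[u - 1]) sub.push_back(mpos[u - 1]);
      else {
        if (rc[u - 1]) st.push_back(rc[u - 1]);
        if (lc[u - 1]) st.push_back(lc[u - 1]);
      }
    }
    std::sort(sub.begin(), sub.end());
    for (int t = cp[v - 1]; t < cp[v]; ++t) {
      ++moved;
      for (size_t u = 0; u < sub.size(); ++u) {
        reloc[sub[u] - 1].push_back(ci[t - 1]);
        ++placed;
      }
    }
  }
  IntegerVector reloc_ptr(nm + 1), reloc_idx((int) placed);
  reloc_ptr[0] = 1;
  for (int i = 0; i < nm; ++i) {
    reloc_ptr[i + 1] = reloc_ptr[i] + (int) reloc[i].size();
    for (size_t t = 0; t < reloc[i].size(); ++t)
      reloc_idx[reloc_ptr[i] - 1 + (int) t] = reloc[i][t];
  }

  // hash indexes are non-decreasing along the member order, so buckets are
  // contiguous runs; a balanced BST over each run is summarised by its height
  // (single node = height 1, artificial routing nodes above the members)
  IntegerVector member_low(nm), member_high(nm), hidx(nm);
  for (int i = 0; i < nm; ++i) {
    member_low[i] = lo[members[i] - 1];
    member_high[i] = hi[members[i] - 1];
    hidx[i] = member_low[i] / preset;
  }
  std::vector<int> b_idx, b_start, b_end, b_h;
  int i = 0;
  while (i < nm) {
    int j = i;
    while (j + 1 < nm && hidx[j + 1] == hidx[i]) ++j;
    int k = j - i + 1;
    b_idx.push_back(hidx[i]);
    b_start.push_back(i + 1);
    b_end.push_back(j + 1);
    int h = 1;                       // height of the median-split BST on k
    for (int c = k; c > 1; c = (c + 1) / 2) ++h;
    b_h.push_back(h);
    i = j + 1;
  }

  return List::create(
    _["cutoff"] = cutoff,
    _["members"] = IntegerVector(members.begin(), members.end()),
    _["member_low"] = member_low, _["member_high"] = member_high,
    _["hidx"] = hidx,
    _["bucket_idx"] = IntegerVector(b_idx.begin(), b_idx.end()),
    _["bucket_start"] = IntegerVector(b_start.begin(), b_start.end()),
    _["bucket_end"] = IntegerVector(b_end.begin(), b_end.end()),
    _["bst_height"] = IntegerVector(b_h.begin(), b_h.end()),
    _["reloc_ptr"] = reloc_ptr, _["reloc_idx"] = reloc_idx,
    _["moved_attachments"] = moved, _["placed_copies"] = (double) placed);
}

// rightmost position with key <= x in keys[s..e] (1-based, sorted); 0 if none
static int right_le(const IntegerVector &keys, int s, int e, int x) {
  int res = 0;
  while (s <= e) {
    int mid = (s + e) / 2;
    if (keys[mid - 1] <= x) { res = mid; s = mid + 1; }
    else e = mid - 1;
  }
  return res;
}

// Resolve the starting linked node for a forest query via the index cascade:
// lowIndex bucket, else the highest occupied index below it, else the
// highIndex bucket, else the lowest occupied index above it; a final
// fallback (highest occupied index <= highIndex) covers queries spanning
// past both ends of the forest. Returns the 1-based member position and a
// branch code 1..5 (0 = no candidate).
static int cascade_start(const IntegerVector &bidx, const IntegerVector &bs,
                         const IntegerVector &be, const IntegerVector &mlow,
                         int li, int hj, int qlo, int *branch) {
  const int nb = bidx.size();
  *branch = 0;
  if (nb == 0) return 0;
  int p = right_le(bidx, 1, nb, li);
  if (p && bidx[p - 1] == li) {           // lowIndex bucket exists
    *branch = 1;
    int r = right_le(mlow, bs[p - 1], be[p - 1], qlo);
    return r ? r : bs[p - 1];
  }
  if (p) {                                 // lowerIndex: highest index < li
    *branch = 2;
    int r = right_le(mlow, bs[p - 1], be[p - 1], qlo);
    return r ? r : bs[p - 1];
  }
  int q = right_le(bidx, 1, nb, hj);
  if (q && bidx[q - 1] == hj) {            // highIndex bucket exists
    *branch = 3;
    return bs[q - 1];
  }
  if (q < nb) {                            // higherIndex: lowest index > hj
    *branch = 4;
    return bs[q];
  }
  if (q) {                                 // interior fallback (see docs)
    *branch = 5;
    return bs[q - 1];
  }
  return 0;
}

// [[Rcpp::export(name = ".istf_lookup")]]
List istf_lookup(List forest, int qlo, int qhi, int preset) {
  IntegerVector bidx = forest["bucket_idx"], bs = forest["bucket_start"],
                be = forest["bucket_end"], mlow = forest["member_low"];
  int branch = 0;
  int pos = cascade_start(bidx, bs, be, mlow, qlo / preset, qhi / preset,
                          qlo, &branch);
  return List::create(_["pos"] = pos, _["branch"] = branch);
}

// [[Rcpp::export(name = ".istf_query_intervals")]]
List istf_query_intervals(List tree, List forest, IntegerVector qlo,
                          IntegerVector qhi, int preset) {
  IntegerVector lo = tree["node_low"], hi = tree["node_high"];
  IntegerVector lc = tree["left"], rc = tree["right"];
  IntegerVector cp = tree["canon_ptr"], ci = tree["canon_idx"];
  const int nint = tree["n_intervals"];
  IntegerVector members = forest["members"], mlow = forest["member_low"],
                mhigh = forest["member_high"], hidx = forest["hidx"],
                bidx = forest["bucket_idx"], bs = forest["bucket_start"],
                be = forest["bucket_end"], rp = forest["reloc_ptr"],
                ri = forest["reloc_idx"];
  const int nm = members.size();
  const int nq = qlo.size();
  std::vector<int> stamp(nint, 0);
  std::vector<int> qid, iid;
  IntegerVector extra(nq), visits(nq);

  for (int j = 0; j < nq; ++j) {
    const int ql = qlo[j], qh = qhi[j];
    const int li = ql / preset, hj = qh / preset;
    int branch = 0, vis = 0, xtra = 0;
    std::vector<int> out;
    int pos = nm ? cascade_start(bidx, bs, be, mlow, li, hj, ql, &branch) : 0;

    if (pos) {
      // members partition the tree span, so the overlapping ones form one
      // contiguous run; slide to it from the cascade's start, then expand
      auto visit_member = [&](int p) {
        if (hidx[p - 1] < li || hidx[p - 1] > hj) ++xtra;
        int f = members[p - 1];
        subtree_query(lo.begin(), hi.begin(), lc.begin(), rc.begin(),
                      cp.begin(), ci.begin(), f, ql, qh, j + 1, stamp, out,
                      vis);
        // relocated attachments contain the whole member span, so any query
        // overlapping Int(f) overlaps them
        if (lo[f - 1] <= qh && ql <= hi[f - 1]) {
          for (int t = rp[p - 1]; t < rp[p]; ++t) {
            int g = ri[t - 1];
            if (stamp[g - 1] != j + 1) { stamp[g - 1] = j + 1; out.push_back(g); }
          }
        }
      };
      auto overlaps = [&](int p) {
        return mlow[p - 1] <= qh && ql <= mhigh[p - 1];
      };
      auto step_over = [&](int p) {
        if (hidx[p - 1] < li || hidx[p - 1] > hj) ++xtra;
      };
      int p = pos;
      if (mlow[p - 1] > qh) {
        // start lies right of the query: slide left to the run's right end
        while (p >= 1 && mlow[p - 1] > qh) { step_over(p); --p; }
        if (p >= 1 && mhigh[p - 1] < ql) p = 0;
      } else if (mhigh[p - 1] < ql) {
        // start lies left of the query: slide right to the run's left end
        while (p <= nm && mhigh[p - 1] < ql) { step_over(p); ++p; }
        if (p > nm || mlow[p - 1] > qh) p = 0;
      }
      if (p >= 1) {
        int pl = p;
        while (pl >= 1 && overlaps(pl)) { visit_member(pl); --pl; }
        int pr = p + 1;
        while (pr <= nm && overlaps(pr)) { visit_member(pr); ++pr; }
      }
    }
    for (size_t t = 0; t < out.size(); ++t) { qid.push_back(j + 1); iid.push_back(out[t]); }
    extra[j] = xtra;
    visits[j] = vis;
  }
  return List::create(
    _["qid"] = IntegerVector(qid.begin(), qid.end()),
    _["iid"] = IntegerVector(iid.begin(), iid.end()),
    _["extra"] = extra, _["visits"] = visits);
}
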