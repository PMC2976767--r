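#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Constrained SPR hill-climb with exact incremental rescoring.
//
// Scoring uses unit-cost Sankoff vectors (4 states), which equal Fitch
// counts on binary trees. For each pruned subtree x the context vectors of
// the remaining tree are recomputed once, after which every regraft target
// costs O(4) per site pattern. Candidate targets are restricted to the
// smallest constraint clade properly containing the pruned tips (moves
// outside it cannot stay compatible); accepted moves are verified against
// the full clade list. The SPR neighbourhood on a rooted binary tree
// includes all NNI rearrangements.

static const int INF = 1 << 28;

struct Tree {
  std::vector<int> parent;              // 1-based, 0 = root
  int ntip, M;
  std::vector<std::vector<int> > kids;
  std::vector<int> post;                // postorder
  int root;

  void rebuild(int forced_root = 0) {
    M = parent.size();
    kids.assign(M + 1, std::vector<int>());
    for (int v = 1; v <= M; ++v) {
      int p = parent[v - 1];
      if (p != 0) kids[p].push_back(v);
    }
    root = forced_root;
    if (root == 0) {
      for (int v = 1; v <= M; ++v) {
        if (parent[v - 1] == 0 && !kids[v].empty()) { root = v; break; }
      }
    }
    post.clear();
    std::vector<std::pair<int, size_t> > st;
    st.push_back(std::make_pair(root, (size_t)0));
    while (!st.empty()) {
      int v = st.back().first;
      size_t i = st.back().second;
      if (i < kids[v].size()) {
        ++st.back().second;
        st.push_back(std::make_pair(kids[v][i], (size_t)0));
      } else {
        post.push_back(v);
        st.pop_back();
      }
    }
  }
};

// per-clade membership counts below every node; clade present iff some
// node's subtree equals it exactly
static bool check_refinement(const Tree& T,
                             const std::vector<std::vector<int> >& clades,
                             const std::vector<int>& clade_sizes) {
  int M = T.M, ntip = T.ntip;
  std::vector<int> tot(M + 1, 0);
  for (size_t k = 0; k < T.post.size(); ++k) {
    int v = T.post[k];
    if (v <= ntip) tot[v] = 1;
    else for (size_t c = 0; c < T.kids[v].size(); ++c) tot[v] += tot[T.kids[v][c]];
  }
  std::vector<char> member(ntip + 1);
  std::vector<int> cnt(M + 1);
  for (size_t ci = 0; ci < clades.size(); ++ci) {
    int len = clade_sizes[ci];
    if (len <= 1 || len >= ntip) continue;
    std::fill(member.begin(), member.end(), 0);
    for (int i = 0; i < len; ++i) member[clades[ci][i]] = 1;
    bool found = false;
    for (size_t k = 0; k < T.post.size() && !found; ++k) {
      int v = T.post[k];
      if (v <= ntip) cnt[v] = member[v];
      else {
        int s = 0;
        for (size_t c = 0; c < T.kids[v].size(); ++c) s += cnt[T.kids[v][c]];
        cnt[v] = s;
        if (s == len && tot[v] == len) found = true;
      }
    }
    if (!found) return false;
  }
  return true;
}

// Sankoff down-pass vectors for the whole tree; D is (M+1) x npat x 4
static void down_pass(const Tree& T, const IntegerMatrix& states,
                      std::vector<int>& D, int npat) {
  for (size_t k = 0; k < T.post.size(); ++k) {
    int v = T.post[k];
    int* dv = &D[((size_t)v) * npat * 4];
    if (v <= T.ntip) {
      for (int s = 0; s < npat; ++s) {
        int mask = states(s, v - 1);
        if (mask <= 0 || mask > 15) mask = 15;
        for (int a = 0; a < 4; ++a)
          dv[s * 4 + a] = (mask & (1 << a)) ? 0 : INF;
      }
    } else {
      for (int s = 0; s < npat * 4; ++s) dv[s] = 0;
      for (size_t c = 0; c < T.kids[v].size(); ++c) {
        const int* dc = &D[((size_t)T.kids[v][c]) * npat * 4];
        for (int s = 0; s < npat; ++s) {
          int m = std::min(std::min(dc[s * 4], dc[s * 4 + 1]),
                           std::min(dc[s * 4 + 2], dc[s * 4 + 3]));
          for (int a = 0; a < 4; ++a)
            dv[s * 4 + a] += std::min(dc[s * 4 + a], m + 1);
        }
      }
    }
  }
}

static double root_score(const Tree& T, const std::vector<int>& D, int npat,
                         const IntegerVector& w) {
  const int* dr = &D[((size_t)T.root) * npat * 4];
  double sc = 0;
  for (int s = 0; s < npat; ++s) {
    int m = std::min(std::min(dr[s * 4], dr[s * 4 + 1]),
                     std::min(dr[s * 4 + 2], dr[s * 4 + 3]));
    sc += (double)m * w[s];
  }
  return sc;
}

// [[Rcpp::export]]
List spr_hillclimb_cpp(IntegerVector parent0, int ntip, IntegerMatrix states,
                       IntegerVector weights, List clades_r) {
  Tree T;
  T.parent.assign(parent0.begin(), parent0.end());
  T.ntip = ntip;
  T.rebuild();
  int M = T.M;
  int npat = states.nrow();

  std::vector<std::vector<int> > clades;
  std::vector<int> clade_sizes;
  for (int i = 0; i < clades_r.size(); ++i) {
    IntegerVector cl = clades_r[i];
    clades.push_back(std::vector<int>(cl.begin(), cl.end()));
    clade_sizes.push_back(cl.size());
  }
  // sort clades by size ascending for min-containing lookup
  std::vector<int> corder(clades.size());
  for (size_t i = 0; i < corder.size(); ++i) corder[i] = i;
  std::sort(corder.begin(), corder.end(), [&](int a, int b) {
    return clade_sizes[a] < clade_sizes[b];
  });

  std::vector<int> D((size_t)(M + 1) * npat * 4);
  std::vector<int> A((size_t)(M + 1) * npat * 4);
  std::vector<int> Dtil((size_t)(M + 1) * npat * 4);

  bool improved_any = true;
  double cur;
  down_pass(T, states, D, npat);
  cur = root_score(T, D, npat, weights);

  std::vector<int> tot(M + 1), depth(M + 1);
  std::vector<std::vector<int> > cmember;  // membership per clade
  cmember.assign(clades.size(), std::vector<int>());
  for (size_t ci = 0; ci < clades.size(); ++ci) {
    cmember[ci].assign(ntip + 1, 0);
    for (size_t i = 0; i < clades[ci].size(); ++i)
      cmember[ci][clades[ci][i]] = 1;
  }
  std::vector<std::vector<int> > ccnt(clades.size());

  while (improved_any) {
    improved_any = false;
    down_pass(T, states, D, npat);
    cur = root_score(T, D, npat, weights);

    // subtree tip totals and clade counts per node
    for (size_t k = 0; k < T.post.size(); ++k) {
      int v = T.post[k];
      tot[v] = (v <= ntip) ? 1 : 0;
      if (v > ntip)
        for (size_t c = 0; c < T.kids[v].size(); ++c) tot[v] += tot[T.kids[v][c]];
    }
    for (size_t ci = 0; ci < clades.size(); ++ci) {
      ccnt[ci].assign(M + 1, 0);
      for (size_t k = 0; k < T.post.size(); ++k) {
        int v = T.post[k];
        if (v <= ntip) ccnt[ci][v] = cmember[ci][v];
        else for (size_t c = 0; c < T.kids[v].size(); ++c)
          ccnt[ci][v] += ccnt[ci][T.kids[v][c]];
      }
    }

    for (int x = 1; x <= M && !improved_any; ++x) {
      int p = T.parent[x - 1];
      if (p == 0) continue;
      if (T.parent[p - 1] == 0) continue;  // parent is root: cannot splice
      int g = T.parent[p - 1];
      int sib = -1;
      for (size_t c = 0; c < T.kids[p].size(); ++c)
        if (T.kids[p][c] != x) sib = T.kids[p][c];

      // smallest constraint clade properly containing tips(x)
      int anchor = 0;  // 0 = unconstrained (whole tree)
      for (size_t q = 0; q < corder.size(); ++q) {
        int ci = corder[q];
        if (clade_sizes[ci] <= tot[x]) continue;
        if (ccnt[ci][x] == tot[x]) {
          // find the node whose subtree equals this clade
          for (int v = ntip + 1; v <= M; ++v) {
            if (tot[v] == clade_sizes[ci] && ccnt[ci][v] == clade_sizes[ci] &&
                T.parent[v - 1] != 0) { anchor = v; break; }
          }
          if (anchor == 0) {
            // clade node is the root (or absent): unconstrained region
            anchor = T.root;
          }
          break;
        }
      }
      if (anchor == 0) anchor = T.root;

      // build T' = T without subtree(x), p spliced out
      Tree Tp = T;
      Tp.parent[sib - 1] = g;
      Tp.parent[p - 1] = 0;
      Tp.parent[x - 1] = 0;
      // detach subtree of x: it stays internally linked but unreachable
      Tp.rebuild(T.root);
      if (Tp.root == x || Tp.root == p) continue;  // degenerate

      // down vectors for T': only ancestors of p change; recompute all for
      // simplicity of the A pass (single O(M npat) sweep)
      down_pass(Tp, states, Dtil, npat);

      // context vectors A on T': A[root] = 0; child v of P with sibling w:
      // A[v][s] = prime over sp of (D'[w][sp] + A[P][sp])
      {
        int* ar = &A[((size_t)Tp.root) * npat * 4];
        for (int s = 0; s < npat * 4; ++s) ar[s] = 0;
      }
      // preorder = reverse postorder
      for (size_t k = Tp.post.size(); k-- > 0;) {
        int P = Tp.post[k];
        if (P <= ntip || Tp.kids[P].empty()) continue;
        if (Tp.kids[P].size() != 2) continue;  // binary trees only
        int a = Tp.kids[P][0], b = Tp.kids[P][1];
        const int* AP = &A[((size_t)P) * npat * 4];
        for (int pass = 0; pass < 2; ++pass) {
          int v = pass == 0 ? a : b;
          int w = pass == 0 ? b : a;
          const int* dw = &Dtil[((size_t)w) * npat * 4];
          int* av = &A[((size_t)v) * npat * 4];
          for (int s = 0; s < npat; ++s) {
            int B[4], mB = INF;
            for (int st = 0; st < 4; ++st) {
              int dwp;
              {
                int m = std::min(std::min(dw[s * 4], dw[s * 4 + 1]),
                                 std::min(dw[s * 4 + 2], dw[s * 4 + 3]));
                dwp = std::min(dw[s * 4 + st], m + 1);
              }
              B[st] = dwp + AP[s * 4 + st];
              if (B[st] < mB) mB = B[st];
            }
            for (int st = 0; st < 4; ++st)
              av[s * 4 + st] = std::min(B[st], mB + 1);
          }
        }
      }

      // pruned-subtree root vector, primed
      std::vector<int> XP(npat * 4);
      {
        const int* dx = &D[((size_t)x) * npat * 4];
        for (int s = 0; s < npat; ++s) {
          int m = std::min(std::min(dx[s * 4], dx[s * 4 + 1]),
                           std::min(dx[s * 4 + 2], dx[s * 4 + 3]));
          for (int st = 0; st < 4; ++st)
            XP[s * 4 + st] = std::min(dx[s * 4 + st], m + 1);
        }
      }

      // candidate targets: descendants of anchor in T' (anchor itself
      // included: stem insertion), excluding T'-root, x's old position
      // (sib would recreate the same tree)
      std::vector<int> region;
      {
        std::vector<int> st;
        int start = (anchor == T.root) ? Tp.root : anchor;
        if (T.parent[anchor - 1] == 0) start = Tp.root;
        // anchor may have been spliced (anchor == p): fall back to root
        if (anchor == p) start = Tp.root;
        st.push_back(start);
        while (!st.empty()) {
          int v = st.back(); st.pop_back();
          region.push_back(v);
          for (size_t c = 0; c < Tp.kids[v].size(); ++c)
            st.push_back(Tp.kids[v][c]);
        }
      }

      for (size_t ri = 0; ri < region.size() && !improved_any; ++ri) {
        int y = region[ri];
        if (y == Tp.root || y == sib || y == x || y == p) continue;
        if (Tp.parent[y - 1] == 0) continue;
        // incremental score of attaching x above y
        const int* ay = &A[((size_t)y) * npat * 4];
        const int* dy = &Dtil[((size_t)y) * npat * 4];
        double sc = 0;
        for (int s = 0; s < npat; ++s) {
          int mdy = std::min(std::min(dy[s * 4], dy[s * 4 + 1]),
                             std::min(dy[s * 4 + 2], dy[s * 4 + 3]));
          int best = INF;
          for (int st = 0; st < 4; ++st) {
            int v = ay[s * 4 + st] + std::min(dy[s * 4 + st], mdy + 1) +
                    XP[s * 4 + st];
            if (v < best) best = v;
          }
          sc += (double)best * weights[s];
        }
        if (sc < cur - 1e-9) {
          // apply: reuse p as the new node above y
          Tree T2 = T;
          T2.parent[sib - 1] = g;
          T2.parent[p - 1] = T.parent[y - 1] == p ? g : T.parent[y - 1];
          if (y == sib) continue;
          T2.parent[y - 1] = p;
          T2.parent[x - 1] = p;
          T2.rebuild();
          if (!check_refinement(T2, clades, clade_sizes)) continue;
          T = T2;
          cur = sc;
          improved_any = true;
        }
      }
    }
  }

  return List::create(Named("parent") = IntegerVector(T.parent.begin(),
                                                      T.parent.end()),
                      Named("score") = cur);
}
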