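#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Nodes are 1-based: tips 1..ntip, internals ntip+1..M, parent[root-1] == 0.
// Trees may be multifurcating; scoring uses Hartigan's generalization of
// Fitch counting, which reduces to Fitch on binary nodes.

static void build_children(const IntegerVector& parent,
                           std::vector<std::vector<int> >& kids,
                           int& root) {
  int M = parent.size();
  kids.assign(M + 1, std::vector<int>());
  root = 0;
  for (int v = 1; v <= M; ++v) {
    int p = parent[v - 1];
    if (p == 0) root = v; else kids[p].push_back(v);
  }
  if (root == 0) stop("parent vector has no root (no zero entry)");
}

static void postorder_nodes(const std::vector<std::vector<int> >& kids,
                            int root, std::vector<int>& order) {
  // iterative DFS; children pushed in reverse so order matches recursion
  order.clear();
  std::vector<std::pair<int, size_t> > stack;
  stack.push_back(std::make_pair(root, (size_t)0));
  while (!stack.empty()) {
    int v = stack.back().first;
    size_t i = stack.back().second;
    if (i < kids[v].size()) {
      ++stack.back().second;
      stack.push_back(std::make_pair(kids[v][i], (size_t)0));
    } else {
      order.push_back(v);
      stack.pop_back();
    }
  }
}

// states: patterns x ntip matrix of IUPAC bitmasks (A=1, C=2, G=4, T=8,
// missing/'?'/'-' = 15). weights: per-pattern column multiplicities.
// [[Rcpp::export]]
double pars_score_cpp(IntegerVector parent, int ntip,
                      IntegerMatrix states, IntegerVector weights) {
  int M = parent.size();
  if (ntip < 1 || ntip > M) stop("bad tip count");
  std::vector<std::vector<int> > kids;
  int root;
  build_children(parent, kids, root);
  std::vector<int> post;
  postorder_nodes(kids, root, post);

  int npat = states.nrow();
  if (states.ncol() != ntip) stop("states must have one column per tip");
  if (weights.size() != npat) stop("weights length must match patterns");

  std::vector<int> set(M + 1);
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    int cost = 0;
    for (size_t k = 0; k < post.size(); ++k) {
      int v = post[k];
      if (v <= ntip) {
        int st = states(s, v - 1);
        set[v] = (st <= 0 || st > 15) ? 15 : st;
      } else {
        int cnt[4] = {0, 0, 0, 0};
        const std::vector<int>& ch = kids[v];
        for (size_t c = 0; c < ch.size(); ++c) {
          int b = set[ch[c]];
          if (b & 1) ++cnt[0];
          if (b & 2) ++cnt[1];
          if (b & 4) ++cnt[2];
          if (b & 8) ++cnt[3];
        }
        int m = cnt[0];
        for (int a = 1; a < 4; ++a) if (cnt[a] > m) m = cnt[a];
        int vs = 0;
        for (int a = 0; a < 4; ++a) if (cnt[a] == m) vs |= (1 << a);
        set[v] = vs;
        cost += (int)ch.size() - m;
      }
    }
    total += (double)cost * (double)weights[s];
  }
  return total;
}

// TRUE iff every clade (integer vector of tip ids) is the exact tip set of
// some node of the tree given by `parent` — i.e. the tree refines them all.
// [[Rcpp::export]]
bool is_refinement_cpp(IntegerVector parent, int ntip, List clades) {
  int M = parent.size();
  std::vector<std::vector<int> > kids;
  int root;
  build_children(parent, kids, root);
  std::vector<int> post;
  postorder_nodes(kids, root, post);

  // subtree tip totals
  std::vector<int> tot(M + 1, 0);
  for (size_t k = 0; k < post.size(); ++k) {
    int v = post[k];
    if (v <= ntip) tot[v] = 1;
    else for (size_t c = 0; c < kids[v].size(); ++c) tot[v] += tot[kids[v][c]];
  }

  std::vector<char> member(ntip + 1);
  std::vector<int> cnt(M + 1);
  for (int ci = 0; ci < clades.size(); ++ci) {
    IntegerVector cl = clades[ci];
    int len = cl.size();
    if (len <= 1 || len >= ntip) continue;  // trivial clades always hold
    std::fill(member.begin(), member.end(), 0);
    for (int i = 0; i < len; ++i) {
      int t = cl[i];
      if (t < 1 || t > ntip) stop("clade tip id out of range");
      member[t] = 1;
    }
    bool found = false;
    for (size_t k = 0; k < post.size() && !found; ++k) {
      int v = post[k];
      if (v <= ntip) cnt[v] = member[v];
      else {
        int s = 0;
        for (size_t c = 0; c < kids[v].size(); ++c) s += cnt[kids[v][c]];
        cnt[v] = s;
        if (s == len && tot[v] == len) found = true;
      }
    }
    if (!found) return false;
  }
  return true;
}

// Global profile-profile alignment with affine gaps (Gotoh).
// A, B: k x L frequency profiles (column sums in [0,1]; remainder = gap mass).
// S: k x k column score matrix. Penalties are positive magnitudes.
// Returns a 2 x Lout matrix: row 1 = source column in A (0 = gap),
// row 2 = source column in B (0 = gap); columns 1-based.
// [[Rcpp::export]]
IntegerMatrix nw_profile_cpp(NumericMatrix A, NumericMatrix B,
                             NumericMatrix S,
                             double gap_open, double gap_extend) {
  int k = A.nrow();
  if (B.nrow() != k || S.nrow() != k || S.ncol() != k)
    stop("profile/score dimensions disagree");
  int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e18;

  // occupancy (non-gap mass) per column scales substitution & gap scores so
  // that columns already rich in gaps are cheap to gap again
  std::vector<double> occA(la), occB(lb);
  for (int i = 0; i < la; ++i) {
    double s = 0; for (int a = 0; a < k; ++a) s += A(a, i);
    occA[i] = s;
  }
  for (int j = 0; j < lb; ++j) {
    double s = 0; for (int a = 0; a < k; ++a) s += B(a, j);
    occB[j] = s;
  }
  // SB[a][j] = sum_b S(a,b) * B(b,j)
  std::vector<double> SB((size_t)k * lb, 0.0);
  for (int j = 0; j < lb; ++j)
    for (int b = 0; b < k; ++b) {
      double f = B(b, j);
      if (f == 0) continue;
      for (int a = 0; a < k; ++a) SB[(size_t)a * lb + j] += S(a, b) * f;
    }

  size_t W = (size_t)lb + 1;
  std::vector<double> Mm(((size_t)la + 1) * W, NEG),
      Xm(((size_t)la + 1) * W, NEG), Ym(((size_t)la + 1) * W, NEG);
  // traceback: 0=M,1=X,2=Y ; store chosen predecessor state per cell/state
  std::vector<unsigned char> tbM(((size_t)la + 1) * W), tbX(((size_t)la + 1) * W),
      tbY(((size_t)la + 1) * W);

  Mm[0] = 0.0;
  {
    double g = 0;
    for (int i = 1; i <= la; ++i) {
      g -= occA[i - 1] * (i == 1 ? gap_open : gap_extend);
      Xm[(size_t)i * W] = g;
      tbX[(size_t)i * W] = 1;
    }
    g = 0;
    for (int j = 1; j <= lb; ++j) {
      g -= occB[j - 1] * (j == 1 ? gap_open : gap_extend);
      Ym[j] = g;
      tbY[j] = 2;
    }
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      size_t c = (size_t)i * W + j, d = (size_t)(i - 1) * W + (j - 1),
             u = (size_t)(i - 1) * W + j, l = (size_t)i * W + (j - 1);
      // substitution score of aligning column i of A with column j of B
      double sub = 0;
      for (int a = 0; a < k; ++a) {
        double f = A(a, i - 1);
        if (f != 0) sub += f * SB[(size_t)a * lb + (j - 1)];
      }
      double m0 = Mm[d], m1 = Xm[d], m2 = Ym[d];
      unsigned char t = 0; double best = m0;
      if (m1 > best) { best = m1; t = 1; }
      if (m2 > best) { best = m2; t = 2; }
      Mm[c] = best + sub; tbM[c] = t;

      // gap penalties scale with the occupancy of the column being gapped,
      // so columns that are mostly gaps already are cheap to gap again
      double wA = occA[i - 1], wB = occB[j - 1];
      double xo = Mm[u] - wA * gap_open, xy = Ym[u] - wA * gap_open,
             xe = Xm[u] - wA * gap_extend;
      t = 0; best = xo;
      if (xe > best) { best = xe; t = 1; }
      if (xy > best) { best = xy; t = 2; }
      Xm[c] = best; tbX[c] = t;

      double yo = Mm[l] - wB * gap_open, yx = Xm[l] - wB * gap_open,
             ye = Ym[l] - wB * gap_extend;
      t = 0; best = yo;
      if (yx > best) { best = yx; t = 1; }
      if (ye > best) { best = ye; t = 2; }
      Ym[c] = best; tbY[c] = t;
    }
  }

  size_t e = (size_t)la * W + lb;
  int state = 0; double best = Mm[e];
  if (Xm[e] > best) { best = Xm[e]; state = 1; }
  if (Ym[e] > best) { best = Ym[e]; state = 2; }

  std::vector<int> ca, cb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      int prev = tbM[c];
      ca.push_back(i); cb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[c];
      ca.push_back(i); cb.push_back(0); --i;
      state = (prev == 1) ? 1 : (prev == 2 ? 2 : 0);
    } else {
      int prev = tbY[c];
      ca.push_back(0); cb.push_back(j); --j;
      state = (prev == 1) ? 1 : (prev == 2 ? 2 : 0);
    }
  }
  int L = ca.size();
  IntegerMatrix out(2, L);
  for (int q = 0; q < L; ++q) {
    out(0, q) = ca[L - 1 - q];
    out(1, q) = cb[L - 1 - q];
  }
  return out;
}
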