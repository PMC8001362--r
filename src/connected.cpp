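#include <Rcpp.h>
using namespace Rcpp;

// Two-pass 8-connected component labeling with union-find.
// mask: H x W integer/numeric matrix, nonzero = foreground.
// Returns H x W integer matrix of labels 1..k in first-encounter order.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(NumericMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background sentinel

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      // previously visited 8-neighbors in column-major scan order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        int nr = nb[k][0], nc = nb[k][1];
        if (nr < 0 || nr >= H || nc < 0) continue;
        int l = lab(nr, nc);
        if (l == 0) continue;
        if (best == 0) {
          best = l;
        } else if (l != best) {
          int ra = find_root(parent, best), rb = find_root(parent, l);
          if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
          best = std::min(find_root(parent, ra), find_root(parent, rb));
        }
      }
      if (best == 0) {
        int fresh = (int)parent.size();
        parent.push_back(fresh);
        lab(r, c) = fresh;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // second pass: compress to consecutive labels in first-encounter order
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}
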