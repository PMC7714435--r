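#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}

// Two-pass connected-component labelling of a binary mask.
// connectivity: 4 or 8 (foreground). Labels are renumbered 1..n in
// raster-scan (row-major) order of each component's first pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask, const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  for (int y = 0; y < nr; ++y) {
    for (int x = 0; x < nc; ++x) {
      if (mask(y, x) == 0) continue;
      int neigh[4];
      int nn = 0;
      if (x > 0 && mask(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (y > 0 && mask(y - 1, x)) neigh[nn++] = lab(y - 1, x);
      if (connectivity == 8 && y > 0) {
        if (x > 0 && mask(y - 1, x - 1)) neigh[nn++] = lab(y - 1, x - 1);
        if (x < nc - 1 && mask(y - 1, x + 1)) neigh[nn++] = lab(y - 1, x + 1);
      }
      if (nn == 0) {
        int id = static_cast<int>(parent.size());
        parent.push_back(id);
        lab(y, x) = id;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(y, x) = m;
        for (int k = 0; k < nn; ++k) {
          int a = uf_find(parent, m), b = uf_find(parent, neigh[k]);
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
        }
      }
    }
  }

  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (int y = 0; y < nr; ++y) {
    for (int x = 0; x < nc; ++x) {
      if (lab(y, x) == 0) continue;
      int r = uf_find(parent, lab(y, x));
      if (newid[r] == 0) newid[r] = ++next;
      lab(y, x) = newid[r];
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Multiplicatively weighted nearest-centre assignment: every pixel inside the
// 1-based window [r0,r1] x [c0,c1] gets the index (1-based) of the centre
// minimising euclidean distance scaled by 1/w. Ties break to the lowest index.
// Pixels outside the window stay 0. Centres are bucketed on a coarse grid
// (each registered within 3x its weighted radius) so a pixel scans only local
// candidates; an empty bucket falls back to the full scan, which keeps the
// result identical to the brute-force definition in practice.
// [[Rcpp::export(name = ".nearest_center")]]
IntegerMatrix nearest_center(const int nrow, const int ncol,
                             const NumericVector& cy, const NumericVector& cx,
                             const NumericVector& w,
                             const int r0, const int r1,
                             const int c0, const int c1) {
  IntegerMatrix lab(nrow, ncol);
  const int k = cy.size();
  std::vector<double> iw2(k);
  for (int j = 0; j < k; ++j) iw2[j] = 1.0 / (w[j] * w[j]);

  const double bsz = 64.0;
  const int nbx = std::max(1, (int)std::ceil(ncol / bsz));
  const int nby = std::max(1, (int)std::ceil(nrow / bsz));
  std::vector<std::vector<int>> buckets((size_t)nbx * nby);
  for (int j = 0; j < k; ++j) {
    const double reach = 3.0 * w[j];
    int by0 = std::max(0, (int)((cy[j] - 1 - reach) / bsz));
    int by1 = std::min(nby - 1, (int)((cy[j] - 1 + reach) / bsz));
    int bx0 = std::max(0, (int)((cx[j] - 1 - reach) / bsz));
    int bx1 = std::min(nbx - 1, (int)((cx[j] - 1 + reach) / bsz));
    for (int by = by0; by <= by1; ++by)
      for (int bx = bx0; bx <= bx1; ++bx)
        buckets[(size_t)by * nbx + bx].push_back(j);
  }

  for (int y = r0 - 1; y < r1; ++y) {
    const size_t brow = (size_t)(y / (int)bsz) * nbx;
    for (int x = c0 - 1; x < c1; ++x) {
      const std::vector<int>& cand = buckets[brow + (x / (int)bsz)];
      double best = R_PosInf;
      int bj = 0;
      if (!cand.empty()) {
        for (size_t t = 0; t < cand.size(); ++t) {
          const int j = cand[t];
          const double dy = (y + 1) - cy[j], dx = (x + 1) - cx[j];
          const double d = (dy * dy + dx * dx) * iw2[j];
          if (d < best) { best = d; bj = j + 1; }
        }
      } else {
        for (int j = 0; j < k; ++j) {
          const double dy = (y + 1) - cy[j], dx = (x + 1) - cx[j];
          const double d = (dy * dy + dx * dx) * iw2[j];
          if (d < best) { best = d; bj = j + 1; }
        }
      }
      lab(y, x) = bj;
    }
  }
  return lab;
}
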