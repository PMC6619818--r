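#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Produces a 1-px-wide 8-connected skeleton,
// the discrete stand-in for the medial axis of a silhouette mask.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img(nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[j * nr + i] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[j * nr + i];
  };

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[j * nr + i]) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(j * nr + i);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) img[kill[k]] = 0;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[j * nr + i] == 1;
  return out;
}

// 8-connected component labeling of a binary mask by flood fill.
// Labels are 1..k in first-encounter (column-major scan) order; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(nj * nr + ni);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Evaluate a boosted forest of kernel-split decision trees at given pixels.
//
// imgPad: image padded by `half` zeros on every side so the full patch window
//   of any queried pixel lies in range. rows/cols are 0-based coordinates in
//   the padded image of the patch centres.
// Per-node arrays are concatenated over all trees; treeRoot[t] is the index of
//   tree t's root node. Children indices are global; -1 marks "none".
// Internal node test: response = sum_{m,n} K[m,n] * patch[ar+m, ac+n], route
//   left when response < tau. ar/ac are 0-based offsets of the kernel window
//   inside the (2*half+1)^2 patch.
// [[Rcpp::export]]
NumericVector cpp_forest_score(NumericMatrix imgPad,
                               IntegerVector rows, IntegerVector cols,
                               int half,
                               IntegerVector treeRoot,
                               IntegerVector isLeaf,
                               NumericVector value,
                               NumericVector tau,
                               IntegerVector left,
                               IntegerVector right,
                               IntegerVector kSize,
                               IntegerVector anchorR,
                               IntegerVector anchorC,
                               IntegerVector kOffset,
                               NumericVector kWeights) {
  int n = rows.size(), nTrees = treeRoot.size();
  int nrP = imgPad.nrow();
  const double* img = REAL(imgPad);
  NumericVector score(n);

  for (int p = 0; p < n; ++p) {
    // top-left corner of the 41x41 patch in padded coords
    int pr = rows[p] - half, pc = cols[p] - half;
    double s = 0.0;
    for (int t = 0; t < nTrees; ++t) {
      int node = treeRoot[t];
      while (!isLeaf[node]) {
        int sz = kSize[node];
        int r0 = pr + anchorR[node], c0 = pc + anchorC[node];
        const double* kw = &kWeights[kOffset[node]];
        // four accumulators break the serial FP dependency chain
        double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
        int ki = 0;
        for (int cc = 0; cc < sz; ++cc) {
          const double* colptr = img + (size_t)(c0 + cc) * nrP + r0;
          int rr = 0;
          for (; rr + 4 <= sz; rr += 4, ki += 4) {
            a0 += kw[ki] * colptr[rr];
            a1 += kw[ki + 1] * colptr[rr + 1];
            a2 += kw[ki + 2] * colptr[rr + 2];
            a3 += kw[ki + 3] * colptr[rr + 3];
          }
          for (; rr < sz; ++rr, ++ki) a0 += kw[ki] * colptr[rr];
        }
        double resp = (a0 + a1) + (a2 + a3);
        node = (resp < tau[node]) ? left[node] : right[node];
      }
      s += value[node];
    }
    score[p] = s;
  }
  return score;
}
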