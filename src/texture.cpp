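#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (crossing number) point-in-polygon test, vectorised over points.
// [[Rcpp::export]]
LogicalVector cppPointsInPolygon(NumericVector x, NumericVector y,
                                 NumericVector px, NumericVector py) {
  const int n = x.size(), m = px.size();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    bool inside = false;
    double xx = x[k], yy = y[k];
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((py[i] > yy) != (py[j] > yy)) &&
          (xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i]))
        inside = !inside;
    }
    out[k] = inside;
  }
  return out;
}

// Grey-level co-occurrence counts for one offset (dx cols, dy rows).
// `levels` holds 1..nLevels inside the mask and NA outside. The returned
// matrix is symmetric (each pair counted in both orders).
// [[Rcpp::export]]
NumericMatrix cppGlcm(IntegerMatrix levels, int nLevels, int dx, int dy) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix P(nLevels, nLevels);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int a = levels(r, c);
      if (a == NA_INTEGER) continue;
      int r2 = r + dy, c2 = c + dx;
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int b = levels(r2, c2);
      if (b == NA_INTEGER) continue;
      P(a - 1, b - 1) += 1.0;
      P(b - 1, a - 1) += 1.0;
    }
  }
  return P;
}

// Run-length counts for one direction: rows = grey level, cols = run length.
// Runs are maximal same-level segments along the direction; masked-out
// pixels break runs.
// [[Rcpp::export]]
NumericMatrix cppGlrlm(IntegerMatrix levels, int nLevels, int dx, int dy) {
  const int nr = levels.nrow(), nc = levels.ncol();
  int maxLen = std::max(nr, nc);
  NumericMatrix R(nLevels, maxLen);
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      int rp = r0 - dy, cp = c0 - dx;
      bool lineStart = (rp < 0 || rp >= nr || cp < 0 || cp >= nc);
      if (!lineStart) continue;
      int curLevel = NA_INTEGER, curLen = 0;
      int r = r0, c = c0;
      while (r >= 0 && r < nr && c >= 0 && c < nc) {
        int v = levels(r, c);
        if (v == NA_INTEGER) {
          if (curLen > 0) R(curLevel - 1, curLen - 1) += 1.0;
          curLevel = NA_INTEGER; curLen = 0;
        } else if (v == curLevel) {
          ++curLen;
        } else {
          if (curLen > 0) R(curLevel - 1, curLen - 1) += 1.0;
          curLevel = v; curLen = 1;
        }
        r += dy; c += dx;
      }
      if (curLen > 0) R(curLevel - 1, curLen - 1) += 1.0;
    }
  }
  return R;
}

// Zones: 8-connected components of equal grey level inside the mask.
// Returns a two-column matrix (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cppZones(IntegerMatrix levels) {
  const int nr = levels.nrow(), nc = levels.ncol();
  std::vector<bool> seen(nr * nc, false);
  std::vector<int> zlevel, zsize;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = c0 * nr + r0;
      if (seen[idx0]) continue;
      int v = levels(r0, c0);
      if (v == NA_INTEGER) { seen[idx0] = true; continue; }
      int size = 0;
      stack.clear();
      stack.push_back(idx0);
      seen[idx0] = true;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        ++size;
        for (int ddr = -1; ddr <= 1; ++ddr) {
          for (int ddc = -1; ddc <= 1; ++ddc) {
            if (ddr == 0 && ddc == 0) continue;
            int r2 = r + ddr, c2 = c + ddc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int idx2 = c2 * nr + r2;
            if (seen[idx2]) continue;
            if (levels(r2, c2) == v) { seen[idx2] = true; stack.push_back(idx2); }
          }
        }
      }
      zlevel.push_back(v);
      zsize.push_back(size);
    }
  }
  IntegerMatrix out(zlevel.size(), 2);
  for (size_t i = 0; i < zlevel.size(); ++i) {
    out(i, 0) = zlevel[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// NGTDM accumulators: per grey level, the count of contributing pixels
// (those with at least one in-mask Chebyshev-1 neighbour) and the summed
// absolute difference to the neighbourhood mean.
// [[Rcpp::export]]
NumericMatrix cppNgtdm(IntegerMatrix levels, int nLevels) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix out(nLevels, 2); // cols: n_i, s_i
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = levels(r, c);
      if (v == NA_INTEGER) continue;
      double sum = 0.0; int cnt = 0;
      for (int ddr = -1; ddr <= 1; ++ddr) {
        for (int ddc = -1; ddc <= 1; ++ddc) {
          if (ddr == 0 && ddc == 0) continue;
          int r2 = r + ddr, c2 = c + ddc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int w = levels(r2, c2);
          if (w == NA_INTEGER) continue;
          sum += w; ++cnt;
        }
      }
      if (cnt == 0) continue;
      out(v - 1, 0) += 1.0;
      out(v - 1, 1) += std::fabs(v - sum / cnt);
    }
  }
  return out;
}

// GLDM counts: rows = grey level, cols = dependence k + 1 where k is the
// number of in-mask Chebyshev-1 neighbours within alpha of the centre.
// [[Rcpp::export]]
NumericMatrix cppGldm(IntegerMatrix levels, int nLevels, int alpha) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix P(nLevels, 9); // dependence 0..8
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = levels(r, c);
      if (v == NA_INTEGER) continue;
      int k = 0;
      for (int ddr = -1; ddr <= 1; ++ddr) {
        for (int ddc = -1; ddc <= 1; ++ddc) {
          if (ddr == 0 && ddc == 0) continue;
          int r2 = r + ddr, c2 = c + ddc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int w = levels(r2, c2);
          if (w == NA_INTEGER) continue;
          if (std::abs(w - v) <= alpha) ++k;
        }
      }
      P(v - 1, k) += 1.0;
    }
  }
  return P;
}
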