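// Small image primitives: 1-D convolution along the axial (row) axis with
// edge replication, and 8-connected component labeling by flood fill.
#include <Rcpp.h>
#include <queue>

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv_rows(Rcpp::NumericMatrix img,
                                  Rcpp::NumericVector kernel) {
  const int H = img.nrow(), W = img.ncol(), K = kernel.size();
  const int r = K / 2;  // kernel assumed odd-length, centred
  Rcpp::NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        int j = i + k - r;
        if (j < 0) j = 0; else if (j >= H) j = H - 1;  // replicate edges
        acc += img(j, c) * kernel[k];
      }
      out(i, c) = acc;
    }
  }
  return out;
}

// BFS flood fill over the 8-neighbourhood; labels are assigned in raster
// (column-major) order of each component's first pixel.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label8(Rcpp::LogicalMatrix bw) {
  const int H = bw.nrow(), W = bw.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!bw(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (bw(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              q.push({nr, nc});
            }
          }
        }
      }
    }
  }
  return lab;
}
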