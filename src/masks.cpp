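// Pixel-set geometry kernels: 8-connected component labelling with
// deterministic raster-scan label order, and Moore border following with
// Jacob's stopping criterion for outer-contour extraction.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  // raster scan: row by row, left to right, so label order is the order
  // of each component's first pixel in reading order
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int pr = stack.back().first, pc = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (m(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  lab.attr("k") = next;
  return lab;
}

// Clockwise neighbour order on screen (row index pointing down),
// starting west: W NW N NE E SE S SW.
static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

// [[Rcpp::export]]
IntegerMatrix trace_contour_cpp(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (m(r, c)) {
        sr = r;
        sc = c;
        break;
      }
  if (sr < 0) return IntegerMatrix(0, 2);

  std::vector<int> rows, cols;
  rows.push_back(sr);
  cols.push_back(sc);

  // direction index of the backtrack pixel relative to the current pixel;
  // the start's west neighbour is background because the start is the
  // first foreground pixel in raster order
  const int b0 = 0;
  int pr = sr, pc = sc, b = b0;
  const long maxit = 4L * H * W + 8;
  for (long it = 0; it < maxit; ++it) {
    int found = -1;
    for (int q = 1; q <= 8; ++q) {  // scan clockwise starting after b
      const int d = (b + q) % 8;
      const int nr = pr + DR[d], nc = pc + DC[d];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (m(nr, nc)) {
        found = d;
        break;
      }
    }
    if (found < 0) break;  // isolated single pixel
    // backtrack for the next step: the neighbour scanned just before the
    // hit, expressed relative to the new pixel
    int prev = found;
    do {
      prev = (prev + 7) % 8;
      const int qr = pr + DR[prev], qc = pc + DC[prev];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W || !m(qr, qc)) break;
    } while (true);
    const int nr = pr + DR[found], nc = pc + DC[found];
    // position of (pr,pc)+prev relative to (nr,nc): recompute as direction
    int nb = -1;
    {
      const int br = pr + DR[prev], bc = pc + DC[prev];
      for (int d = 0; d < 8; ++d)
        if (nr + DR[d] == br && nc + DC[d] == bc) {
          nb = d;
          break;
        }
      if (nb < 0) nb = 0;  // off-grid backtrack: fall back to west
    }
    if (nr == sr && nc == sc && nb == b0) break;  // closed the contour
    rows.push_back(nr);
    cols.push_back(nc);
    pr = nr;
    pc = nc;
    b = nb;
  }

  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;  // 1-based for R
    out(i, 1) = cols[i] + 1;
  }
  return out;
}
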