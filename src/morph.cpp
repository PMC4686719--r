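// Mask-based morphometry primitives: 8-connected component labeling,
// Moore-neighbor outer-boundary tracing with 1 / sqrt(2) step weights, and
// city-block (plus-shaped) dilation of a pixel set.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling by BFS; labels 1..k in scan order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int rr = q.front().first, cc = q.front().second; q.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || c2 < 0 || r2 >= H || c2 >= W) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              q.push(std::make_pair(r2, c2));
            }
          }
      }
    }
  }
  return lab;
}

// Moore-neighbor tracing of the outer boundary of one labeled region
// (interior holes are not traced). Returns the ordered boundary pixels
// (row, col; 1-based) and the closed-path length with orthogonal steps
// weighted 1 and diagonal steps sqrt(2). Single-pixel regions get length 1
// by convention.
// [[Rcpp::export(name = ".cpp_trace_boundary")]]
List cpp_trace_boundary(IntegerMatrix lab, int label) {
  int H = lab.nrow(), W = lab.ncol();
  // neighbors clockwise starting from W
  const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int DC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) stop("label not present in matrix");

  // scan order guarantees all neighbors above and to the left of the start
  // pixel are background, so the initial backtrack direction is W.
  std::vector<int> br, bc;
  br.push_back(sr); bc.push_back(sc);
  double len = 0.0;
  int cr = sr, cc = sc, from = 0;  // 'from' = direction of the backtrack pixel
  bool single = true;
  long guard = 8L * H * W + 16;
  int p1r = -1, p1c = -1, from1 = -1;  // state after the first move
  for (;;) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {     // clockwise, just after the backtrack
      int d = (from + k) % 8;
      int r2 = cr + DR[d], c2 = cc + DC[d];
      if (r2 < 0 || c2 < 0 || r2 >= H || c2 >= W) continue;
      if (lab(r2, c2) == label) { found = d; break; }
    }
    if (found < 0) break;              // isolated pixel
    double w = (DR[found] && DC[found]) ? M_SQRT2 : 1.0;
    int r2 = cr + DR[found], c2 = cc + DC[found];
    int nfrom = (found + 4) % 8;
    if (single) {                      // record the post-first-move state
      single = false;
      p1r = r2; p1c = c2; from1 = nfrom;
    } else if (r2 == p1r && c2 == p1c && nfrom == from1) {
      break;                           // full outer boundary traversed
    }
    len += w;
    cr = r2; cc = c2; from = nfrom;
    br.push_back(cr); bc.push_back(cc);
    if (--guard < 0) stop("boundary trace failed to terminate");
  }
  if (single) len = 1.0;
  // the trace closes on the start pixel; drop the duplicated terminal pixels
  while (br.size() > 1 && br.back() == sr && bc.back() == sc &&
         br.front() == sr && bc.front() == sc) {
    br.pop_back(); bc.pop_back();
  }
  int n = (int)br.size();
  IntegerMatrix pts(n, 2);
  for (int i = 0; i < n; ++i) { pts(i, 0) = br[i] + 1; pts(i, 1) = bc[i] + 1; }
  return List::create(_["perimeter"] = len, _["boundary"] = pts);
}

// City-block dilation: all pixels within L1 distance <= radius of any seed
// pixel (multi-source BFS over the full H x W grid).
// [[Rcpp::export(name = ".cpp_l1_zone")]]
LogicalMatrix cpp_l1_zone(IntegerMatrix seeds, int H, int W, int radius) {
  std::vector<int> dist((size_t)H * W, -1);
  std::queue<int> q;
  for (int i = 0; i < seeds.nrow(); ++i) {
    int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    if (r < 0 || c < 0 || r >= H || c >= W) continue;
    int k = r * W + c;
    if (dist[k] == -1) { dist[k] = 0; q.push(k); }
  }
  const int DR[4] = {-1, 1, 0, 0}, DC[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int k = q.front(); q.pop();
    int r = k / W, c = k % W;
    if (dist[k] >= radius) continue;
    for (int d = 0; d < 4; ++d) {
      int r2 = r + DR[d], c2 = c + DC[d];
      if (r2 < 0 || c2 < 0 || r2 >= H || c2 >= W) continue;
      int k2 = r2 * W + c2;
      if (dist[k2] == -1) { dist[k2] = dist[k] + 1; q.push(k2); }
    }
  }
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = dist[r * W + c] >= 0;
  return out;
}
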