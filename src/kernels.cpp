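// Low-level raster kernels. Images are R matrices (row = y, col = x),
// pixel (x, y) maps to mat(y, x) with 0-based pixel-center coordinates.
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// large finite stand-in for "no feature" so the parabola intersections stay finite
static const double BIG = 1e15;

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance of every pixel to the nearest TRUE pixel of `feature`.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix feature) {
  int h = feature.nrow(), w = feature.ncol();
  NumericMatrix out(h, w);
  // column pass
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  for (int x = 0; x < w; x++) {
    for (int y = 0; y < h; y++) f[y] = feature(y, x) ? 0.0 : BIG;
    dt1d(f, d, h);
    for (int y = 0; y < h; y++) out(y, x) = d[y];
  }
  for (int y = 0; y < h; y++) {
    for (int x = 0; x < w; x++) f[x] = out(y, x);
    dt1d(f, d, w);
    for (int x = 0; x < w; x++) out(y, x) = d[x];
  }
  return out;
}

// ---- flood fill (wand selection) ----------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_flood(NumericMatrix img, int seed_y, int seed_x,
                        double lo, double hi, int conn) {
  int h = img.nrow(), w = img.ncol();
  LogicalMatrix out(h, w);
  if (img(seed_y, seed_x) < lo || img(seed_y, seed_x) > hi) return out;
  std::deque<std::pair<int, int> > q;
  q.push_back(std::make_pair(seed_y, seed_x));
  out(seed_y, seed_x) = true;
  int dy8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  int dx8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  int dy4[4] = { -1, 0, 0, 1 };
  int dx4[4] = { 0, -1, 1, 0 };
  int n = (conn == 4) ? 4 : 8;
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop_front();
    for (int i = 0; i < n; i++) {
      int y = p.first + ((conn == 4) ? dy4[i] : dy8[i]);
      int x = p.second + ((conn == 4) ? dx4[i] : dx8[i]);
      if (y < 0 || y >= h || x < 0 || x >= w) continue;
      if (out(y, x)) continue;
      double v = img(y, x);
      if (v >= lo && v <= hi) { out(y, x) = true; q.push_back(std::make_pair(y, x)); }
    }
  }
  return out;
}

// ---- connected component labeling ---------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int dy8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  int dx8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  int dy4[4] = { -1, 0, 0, 1 };
  int dx4[4] = { 0, -1, 1, 0 };
  int n = (conn == 4) ? 4 : 8;
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int x0 = 0; x0 < w; x0++) for (int y0 = 0; y0 < h; y0++) {
    if (!mask(y0, x0) || lab(y0, x0)) continue;
    next++;
    lab(y0, x0) = next;
    q.push_back(std::make_pair(y0, x0));
    while (!q.empty()) {
      std::pair<int, int> p = q.front(); q.pop_front();
      for (int i = 0; i < n; i++) {
        int y = p.first + ((conn == 4) ? dy4[i] : dy8[i]);
        int x = p.second + ((conn == 4) ? dx4[i] : dx8[i]);
        if (y < 0 || y >= h || x < 0 || x >= w) continue;
        if (!mask(y, x) || lab(y, x)) continue;
        lab(y, x) = next;
        q.push_back(std::make_pair(y, x));
      }
    }
  }
  return lab;
}

// ---- local disk mean / sd (Phansalkar) ----------------------------------

// [[Rcpp::export]]
List cpp_local_mean_sd(NumericMatrix img, int radius) {
  int h = img.nrow(), w = img.ncol();
  std::vector<int> offy, offx;
  for (int dy = -radius; dy <= radius; dy++)
    for (int dx = -radius; dx <= radius; dx++)
      if (dy * dy + dx * dx <= radius * radius) { offy.push_back(dy); offx.push_back(dx); }
  int m = (int)offy.size();
  NumericMatrix mu(h, w), sd(h, w);
  for (int x = 0; x < w; x++) for (int y = 0; y < h; y++) {
    double s = 0, s2 = 0; int n = 0;
    for (int i = 0; i < m; i++) {
      int yy = y + offy[i], xx = x + offx[i];
      if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
      double v = img(yy, xx);
      s += v; s2 += v * v; n++;
    }
    double mn = s / n;
    double var = s2 / n - mn * mn;
    mu(y, x) = mn;
    sd(y, x) = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// ---- grayscale morphology with a ball structuring surface ---------------

// op: 0 = erode (min of img - ball), 1 = dilate (max of img + ball)
// [[Rcpp::export]]
NumericMatrix cpp_gray_ball(NumericMatrix img, double radius, int op) {
  int h = img.nrow(), w = img.ncol();
  int r = (int)std::ceil(radius);
  std::vector<int> offy, offx; std::vector<double> bh;
  for (int dy = -r; dy <= r; dy++)
    for (int dx = -r; dx <= r; dx++) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 <= radius * radius) {
        offy.push_back(dy); offx.push_back(dx);
        bh.push_back(std::sqrt(radius * radius - d2));
      }
    }
  int m = (int)offy.size();
  NumericMatrix out(h, w);
  for (int x = 0; x < w; x++) for (int y = 0; y < h; y++) {
    double best = (op == 0) ? INF : -INF;
    for (int i = 0; i < m; i++) {
      int yy = y + offy[i], xx = x + offx[i];
      if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
      double v = (op == 0) ? img(yy, xx) - bh[i] : img(yy, xx) + bh[i];
      if (op == 0) { if (v < best) best = v; } else { if (v > best) best = v; }
    }
    out(y, x) = best;
  }
  return out;
}

// ---- separable convolution with reflective boundary ---------------------

// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(NumericMatrix img, NumericVector kernel) {
  int h = img.nrow(), w = img.ncol();
  int kn = kernel.size(), kr = kn / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // rows (convolve along x)
  for (int y = 0; y < h; y++) for (int x = 0; x < w; x++) {
    double s = 0;
    for (int i = 0; i < kn; i++) {
      int xx = x + i - kr;
      if (xx < 0) xx = -xx - 1;
      if (xx >= w) xx = 2 * w - xx - 1;
      s += img(y, xx) * kernel[i];
    }
    tmp(y, x) = s;
  }
  for (int y = 0; y < h; y++) for (int x = 0; x < w; x++) {
    double s = 0;
    for (int i = 0; i < kn; i++) {
      int yy = y + i - kr;
      if (yy < 0) yy = -yy - 1;
      if (yy >= h) yy = 2 * h - yy - 1;
      s += tmp(yy, x) * kernel[i];
    }
    out(y, x) = s;
  }
  return out;
}

// ---- polygon rasterization (even-odd, pixel centers; on-boundary included)

// [[Rcpp::export]]
LogicalMatrix cpp_rasterize(NumericVector xs, NumericVector ys, int h, int w) {
  int nv = xs.size();
  LogicalMatrix out(h, w);
  const double eps = 1e-9;
  for (int y = 0; y < h; y++) {
    // collect crossings of the scanline at this row's pixel-center y
    std::vector<double> cross;
    for (int i = 0; i < nv; i++) {
      int j = (i + 1) % nv;
      double y1 = ys[i], y2 = ys[j], x1 = xs[i], x2 = xs[j];
      if ((y1 <= y) != (y2 <= y)) {
        double t = (y - y1) / (y2 - y1);
        cross.push_back(x1 + t * (x2 - x1));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (int x = 0; x < w; x++) {
      int nleft = 0;
      for (size_t i = 0; i < cross.size(); i++)
        if (cross[i] < x - eps) nleft++;
      bool inside = (nleft % 2) == 1;
      if (!inside) {
        // on-boundary test: distance from (x, y) to any edge < eps
        for (int i = 0; i < nv && !inside; i++) {
          int j = (i + 1) % nv;
          double ex = xs[j] - xs[i], ey = ys[j] - ys[i];
          double len2 = ex * ex + ey * ey;
          double t = len2 > 0 ? ((x - xs[i]) * ex + (y - ys[i]) * ey) / len2 : 0.0;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double dx = x - (xs[i] + t * ex), dy = y - (ys[i] + t * ey);
          if (dx * dx + dy * dy < 1e-12) inside = true;
        }
      }
      if (inside) out(y, x) = true;
    }
  }
  return out;
}

// ---- crack boundary tracing ---------------------------------------------

// Trace the outer pixel-edge ("crack") contour of component `id` in `lab`.
// Returns an (n x 2) matrix of (x, y) vertices on half-integer coordinates;
// shoelace area equals the pixel count for hole-free 4-connected components.
// [[Rcpp::export]]
NumericMatrix cpp_trace_crack(IntegerMatrix lab, int id) {
  int h = lab.nrow(), w = lab.ncol();
  // find start: topmost row, then leftmost column
  int sy = -1, sx = -1;
  for (int y = 0; y < h && sy < 0; y++)
    for (int x = 0; x < w; x++)
      if (lab(y, x) == id) { sy = y; sx = x; break; }
  if (sy < 0) stop("component not found");
  // walk along cracks keeping the component on the right of the direction of
  // travel (clockwise on screen, positive shoelace with y down).
  // corner (cx, cy) = point (cx - 0.5, cy - 0.5); cx in 0..w, cy in 0..h.
  // directions: 0 = +x, 1 = +y, 2 = -x, 3 = -y
  int dcx[4] = { 1, 0, -1, 0 };
  int dcy[4] = { 0, 1, 0, -1 };
  std::vector<double> vx, vy;
  int cx = sx, cy = sy, dir = 0;  // start at top-left corner of start pixel
  int scx = cx, scy = cy, sdir = dir;
  int guard = 8 * h * w + 16;
  do {
    vx.push_back(cx - 0.5); vy.push_back(cy - 0.5);
    // step to the next corner
    cx += dcx[dir]; cy += dcy[dir];
    // decide new direction from the two pixels ahead of the new corner:
    // left-ahead and right-ahead relative to current direction.
    // pixel(px, py) inside test
    for (int turn = 1; turn >= -2; turn--) {
      // candidate direction; try left turn first (keeps loop tight, pinches
      // through diagonal contacts), then straight, then right, then back.
      int nd = ((dir + ((turn == 1) ? 3 : (turn == 0) ? 0 : (turn == -1) ? 1 : 2)) % 4);
      // moving from corner (cx,cy) in direction nd: pixel on the right is
      int rpx, rpy, lpx, lpy;
      if (nd == 0)      { rpx = cx;     rpy = cy;     lpx = cx;     lpy = cy - 1; }
      else if (nd == 1) { rpx = cx - 1; rpy = cy;     lpx = cx;     lpy = cy;     }
      else if (nd == 2) { rpx = cx - 1; rpy = cy - 1; lpx = cx - 1; lpy = cy;     }
      else              { rpx = cx;     rpy = cy - 1; lpx = cx - 1; lpy = cy - 1; }
      bool rin = rpx >= 0 && rpx < w && rpy >= 0 && rpy < h && lab(rpy, rpx) == id;
      bool lin = lpx >= 0 && lpx < w && lpy >= 0 && lpy < h && lab(lpy, lpx) == id;
      if (rin && !lin) { dir = nd; break; }
    }
    if (--guard <= 0) stop("boundary trace failed to close");
  } while (!(cx == scx && cy == scy && dir == sdir));
  // drop collinear duplicates along straight runs
  int n = (int)vx.size();
  std::vector<double> ox, oy;
  for (int i = 0; i < n; i++) {
    int ip = (i + n - 1) % n, in = (i + 1) % n;
    double ax = vx[i] - vx[ip], ay = vy[i] - vy[ip];
    double bx = vx[in] - vx[i], by = vy[in] - vy[i];
    if (ax * by - ay * bx != 0 || ax * bx + ay * by < 0) { ox.push_back(vx[i]); oy.push_back(vy[i]); }
  }
  NumericMatrix out((int)ox.size(), 2);
  for (size_t i = 0; i < ox.size(); i++) { out(i, 0) = ox[i]; out(i, 1) = oy[i]; }
  return out;
}

// ---- Moore boundary chain (for Kulpa perimeter) -------------------------

// Returns c(n_straight, n_diagonal) steps of the 8-connected outer boundary
// chain of component `id`.
// [[Rcpp::export]]
IntegerVector cpp_moore_chain(IntegerMatrix lab, int id) {
  int h = lab.nrow(), w = lab.ncol();
  int sy = -1, sx = -1;
  for (int y = 0; y < h && sy < 0; y++)
    for (int x = 0; x < w; x++)
      if (lab(y, x) == id) { sy = y; sx = x; break; }
  if (sy < 0) stop("component not found");
  // Moore neighborhood in clockwise screen order starting from W
  int dy[8] = { 0, -1, -1, -1, 0, 1, 1, 1 };
  int dx8[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  int ns = 0, nd = 0;
  int py = sy, px = sx;
  int pb = 0;        // backtrack: came from the W (row scan found it from the left)
  int first_dir = -1;
  int guard = 8 * h * w + 16;
  while (guard-- > 0) {
    int found = -1;
    for (int i = 0; i < 8; i++) {
      int k = (pb + 1 + i) % 8;
      int yy = py + dy[k], xx = px + dx8[k];
      if (yy >= 0 && yy < h && xx >= 0 && xx < w && lab(yy, xx) == id) { found = k; break; }
    }
    if (found < 0) break; // isolated pixel, no steps
    if (py == sy && px == sx) {
      if (first_dir < 0) first_dir = found;
      else if (found == first_dir) break; // Jacob's criterion: repeating start move
    }
    if ((dy[found] != 0) && (dx8[found] != 0)) nd++; else ns++;
    py += dy[found]; px += dx8[found];
    pb = (found + 4) % 8;
  }
  return IntegerVector::create(ns, nd);
}

// ---- CRC32 (for zip writing) --------------------------------------------

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (int i = 0; i < data.size(); i++)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  return (double)crc;
}
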