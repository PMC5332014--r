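#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Offsets of a circular neighborhood: dx*dx + dy*dy <= r*r.
static std::vector<std::pair<int,int>> disc_offsets(int radius) {
  std::vector<std::pair<int,int>> off;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= radius * radius)
        off.push_back(std::make_pair(dy, dx));
  return off;
}

// Median filter over a circular neighborhood; edges use nearest-pixel
// extension (indices clamped to the raster).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  const int k = static_cast<int>(off.size());
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int i = 0; i < k; ++i) {
        int rr = r + off[i].first;
        int cc = c + off[i].second;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
        buf[i] = img(rr, cc);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = 0.5 * (lo + med);
      }
      out(r, c) = med;
    }
  }
  return out;
}

// 1-D sliding min and max over columns with halfwidth w (window clipped at
// the borders), for every row of the matrix; results written to mn / mx.
static void sliding_minmax_rows(const NumericMatrix &img, int w,
                                NumericMatrix &mn, NumericMatrix &mx) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dq(nc);
  for (int r = 0; r < nr; ++r) {
    // min
    int head = 0, tail = 0;
    for (int c = 0; c < nc + w; ++c) {
      if (c < nc) {
        while (tail > head && img(r, dq[tail - 1]) >= img(r, c)) --tail;
        dq[tail++] = c;
      }
      int out_c = c - w;
      if (out_c >= 0 && out_c < nc) {
        while (dq[head] < out_c - w) ++head;
        mn(r, out_c) = img(r, dq[head]);
      }
    }
    // max
    head = 0; tail = 0;
    for (int c = 0; c < nc + w; ++c) {
      if (c < nc) {
        while (tail > head && img(r, dq[tail - 1]) <= img(r, c)) --tail;
        dq[tail++] = c;
      }
      int out_c = c - w;
      if (out_c >= 0 && out_c < nc) {
        while (dq[head] < out_c - w) ++head;
        mx(r, out_c) = img(r, dq[head]);
      }
    }
  }
}

// Bernsen local threshold over a circular window (clipped at image borders).
// contrast = max - min; midgray = (max + min) / 2.  Low-contrast windows are
// classified wholesale by midgray >= 128, otherwise pixel >= midgray.
// The circular window is decomposed into per-row segments |dx| <= wx(dy),
// each served by an O(n) sliding min/max, so the cost is ~(2r+1) passes.
// [[Rcpp::export]]
LogicalMatrix cpp_bernsen(NumericMatrix img, int radius, double contrast_threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> wx(radius + 1);
  for (int dy = 0; dy <= radius; ++dy)
    wx[dy] = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
  // distinct segment halfwidths -> precomputed per-row sliding min/max
  std::vector<int> widths(wx);
  std::sort(widths.begin(), widths.end());
  widths.erase(std::unique(widths.begin(), widths.end()), widths.end());
  std::vector<NumericMatrix> mins, maxs;
  std::vector<int> width_of(radius + 1);
  for (size_t i = 0; i < widths.size(); ++i) {
    NumericMatrix mn(nr, nc), mx(nr, nc);
    sliding_minmax_rows(img, widths[i], mn, mx);
    mins.push_back(mn); maxs.push_back(mx);
    for (int dy = 0; dy <= radius; ++dy)
      if (wx[dy] == widths[i]) width_of[dy] = (int)i;
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double vmin = std::numeric_limits<double>::infinity();
      double vmax = -vmin;
      int dlo = std::max(-radius, -r), dhi = std::min(radius, nr - 1 - r);
      for (int dy = dlo; dy <= dhi; ++dy) {
        int i = width_of[dy < 0 ? -dy : dy];
        double a = mins[i](r + dy, c), b = maxs[i](r + dy, c);
        if (a < vmin) vmin = a;
        if (b > vmax) vmax = b;
      }
      double contrast = vmax - vmin;
      double midgray = 0.5 * (vmax + vmin);
      bool fg;
      if (contrast < contrast_threshold) fg = (midgray >= 128.0);
      else fg = (img(r, c) >= midgray);
      out(r, c) = fg;
    }
  }
  return out;
}

// Lower envelope e(i) = min_j f(j) + coeff * (i - j)^2 in O(n)
// (Felzenszwalb-Huttenlocher parabolic distance transform).
static void parab_erode(std::vector<double> &f, double coeff, std::vector<double> &out,
                        std::vector<int> &v, std::vector<double> &z) {
  const int n = static_cast<int>(f.size());
  if (n == 1) { out[0] = f[0]; return; }
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + coeff * q * q) - (f[p] + coeff * p * p)) / (2.0 * coeff * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    out[q] = coeff * (q - p) * (q - p) + f[p];
  }
}

// Grayscale opening of a 1-D line with the paraboloid z = coeff * d^2:
// parabolic erosion followed by parabolic dilation.  This is the "slide the
// paraboloid under the profile" operation.
static void parab_open_line(std::vector<double> &line, double coeff,
                            std::vector<double> &tmp, std::vector<double> &tmp2,
                            std::vector<int> &v, std::vector<double> &z) {
  const int n = static_cast<int>(line.size());
  parab_erode(line, coeff, tmp, v, z);
  for (int i = 0; i < n; ++i) tmp[i] = -tmp[i];
  parab_erode(tmp, coeff, tmp2, v, z);
  for (int i = 0; i < n; ++i) line[i] = -tmp2[i];
}

// Sliding-paraboloid background: open the image with a 1-D paraboloid of
// curvature 1/(2*radius) successively along rows, columns and both diagonal
// directions.  Each pass lowers (or keeps) the background estimate, so thin
// structures are excluded while smooth shading is retained.
// [[Rcpp::export]]
NumericMatrix cpp_paraboloid_background(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const double coeff = 0.5 / radius;
  NumericMatrix bg(clone(img));
  int nmax = std::max(nr, nc) + 2;
  std::vector<double> line(nmax), tmp(nmax), tmp2(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // rows
  for (int r = 0; r < nr; ++r) {
    line.resize(nc);
    for (int c = 0; c < nc; ++c) line[c] = bg(r, c);
    parab_open_line(line, coeff, tmp, tmp2, v, z);
    for (int c = 0; c < nc; ++c) bg(r, c) = line[c];
  }
  // columns
  for (int c = 0; c < nc; ++c) {
    line.resize(nr);
    for (int r = 0; r < nr; ++r) line[r] = bg(r, c);
    parab_open_line(line, coeff, tmp, tmp2, v, z);
    for (int r = 0; r < nr; ++r) bg(r, c) = line[r];
  }
  // diagonals (down-right): start points on first column and first row
  for (int s = -(nc - 1); s < nr; ++s) {
    int r0 = s > 0 ? s : 0;
    int c0 = s > 0 ? 0 : -s;
    int len = std::min(nr - r0, nc - c0);
    if (len < 2) continue;
    line.resize(len);
    for (int i = 0; i < len; ++i) line[i] = bg(r0 + i, c0 + i);
    parab_open_line(line, coeff, tmp, tmp2, v, z);
    for (int i = 0; i < len; ++i) bg(r0 + i, c0 + i) = line[i];
  }
  // diagonals (up-right)
  for (int s = 0; s < nr + nc - 1; ++s) {
    int r0 = s < nr ? s : nr - 1;
    int c0 = s < nr ? 0 : s - nr + 1;
    int len = std::min(r0 + 1, nc - c0);
    if (len < 2) continue;
    line.resize(len);
    for (int i = 0; i < len; ++i) line[i] = bg(r0 - i, c0 + i);
    parab_open_line(line, coeff, tmp, tmp2, v, z);
    for (int i = 0; i < len; ++i) bg(r0 - i, c0 + i) = line[i];
  }
  return bg;
}

// 8-connected component labeling; labels 1..N assigned in raster-scan order
// (row-major, 0-based) of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  const int dy[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int i = 0; i < 8; ++i) {
          int rr = p.first + dy[i], cc = p.second + dx[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Discrete Voronoi: label every pixel by the nearest centroid (Euclidean,
// pixel-center coordinates, 0-based); ties broken by the lower centroid index.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_centroid(int nrow, int ncol, NumericVector cy, NumericVector cx) {
  const int k = cy.size();
  IntegerMatrix out(nrow, ncol);
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < k; ++i) {
        double dy = r - cy[i], dx = c - cx[i];
        double d = dy * dy + dx * dx;
        if (d < best) { best = d; bi = i + 1; }
      }
      out(r, c) = bi;
    }
  }
  return out;
}
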