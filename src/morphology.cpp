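#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale flat-disc erosion/dilation, decomposed into vertical line
// segments per column offset of the disc. Pixels outside the image are
// ignored (erosion pads with +Inf, dilation with -Inf), which preserves
// opening(x) <= x and top_hat(x + c) = top_hat(x).

static void col_extremum(const NumericMatrix& src, NumericMatrix& dst,
                         int h, bool take_min) {
  const int nr = src.nrow(), nc = src.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int lo = std::max(0, i - h), hi = std::min(nr - 1, i + h);
      double v = src(lo, j);
      for (int k = lo + 1; k <= hi; ++k) {
        const double x = src(k, j);
        if (take_min ? (x < v) : (x > v)) v = x;
      }
      dst(i, j) = v;
    }
  }
}

static NumericMatrix disc_extremum(const NumericMatrix& img, int radius,
                                   bool take_min) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double init = take_min ? std::numeric_limits<double>::infinity()
                               : -std::numeric_limits<double>::infinity();
  std::fill(out.begin(), out.end(), init);
  NumericMatrix vert(nr, nc);
  for (int adj = 0; adj <= radius; ++adj) {
    const int h = (int)std::floor(std::sqrt((double)radius * radius -
                                            (double)adj * adj));
    col_extremum(img, vert, h, take_min);
    for (int sgn = (adj == 0 ? 1 : -1); sgn <= 1; sgn += 2) {
      const int dj = sgn * adj;
      for (int j = 0; j < nc; ++j) {
        const int js = j + dj;
        if (js < 0 || js >= nc) continue;
        for (int i = 0; i < nr; ++i) {
          const double x = vert(i, js);
          double& v = out(i, j);
          if (take_min ? (x < v) : (x > v)) v = x;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gray_erode_disc(NumericMatrix img, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(img);
  return disc_extremum(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix gray_dilate_disc(NumericMatrix img, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(img);
  return disc_extremum(img, radius, false);
}

// Connected-component labeling of a 0/1 mask with 4- or 8-connectivity.
// Labels are assigned contiguously from 1 in column-major scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di4[] = {-1, 1, 0, 0}, dj4[] = {0, 0, -1, 1};
  const int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* di = connectivity == 4 ? di4 : di8;
  const int* dj = connectivity == 4 ? dj4 : dj8;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          const int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Squared distance from each pixel centre of an nr x nc grid to the line
// segment (x0,y0)-(x1,y1), restricted to a bounding box; used to render
// capsule-shaped (segment dilated by a disc) synthetic myotubes quickly.
// [[Rcpp::export]]
NumericMatrix segment_dist2(int nr, int nc, double x0, double y0,
                            double x1, double y1,
                            int rmin, int rmax, int cmin, int cmax) {
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(),
            std::numeric_limits<double>::infinity());
  const double vx = x1 - x0, vy = y1 - y0;
  const double vv = vx * vx + vy * vy;
  rmin = std::max(rmin, 1); cmin = std::max(cmin, 1);
  rmax = std::min(rmax, nr); cmax = std::min(cmax, nc);
  for (int j = cmin - 1; j < cmax; ++j) {
    for (int i = rmin - 1; i < rmax; ++i) {
      const double px = (double)(i + 1), py = (double)(j + 1);
      double t = vv > 0 ? ((px - x0) * vx + (py - y0) * vy) / vv : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      const double dx = px - (x0 + t * vx), dy = py - (y0 + t * vy);
      out(i, j) = dx * dx + dy * dy;
    }
  }
  return out;
}
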