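#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-point counts of other points in half-open distance bins
// (breaks[b], breaks[b+1]].  Returns an n x (length(breaks)-1) matrix.
// Distances are binned on the squared scale to avoid n^2 square roots.
// [[Rcpp::export]]
IntegerMatrix pair_bin_counts_cpp(NumericVector x, NumericVector y,
                                  NumericVector breaks) {
  const int n = x.size();
  const int B = breaks.size() - 1;
  IntegerMatrix out(n, B);
  std::vector<double> br2(B + 1);
  for (int b = 0; b <= B; ++b) br2[b] = breaks[b] * breaks[b];
  const double lo2 = br2[0], hi2 = br2[B];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 <= lo2 || d2 > hi2) continue;
      const int k = int(std::lower_bound(br2.begin(), br2.end(), d2) -
                        br2.begin());
      const int b = k - 1;  // br2[b] < d2 <= br2[b+1]
      out(i, b)++;
      out(j, b)++;
    }
  }
  return out;
}

// Area of {0 <= x <= a, 0 <= y <= b, x^2 + y^2 <= r^2}.
static double quadrant_piece(double a, double b, double r) {
  if (r <= 0.0 || a <= 0.0 || b <= 0.0) return 0.0;
  const double a2 = std::min(a, r);
  const double x1 = (b >= r) ? 0.0 : std::sqrt(r * r - b * b);
  if (a2 <= x1) return a2 * b;
  // flat part up to x1, circular part from x1 to a2
  const double circ = 0.5 * (a2 * std::sqrt(std::max(r * r - a2 * a2, 0.0)) +
                             r * r * std::asin(std::min(a2 / r, 1.0))) -
                      0.5 * (x1 * std::sqrt(std::max(r * r - x1 * x1, 0.0)) +
                             r * r * std::asin(std::min(x1 / r, 1.0)));
  return x1 * b + circ;
}

// Elementwise area of disc(centre (cx,cy), radius r) intersected with
// the rectangle [0,width] x [0,height]; centres must lie inside.
// [[Rcpp::export]]
NumericVector disc_window_area_cpp(NumericVector cx, NumericVector cy,
                                   NumericVector r, double width,
                                   double height) {
  const int n = cx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = quadrant_piece(width - cx[i], height - cy[i], r[i]) +
             quadrant_piece(cx[i], height - cy[i], r[i]) +
             quadrant_piece(width - cx[i], cy[i], r[i]) +
             quadrant_piece(cx[i], cy[i], r[i]);
  }
  return out;
}

// Nearest-neighbour distance for each point (n >= 2).
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < out[i]) out[i] = d2;
      if (d2 < out[j]) out[j] = d2;
    }
  }
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Distance from each reference location to the nearest pattern point.
// [[Rcpp::export]]
NumericVector ref_nn_dist_cpp(NumericVector rx, NumericVector ry,
                              NumericVector px, NumericVector py) {
  const int m = rx.size(), n = px.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      const double dx = rx[i] - px[j], dy = ry[i] - py[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Sequential hard-core placement with compartment quotas.
//
// Candidates are proposed uniformly over the window (using R's RNG, so
// results are reproducible under set.seed); a candidate is accepted iff
// its compartment's quota is not yet filled and it lies at least
// `exclusion` from every accepted point.  A cell grid (cell size >=
// exclusion) limits the hard-core check to the 3x3 neighbourhood.
// Gives up after `max_rejections` consecutive rejections.
// [[Rcpp::export]]
List place_points_cpp(LogicalMatrix mask, double width, double height,
                      int n_tumour, int n_stroma, double exclusion,
                      int max_rejections) {
  const int res_x = mask.nrow(), res_y = mask.ncol();
  const int target = n_tumour + n_stroma;
  std::vector<double> px, py;
  std::vector<int> tumour_flag;
  px.reserve(target); py.reserve(target); tumour_flag.reserve(target);

  const double cell = std::max(exclusion, 1e-9);
  const int gx = std::max(1, int(std::ceil(width / cell)));
  const int gy = std::max(1, int(std::ceil(height / cell)));
  std::vector<std::vector<int> > cells((size_t)gx * gy);

  int got_t = 0, got_s = 0, consec = 0;
  long total_rej = 0;
  while (got_t + got_s < target) {
    if (consec >= max_rejections) break;
    const double x = R::runif(0.0, width);
    const double y = R::runif(0.0, height);
    int ix = int(x / width * res_x);  if (ix >= res_x) ix = res_x - 1;
    int iy = int(y / height * res_y); if (iy >= res_y) iy = res_y - 1;
    const bool in_tumour = mask(ix, iy);
    if ((in_tumour && got_t >= n_tumour) || (!in_tumour && got_s >= n_stroma)) {
      ++consec; ++total_rej;
      continue;
    }
    bool clash = false;
    if (exclusion > 0.0 && !px.empty()) {
      int cx = int(x / cell); if (cx >= gx) cx = gx - 1;
      int cy = int(y / cell); if (cy >= gy) cy = gy - 1;
      const double e2 = exclusion * exclusion;
      for (int ax = std::max(0, cx - 1); ax <= std::min(gx - 1, cx + 1) && !clash; ++ax) {
        for (int ay = std::max(0, cy - 1); ay <= std::min(gy - 1, cy + 1) && !clash; ++ay) {
          const std::vector<int>& bucket = cells[(size_t)ax * gy + ay];
          for (size_t k = 0; k < bucket.size(); ++k) {
            const double dx = x - px[bucket[k]], dy = y - py[bucket[k]];
            if (dx * dx + dy * dy < e2) { clash = true; break; }
          }
        }
      }
    }
    if (clash) {
      ++consec; ++total_rej;
      continue;
    }
    const int idx = (int)px.size();
    px.push_back(x); py.push_back(y);
    tumour_flag.push_back(in_tumour ? 1 : 0);
    if (in_tumour) ++got_t; else ++got_s;
    if (exclusion > 0.0) {
      int cx = int(x / cell); if (cx >= gx) cx = gx - 1;
      int cy = int(y / cell); if (cy >= gy) cy = gy - 1;
      cells[(size_t)cx * gy + cy].push_back(idx);
    }
    consec = 0;
  }
  return List::create(_["x"] = px, _["y"] = py,
                      _["in_tumour"] = tumour_flag,
                      _["filled_tumour"] = got_t,
                      _["filled_stroma"] = got_s,
                      _["complete"] = (got_t + got_s == target),
                      _["rejections"] = (double)total_rej);
}
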