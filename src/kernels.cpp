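#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Nearest-neighbour distance of every point to any *other* point, O(n^2).
// Used by the NNI machinery; the testthat suite checks it against a plain-R
// double loop, so keep this free of shortcuts.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_mean_nn_dist(NumericVector x, NumericVector y) {
  int n = x.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    acc += std::sqrt(best);
  }
  return acc / n;
}

// [[Rcpp::export]]
double cpp_min_pairwise_dist(NumericVector x, NumericVector y) {
  int n = x.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Squared distance from each query location (pixel centre) to the nearest
// stomatal centroid.
// [[Rcpp::export]]
NumericVector cpp_nsd_sq(NumericVector px, NumericVector py,
                         NumericVector sx, NumericVector sy) {
  int np = px.size(), ns = sx.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < ns; ++j) {
      double dx = px[i] - sx[j], dy = py[i] - sy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}

// Scan-line walk over a triangular lattice (constant s, translation tx/ty
// in the lattice frame, rotated into the window frame by theta): for each
// lattice row, the window [0,W]x[0,H] pulls back to an x-interval in the
// lattice frame, and the in-row points are counted by floor arithmetic.
// With build = true the in-window points are appended (window-frame
// coordinates, clamped to the window against rounding).
// theta is restricted to [0, 60) degrees (lattice symmetry), so
// cos(theta) > 0 throughout.
static long tri_scan(double s, double theta, double tx, double ty,
                     double W, double H, bool build,
                     std::vector<double> *outx, std::vector<double> *outy,
                     long stop_above) {
  const double sqrt3 = std::sqrt(3.0);
  double dy = s * sqrt3 / 2.0;
  double ct = std::cos(theta), st = std::sin(theta);
  // lattice-frame y-range of the pulled-back window
  double ylo = -st * W, yhi = ct * H;
  int jlo = (int)std::ceil((ylo - ty) / dy);
  int jhi = (int)std::floor((yhi - ty) / dy);
  long total = 0;
  for (int j = jlo; j <= jhi; ++j) {
    double Y = ty + j * dy;
    // window constraints along the row: 0 <= ct*x - st*Y <= W and
    // 0 <= st*x + ct*Y <= H
    double xlo = (st * Y) / ct, xhi = (W + st * Y) / ct;
    if (st > 0) {
      double lo2 = (0.0 - ct * Y) / st, hi2 = (H - ct * Y) / st;
      if (lo2 > xlo) xlo = lo2;
      if (hi2 < xhi) xhi = hi2;
    } else {
      if (Y < 0 || Y > H) continue;
    }
    if (xhi < xlo) continue;
    double ox = tx + j * s / 2.0;
    int ilo = (int)std::ceil((xlo - ox) / s);
    int ihi = (int)std::floor((xhi - ox) / s);
    if (ihi < ilo) continue;
    total += (ihi - ilo + 1);
    if (!build && total > stop_above) return total;
    if (build) {
      for (int i = ilo; i <= ihi; ++i) {
        double xl = ox + i * s;
        double xw = ct * xl - st * Y;
        double yw = st * xl + ct * Y;
        if (xw < 0) xw = 0; if (xw > W) xw = W;
        if (yw < 0) yw = 0; if (yw > H) yw = H;
        outx->push_back(xw);
        outy->push_back(yw);
      }
    }
  }
  return total;
}

// In-window points of the lattice with the given parameters.
// [[Rcpp::export]]
List cpp_lattice_points(double s, double theta, double tx, double ty,
                        double W, double H) {
  std::vector<double> xs, ys;
  tri_scan(s, theta, tx, ty, W, H, true, &xs, &ys, LONG_MAX);
  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys));
}

// Equilateral triangular lattice conditioned on an exact in-window count.
// Procedure per try: lambda ~ Gamma(n, 1); m ~ Poisson(lambda); build a
// lattice whose areal density is m / (W*H); translate it uniformly over the
// fundamental cell (and rotate uniformly in [0, 60) degrees when rotate is
// true); accept iff exactly n points fall in [0,W] x [0,H]. Rejected tries
// never materialise coordinates. Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List cpp_tri_grid_conditioned(int n, double W, double H, int max_rej,
                              bool rotate = true) {
  const double sqrt3 = std::sqrt(3.0);
  double area = W * H;
  for (int t = 1; t <= max_rej; ++t) {
    double lambda = R::rgamma((double)n, 1.0);
    double m = R::rpois(lambda);
    if (m < 1.0) continue;
    double s = std::sqrt(2.0 / (sqrt3 * (m / area)));  // lattice constant
    double dy = s * sqrt3 / 2.0;                       // row spacing
    double u1 = unif_rand(), u2 = unif_rand();
    double tx = u1 * s + u2 * s / 2.0;  // uniform over fundamental cell
    double ty = u2 * dy;
    double theta = rotate ? unif_rand() * M_PI / 3.0 : 0.0;
    long total = tri_scan(s, theta, tx, ty, W, H, false, NULL, NULL, n);
    if (total != n) continue;
    std::vector<double> xs, ys;
    tri_scan(s, theta, tx, ty, W, H, true, &xs, &ys, LONG_MAX);
    return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys),
                        _["spacing"] = s, _["tx"] = tx, _["ty"] = ty,
                        _["theta"] = theta, _["tries"] = t);
  }
  return List::create(_["x"] = R_NilValue, _["y"] = R_NilValue,
                      _["spacing"] = NA_REAL, _["tx"] = NA_REAL,
                      _["ty"] = NA_REAL, _["theta"] = NA_REAL,
                      _["tries"] = max_rej);
}

// Sequential dart-throwing hard-core process: candidates are uniform on the
// window and kept when at least rmin from every accepted point.
// [[Rcpp::export]]
List cpp_hardcore(int n, double W, double H, double rmin, double max_tries) {
  NumericVector xs(n), ys(n);
  double r2 = rmin * rmin;
  int placed = 0;
  double tries = 0;
  while (placed < n) {
    if (tries >= max_tries)
      return List::create(_["x"] = R_NilValue, _["y"] = R_NilValue,
                          _["placed"] = placed, _["tries"] = tries);
    ++tries;
    double cx = unif_rand() * W, cy = unif_rand() * H;
    bool ok = true;
    for (int j = 0; j < placed; ++j) {
      double dx = cx - xs[j], dy = cy - ys[j];
      if (dx * dx + dy * dy < r2) { ok = false; break; }
    }
    if (ok) { xs[placed] = cx; ys[placed] = cy; ++placed; }
  }
  return List::create(_["x"] = xs, _["y"] = ys,
                      _["placed"] = placed, _["tries"] = tries);
}
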