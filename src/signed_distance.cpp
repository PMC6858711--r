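#include <Rcpp.h>
using namespace Rcpp;

// Exact signed Euclidean distance to a polygon set given as a list of rings
// (n x 2 matrices, vertices in order, last edge implicit). Inside/outside by
// the even-odd rule over all rings, so interior rings act as holes (points
// in a hole get positive distance). Sign convention: negative inside tumor,
// positive outside, 0 on the boundary.

namespace {

struct RingSet {
  std::vector<std::vector<double>> x1, y1, x2, y2;
};

RingSet make_rings(List rings) {
  RingSet R;
  const int nr = rings.size();
  R.x1.resize(nr); R.y1.resize(nr); R.x2.resize(nr); R.y2.resize(nr);
  for (int r = 0; r < nr; ++r) {
    NumericMatrix M = as<NumericMatrix>(rings[r]);
    const int n = M.nrow();
    R.x1[r].resize(n); R.y1[r].resize(n);
    R.x2[r].resize(n); R.y2[r].resize(n);
    for (int j = 0; j < n; ++j) {
      const int k = (j + 1 == n) ? 0 : j + 1;
      R.x1[r][j] = M(j, 0); R.y1[r][j] = M(j, 1);
      R.x2[r][j] = M(k, 0); R.y2[r][j] = M(k, 1);
    }
  }
  return R;
}

double signed_dist(const RingSet& R, double x, double y) {
  double best = R_PosInf;
  int crossings = 0;
  for (size_t r = 0; r < R.x1.size(); ++r) {
    const size_t n = R.x1[r].size();
    const double* X1 = R.x1[r].data(); const double* Y1 = R.y1[r].data();
    const double* X2 = R.x2[r].data(); const double* Y2 = R.y2[r].data();
    for (size_t j = 0; j < n; ++j) {
      const double dx = X2[j] - X1[j], dy = Y2[j] - Y1[j];
      const double len2 = dx * dx + dy * dy;
      double t = len2 > 0.0 ? ((x - X1[j]) * dx + (y - Y1[j]) * dy) / len2 : 0.0;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      const double ex = X1[j] + t * dx - x;
      const double ey = Y1[j] + t * dy - y;
      const double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
      // horizontal ray toward +x, half-open in y to avoid double counts
      if ((Y1[j] > y) != (Y2[j] > y)) {
        const double xint = X1[j] + (y - Y1[j]) / (Y2[j] - Y1[j]) * dx;
        if (xint > x) ++crossings;
      }
    }
  }
  const double d = std::sqrt(best);
  return (crossings % 2 == 1) ? -d : d;
}

inline double pos2(double z) { return z > 0.0 ? z * z : 0.0; }

// Area fraction of the unit square where the plane with mean m and spans
// gx, gy (value m + gx*(u-1/2) + gy*(v-1/2)) is <= t. Closed form.
double frac_below(double t, double m, double gx, double gy) {
  if (t == R_PosInf) return 1.0;
  if (t == R_NegInf) return 0.0;
  const double p = std::abs(gx), q = std::abs(gy);
  const double s = t - m + (p + q) / 2.0;
  if (p + q < 1e-12) return s >= 0.0 ? 1.0 : 0.0;
  if (std::min(p, q) < 1e-12 * std::max(p, q)) {
    double f = s / (p + q);
    return f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f);
  }
  double f = (pos2(s) - pos2(s - p) - pos2(s - q) + pos2(s - p - q)) /
    (2.0 * p * q);
  return f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f);
}

struct BandIntegrator {
  const RingSet* R;
  std::vector<double> edges;  // strictly increasing, may start at -inf
  double bxmin, bymin, bxmax, bymax;
  double min_cell;
  std::vector<double> area;   // per band, um^2

  double clipped_area(double cx, double cy, double s) const {
    const double h = s / 2.0;
    const double fx = std::min(cx + h, bxmax) - std::max(cx - h, bxmin);
    const double fy = std::min(cy + h, bymax) - std::max(cy - h, bymin);
    return (fx > 0.0 && fy > 0.0) ? fx * fy : 0.0;
  }

  void refine(double cx, double cy, double s) {
    const double ca = clipped_area(cx, cy, s);
    if (ca <= 0.0) return;
    const double d = signed_dist(*R, cx, cy);
    const double hd = s * 0.70710678118654752;  // half-diagonal (1-Lipschitz)
    const int nb = (int)edges.size() - 1;
    if (d + hd <= edges[0] || d - hd > edges[nb]) return;
    for (int i = 0; i < nb; ++i) {
      if (d - hd > edges[i] && d + hd <= edges[i + 1]) {
        area[i] += ca;
        return;
      }
    }
    if (s <= min_cell) {
      const double h = s / 2.0;
      const double d00 = signed_dist(*R, cx - h, cy - h);
      const double d10 = signed_dist(*R, cx + h, cy - h);
      const double d01 = signed_dist(*R, cx - h, cy + h);
      const double d11 = signed_dist(*R, cx + h, cy + h);
      const double m = (d00 + d10 + d01 + d11) / 4.0;
      const double gx = ((d10 + d11) - (d00 + d01)) / 2.0;
      const double gy = ((d01 + d11) - (d00 + d10)) / 2.0;
      for (int i = 0; i < nb; ++i) {
        if (d + hd <= edges[i] || d - hd > edges[i + 1]) continue;
        const double f = frac_below(edges[i + 1], m, gx, gy) -
          frac_below(edges[i], m, gx, gy);
        if (f > 0.0) area[i] += f * ca;
      }
      return;
    }
    const double q = s / 4.0;
    refine(cx - q, cy - q, s / 2.0);
    refine(cx + q, cy - q, s / 2.0);
    refine(cx - q, cy + q, s / 2.0);
    refine(cx + q, cy + q, s / 2.0);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_signed_distance(NumericVector px, NumericVector py,
                                  List rings) {
  const RingSet R = make_rings(rings);
  const int np = px.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) out[i] = signed_dist(R, px[i], py[i]);
  return out;
}

// Adaptive quadtree integration of the per-band areas (um^2) of the regions
// {p in bounds : edges[i] < d(p) <= edges[i+1]}. Cells whose distance
// interval provably lies inside one band (or outside all) are resolved
// wholesale; straddling cells are subdivided to min_cell and finished with
// an exact planar-cut fraction from the corner distances.
// [[Rcpp::export]]
NumericVector cpp_band_areas(List rings, NumericVector bounds,
                             NumericVector edges, double min_cell) {
  const RingSet R = make_rings(rings);
  BandIntegrator B;
  B.R = &R;
  B.edges = std::vector<double>(edges.begin(), edges.end());
  B.bxmin = bounds[0]; B.bymin = bounds[1];
  B.bxmax = bounds[2]; B.bymax = bounds[3];
  B.min_cell = min_cell;
  B.area.assign(edges.size() - 1, 0.0);
  const double w = B.bxmax - B.bxmin, h = B.bymax - B.bymin;
  const double s0 = std::max(w, h) / 16.0;
  const int nx = (int)std::ceil(w / s0), ny = (int)std::ceil(h / s0);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix)
      B.refine(B.bxmin + (ix + 0.5) * s0, B.bymin + (iy + 0.5) * s0, s0);
  return wrap(B.area);
}
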