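#include <Rcpp.h>
using namespace Rcpp;

// Even-odd point-in-polygon test (open polygon, no repeated last vertex).
static bool pnpoly(double x, double y, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// Cell centres of the absolute axis-aligned `step` lattice that fall inside
// the polygon. The lattice is anchored at the coordinate origin so identical
// inputs always produce identical grids.
// [[Rcpp::export(name = ".grid_points_cpp")]]
NumericMatrix grid_points_cpp(NumericMatrix poly, double step) {
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < poly.nrow(); ++i) {
    xmin = std::min(xmin, poly(i, 0)); xmax = std::max(xmax, poly(i, 0));
    ymin = std::min(ymin, poly(i, 1)); ymax = std::max(ymax, poly(i, 1));
  }
  long i0 = (long)std::floor(xmin / step), i1 = (long)std::ceil(xmax / step);
  long j0 = (long)std::floor(ymin / step), j1 = (long)std::ceil(ymax / step);
  std::vector<double> xs, ys;
  for (long i = i0; i < i1; ++i) {
    double x = (i + 0.5) * step;
    for (long j = j0; j < j1; ++j) {
      double y = (j + 0.5) * step;
      if (pnpoly(x, y, poly)) { xs.push_back(x); ys.push_back(y); }
    }
  }
  NumericMatrix out(xs.size(), 2);
  for (size_t k = 0; k < xs.size(); ++k) { out(k, 0) = xs[k]; out(k, 1) = ys[k]; }
  return out;
}

// Does the ray from ground point (px, py, 0) along unit direction u hit the
// vertical extrusion of `poly` up to height h?
static bool hits_extrusion(double px, double py, const NumericMatrix& poly,
                           double h, double ux, double uy, double uz) {
  if (pnpoly(px, py, poly)) return true;  // start inside the footprint
  int n = poly.nrow();
  double tmin = R_PosInf;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double ax = poly(j, 0), ay = poly(j, 1);
    double dx = poly(i, 0) - ax, dy = poly(i, 1) - ay;
    double denom = ux * dy - uy * dx;
    if (std::fabs(denom) < 1e-14) continue;  // ray parallel to edge
    double wx = ax - px, wy = ay - py;
    double t = (wx * dy - wy * dx) / denom;
    double s = (wx * uy - wy * ux) / denom;
    if (t > 1e-9 && s >= 0.0 && s < 1.0) tmin = std::min(tmin, t);
  }
  // Entry point of the ray into the footprint; the ray is inside the solid
  // there iff it has not yet climbed above the roof.
  return R_finite(tmin) && tmin * uz <= h;
}

// Does the ray hit the axis-aligned crown ellipsoid centred at (cx, cy, cz)
// with horizontal semi-axis rx and vertical semi-axis rz?
static bool hits_ellipsoid(double px, double py, double cx, double cy,
                           double cz, double rx, double rz,
                           double ux, double uy, double uz) {
  double ox = (px - cx) / rx, oy = (py - cy) / rx, oz = (0.0 - cz) / rz;
  double vx = ux / rx, vy = uy / rx, vz = uz / rz;
  double a = vx * vx + vy * vy + vz * vz;
  double b = 2.0 * (ox * vx + oy * vy + oz * vz);
  double c = ox * ox + oy * oy + oz * oz - 1.0;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0) return false;
  double t2 = (-b + std::sqrt(disc)) / (2.0 * a);  // far intersection
  return t2 > 1e-9;  // any forward intersection (or start inside the crown)
}

// Classify each grid point: 0 = sun, 1 = tree shade, 2 = building shade.
// Building occlusion takes precedence over tree occlusion.
// [[Rcpp::export(name = ".cast_rays_cpp")]]
IntegerVector cast_rays_cpp(NumericMatrix pts, List footprints,
                            NumericVector heights, NumericMatrix trees,
                            NumericVector u) {
  int npt = pts.nrow(), nb = footprints.size(), nt = trees.nrow();
  double ux = u[0], uy = u[1], uz = u[2];
  std::vector<NumericMatrix> fps;
  fps.reserve(nb);
  for (int b = 0; b < nb; ++b) fps.push_back(as<NumericMatrix>(footprints[b]));
  IntegerVector out(npt);
  for (int i = 0; i < npt; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    int code = 0;
    for (int b = 0; b < nb; ++b) {
      if (hits_extrusion(px, py, fps[b], heights[b], ux, uy, uz)) { code = 2; break; }
    }
    if (code == 0) {
      for (int t = 0; t < nt; ++t) {
        if (hits_ellipsoid(px, py, trees(t, 0), trees(t, 1), trees(t, 2),
                           trees(t, 3), trees(t, 4), ux, uy, uz)) { code = 1; break; }
      }
    }
    out[i] = code;
  }
  return out;
}
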