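// Compiled kernels for the spherocylinder ("capsule") cell model:
//  - segment-segment closest points (contact geometry)
//  - broad-phase binned contact finding
//  - regularized impulse relaxation to mechanical quasi-equilibrium
//  - two-step T6SS needle hit detection
// All cells live in the z = 0 plane; a cell is a segment of half-length h
// (centre x,y, unit axis ax,ay) swept by a disc of radius R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// Closest points of segments P(s) = p0 + s(p1-p0), Q(t) = q0 + t(q1-q0),
// s,t in [0,1]. Near-parallel pairs break the tie at the midpoint of the
// projected overlap interval, so symmetric configurations stay symmetric.
static void seg_seg_closest(double p0x, double p0y, double p1x, double p1y,
                            double q0x, double q0y, double q1x, double q1y,
                            double &s, double &t) {
  const double ux = p1x - p0x, uy = p1y - p0y;
  const double vx = q1x - q0x, vy = q1y - q0y;
  const double wx = p0x - q0x, wy = p0y - q0y;
  const double a = ux * ux + uy * uy;
  const double b = ux * vx + uy * vy;
  const double c = vx * vx + vy * vy;
  const double d = ux * wx + uy * wy;
  const double e = vx * wx + vy * wy;
  const double EPS = 1e-14;

  if (a <= EPS && c <= EPS) { s = 0.0; t = 0.0; return; }
  if (a <= EPS) { s = 0.0; t = clamp01(e / c); return; }
  if (c <= EPS) { t = 0.0; s = clamp01(-d / a); return; }

  const double D = a * c - b * b;
  if (D > 1e-12 * a * c) {
    s = clamp01((b * e - c * d) / D);
    t = (b * s + e) / c;
    if (t < 0.0)      { t = 0.0; s = clamp01(-d / a); }
    else if (t > 1.0) { t = 1.0; s = clamp01((b - d) / a); }
  } else {
    // parallel: project Q's endpoints onto P's parameter axis
    double t0 = -d / a;          // q0
    double t1 = (b - d) / a;     // q1
    double lo = t0 < t1 ? t0 : t1;
    double hi = t0 < t1 ? t1 : t0;
    double l = lo > 0.0 ? lo : 0.0;
    double hh = hi < 1.0 ? hi : 1.0;
    if (l <= hh) s = 0.5 * (l + hh);
    else s = (hi < 0.0) ? 0.0 : 1.0;
    t = clamp01((b * s + e) / c);
    if (t <= 0.0 || t >= 1.0) s = clamp01((b * t - d) / a);
  }
}

// [[Rcpp::export]]
List seg_seg_closest_cpp(NumericVector p0, NumericVector p1,
                         NumericVector q0, NumericVector q1) {
  double s, t;
  seg_seg_closest(p0[0], p0[1], p1[0], p1[1], q0[0], q0[1], q1[0], q1[1], s, t);
  double c1x = p0[0] + s * (p1[0] - p0[0]);
  double c1y = p0[1] + s * (p1[1] - p0[1]);
  double c2x = q0[0] + t * (q1[0] - q0[0]);
  double c2y = q0[1] + t * (q1[1] - q0[1]);
  double dist = std::sqrt((c2x - c1x) * (c2x - c1x) + (c2y - c1y) * (c2y - c1y));
  return List::create(_["s"] = s, _["t"] = t, _["dist"] = dist,
                      _["c1"] = NumericVector::create(c1x, c1y),
                      _["c2"] = NumericVector::create(c2x, c2y));
}

struct Contact {
  int i, j;            // 0-based
  double d;            // signed gap (negative = overlap)
  double wix, wiy, wjx, wjy;
  double nx, ny;       // unit normal from i to j
};

// All pairs with gap < cutoff; near-linear via uniform binning on centres.
static void find_contacts_impl(const NumericVector &x, const NumericVector &y,
                               const NumericVector &ax, const NumericVector &ay,
                               const NumericVector &h, double R, double cutoff,
                               std::vector<Contact> &out) {
  const int n = x.size();
  out.clear();
  if (n < 2) return;
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (h[i] > hmax) hmax = h[i];
  const double reach = 2.0 * hmax + 2.0 * R + std::max(cutoff, 0.0) + 1e-9;

  std::unordered_map<int64_t, std::vector<int> > bins;
  bins.reserve(2 * n);
  std::vector<int64_t> keyx(n), keyy(n);
  for (int i = 0; i < n; ++i) {
    keyx[i] = (int64_t)std::floor(x[i] / reach);
    keyy[i] = (int64_t)std::floor(y[i] / reach);
    bins[(keyx[i] << 32) ^ (keyy[i] & 0xffffffffLL)].push_back(i);
  }

  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        int64_t key = ((keyx[i] + dx) << 32) ^ ((keyy[i] + dy) & 0xffffffffLL);
        std::unordered_map<int64_t, std::vector<int> >::const_iterator it = bins.find(key);
        if (it == bins.end()) continue;
        const std::vector<int> &cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          if (j <= i) continue;
          double cdx = x[j] - x[i], cdy = y[j] - y[i];
          double rad = h[i] + h[j] + 2.0 * R + cutoff;
          if (cdx * cdx + cdy * cdy > rad * rad) continue;
          double p0x = x[i] - ax[i] * h[i], p0y = y[i] - ay[i] * h[i];
          double p1x = x[i] + ax[i] * h[i], p1y = y[i] + ay[i] * h[i];
          double q0x = x[j] - ax[j] * h[j], q0y = y[j] - ay[j] * h[j];
          double q1x = x[j] + ax[j] * h[j], q1y = y[j] + ay[j] * h[j];
          double s, t;
          seg_seg_closest(p0x, p0y, p1x, p1y, q0x, q0y, q1x, q1y, s, t);
          double wix = p0x + s * (p1x - p0x), wiy = p0y + s * (p1y - p0y);
          double wjx = q0x + t * (q1x - q0x), wjy = q0y + t * (q1y - q0y);
          double ddx = wjx - wix, ddy = wjy - wiy;
          double dist = std::sqrt(ddx * ddx + ddy * ddy);
          double gap = dist - 2.0 * R;
          if (gap >= cutoff) continue;
          Contact con;
          con.i = i; con.j = j; con.d = gap;
          con.wix = wix; con.wiy = wiy; con.wjx = wjx; con.wjy = wjy;
          if (dist > 1e-12) { con.nx = ddx / dist; con.ny = ddy / dist; }
          else {
            // coincident witness points: fall back to centre separation
            double cl = std::sqrt(cdx * cdx + cdy * cdy);
            if (cl > 1e-12) { con.nx = cdx / cl; con.ny = cdy / cl; }
            else { con.nx = 1.0; con.ny = 0.0; }
          }
          out.push_back(con);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix find_contacts_cpp(NumericVector x, NumericVector y,
                                NumericVector ax, NumericVector ay,
                                NumericVector h, double R, double cutoff) {
  std::vector<Contact> cons;
  find_contacts_impl(x, y, ax, ay, h, R, cutoff, cons);
  NumericMatrix out(cons.size(), 9);
  for (size_t k = 0; k < cons.size(); ++k) {
    out(k, 0) = cons[k].i + 1;
    out(k, 1) = cons[k].j + 1;
    out(k, 2) = cons[k].d;
    out(k, 3) = cons[k].wix; out(k, 4) = cons[k].wiy;
    out(k, 5) = cons[k].wjx; out(k, 6) = cons[k].wjy;
    out(k, 7) = cons[k].nx;  out(k, 8) = cons[k].ny;
  }
  return out;
}

// Jacobi-preconditioned CG for (A'A + alpha*M) p = -A'd built from contacts.
// DOFs per body: (x, y, theta). Returns false if CG failed to converge.
static bool solve_impulses(const std::vector<Contact> &cons,
                           const NumericVector &x, const NumericVector &y,
                           const std::vector<double> &Mdiag,
                           double alpha, std::vector<double> &p) {
  const int ndof = (int)Mdiag.size();
  const int nc = (int)cons.size();
  std::vector<double> gi(nc), gj(nc);
  for (int k = 0; k < nc; ++k) {
    const Contact &c = cons[k];
    double lix = c.wix - x[c.i], liy = c.wiy - y[c.i];
    double ljx = c.wjx - x[c.j], ljy = c.wjy - y[c.j];
    gi[k] = lix * c.ny - liy * c.nx;   // d(gap)/d(theta_i) sign folded below
    gj[k] = ljx * c.ny - ljy * c.nx;
  }
  std::vector<double> b(ndof, 0.0), diag(ndof);
  for (int q = 0; q < ndof; ++q) diag[q] = alpha * Mdiag[q];
  for (int k = 0; k < nc; ++k) {
    const Contact &c = cons[k];
    int bi = 3 * c.i, bj = 3 * c.j;
    // row_k = [-nx,-ny,-gi | +nx,+ny,+gj];  b = -A'd
    b[bi]     += c.nx * c.d;  b[bi + 1] += c.ny * c.d;  b[bi + 2] += gi[k] * c.d;
    b[bj]     -= c.nx * c.d;  b[bj + 1] -= c.ny * c.d;  b[bj + 2] -= gj[k] * c.d;
    diag[bi]     += c.nx * c.nx; diag[bi + 1] += c.ny * c.ny; diag[bi + 2] += gi[k] * gi[k];
    diag[bj]     += c.nx * c.nx; diag[bj + 1] += c.ny * c.ny; diag[bj + 2] += gj[k] * gj[k];
  }

  std::vector<double> r(b), z(ndof), dvec(ndof), Ad(ndof);
  std::fill(p.begin(), p.end(), 0.0);
  double bnorm2 = 0.0;
  for (int q = 0; q < ndof; ++q) bnorm2 += b[q] * b[q];
  if (bnorm2 < 1e-30) return true;
  for (int q = 0; q < ndof; ++q) z[q] = r[q] / diag[q];
  dvec = z;
  double rz = 0.0;
  for (int q = 0; q < ndof; ++q) rz += r[q] * z[q];
  // residuals ~1e-3 of b are far below relax_tol; no need to over-converge
  const double tol2 = 1e-6 * bnorm2;
  const int maxit = 200;
  for (int it = 0; it < maxit; ++it) {
    // Ad = (A'A + alpha M) d
    for (int q = 0; q < ndof; ++q) Ad[q] = alpha * Mdiag[q] * dvec[q];
    for (int k = 0; k < nc; ++k) {
      const Contact &c = cons[k];
      int bi = 3 * c.i, bj = 3 * c.j;
      double row = -c.nx * dvec[bi] - c.ny * dvec[bi + 1] - gi[k] * dvec[bi + 2]
                 +  c.nx * dvec[bj] + c.ny * dvec[bj + 1] + gj[k] * dvec[bj + 2];
      Ad[bi]     -= c.nx * row; Ad[bi + 1] -= c.ny * row; Ad[bi + 2] -= gi[k] * row;
      Ad[bj]     += c.nx * row; Ad[bj + 1] += c.ny * row; Ad[bj + 2] += gj[k] * row;
    }
    double dAd = 0.0;
    for (int q = 0; q < ndof; ++q) dAd += dvec[q] * Ad[q];
    if (dAd <= 0.0) return false;
    double alp = rz / dAd;
    double rnorm2 = 0.0;
    for (int q = 0; q < ndof; ++q) {
      p[q] += alp * dvec[q];
      r[q] -= alp * Ad[q];
      rnorm2 += r[q] * r[q];
    }
    if (rnorm2 < tol2) return true;
    double rznew = 0.0;
    for (int q = 0; q < ndof; ++q) { z[q] = r[q] / diag[q]; rznew += r[q] * z[q]; }
    double beta = rznew / rz;
    rz = rznew;
    for (int q = 0; q < ndof; ++q) dvec[q] = z[q] + beta * dvec[q];
  }
  return false;
}

// [[Rcpp::export]]
List relax_cpp(NumericVector x, NumericVector y,
               NumericVector ax, NumericVector ay,
               NumericVector h, double R,
               NumericVector drag_t, NumericVector drag_r,
               double alpha, double tol, int max_iter) {
  const int n = x.size();
  NumericVector X = clone(x), Y = clone(y), AX = clone(ax), AY = clone(ay);
  std::vector<double> Mdiag(3 * n);
  for (int i = 0; i < n; ++i) {
    Mdiag[3 * i] = drag_t[i];
    Mdiag[3 * i + 1] = drag_t[i];
    Mdiag[3 * i + 2] = drag_r[i];
  }
  std::vector<Contact> cons;
  std::vector<double> p(3 * n);
  double max_ov_init = 0.0, max_ov = 0.0;
  int iters = 0;
  double alpha_used = alpha;
  bool warned = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    find_contacts_impl(X, Y, AX, AY, h, R, 0.0, cons);
    max_ov = 0.0;
    for (size_t k = 0; k < cons.size(); ++k)
      if (-cons[k].d > max_ov) max_ov = -cons[k].d;
    if (iter == 0) max_ov_init = max_ov;
    if (max_ov < tol) break;
    iters = iter + 1;

    bool ok = false;
    double a_try = alpha_used;
    for (int esc = 0; esc < 4; ++esc) {
      ok = solve_impulses(cons, X, Y, Mdiag, a_try, p);
      if (ok) break;
      a_try *= 10.0;   // singular/ill-conditioned system: escalate regularization
    }
    if (!ok) { warned = true; break; }
    if (a_try != alpha_used) { alpha_used = a_try; warned = true; }

    for (int i = 0; i < n; ++i) {
      X[i] += p[3 * i];
      Y[i] += p[3 * i + 1];
      double th = p[3 * i + 2];
      if (th > 0.5) th = 0.5; else if (th < -0.5) th = -0.5;
      double ca = std::cos(th), sa = std::sin(th);
      double nax = ca * AX[i] - sa * AY[i];
      double nay = sa * AX[i] + ca * AY[i];
      double norm = std::sqrt(nax * nax + nay * nay);
      AX[i] = nax / norm; AY[i] = nay / norm;
    }
  }
  // final overlap after last impulse application
  find_contacts_impl(X, Y, AX, AY, h, R, 0.0, cons);
  max_ov = 0.0;
  for (size_t k = 0; k < cons.size(); ++k)
    if (-cons[k].d > max_ov) max_ov = -cons[k].d;

  return List::create(_["x"] = X, _["y"] = Y, _["ax"] = AX, _["ay"] = AY,
                      _["iterations"] = iters,
                      _["max_overlap_initial"] = max_ov_init,
                      _["max_overlap_final"] = max_ov,
                      _["alpha_used"] = alpha_used,
                      _["warned"] = warned);
}

static inline double point_seg_dist(double px, double py,
                                    double q0x, double q0y, double q1x, double q1y) {
  double vx = q1x - q0x, vy = q1y - q0y;
  double c2 = vx * vx + vy * vy;
  double t = 0.0;
  if (c2 > 1e-14) t = clamp01(((px - q0x) * vx + (py - q0y) * vy) / c2);
  double cx = q0x + t * vx, cy = q0y + t * vy;
  return std::sqrt((px - cx) * (px - cx) + (py - cy) * (py - cy));
}

// Two-step hit detection. A needle is a segment origin -> origin + len*dir.
// Step (i): candidate iff min segment-segment distance < R - Lpen.
// Step (ii): entry point = nearest crossing of the capsule surface (distance
// R from the axis segment) along the needle; found by bisection between the
// origin (outside) and the closest-approach parameter (inside). A needle
// stops at the first cell it enters (smallest entry parameter).
// [[Rcpp::export]]
NumericMatrix detect_hits_cpp(NumericMatrix origin, NumericMatrix dir,
                              NumericVector len, IntegerVector source,
                              NumericVector x, NumericVector y,
                              NumericVector ax, NumericVector ay,
                              NumericVector h, double R, double Lpen) {
  const int m = origin.nrow();
  const int n = x.size();
  std::vector<double> res_needle, res_target, res_ex, res_ey, res_s;

  for (int k = 0; k < m; ++k) {
    const double ox = origin(k, 0), oy = origin(k, 1);
    const double dxn = dir(k, 0), dyn = dir(k, 1);
    const double L = len[k];
    const double ex_ = ox + L * dxn, ey_ = oy + L * dyn;
    int best = -1;
    double best_s = 0.0, best_px = 0.0, best_py = 0.0;

    for (int j = 0; j < n; ++j) {
      if (j + 1 == source[k]) continue;
      // cheap reject: bounding circles
      double bx = x[j] - ox, by = y[j] - oy;
      double reach = h[j] + R + L;
      if (bx * bx + by * by > reach * reach) continue;
      double q0x = x[j] - ax[j] * h[j], q0y = y[j] - ay[j] * h[j];
      double q1x = x[j] + ax[j] * h[j], q1y = y[j] + ay[j] * h[j];
      double s, t;
      seg_seg_closest(ox, oy, ex_, ey_, q0x, q0y, q1x, q1y, s, t);
      double cx = ox + s * (ex_ - ox), cy = oy + s * (ey_ - oy);
      double dmin = point_seg_dist(cx, cy, q0x, q0y, q1x, q1y);
      if (dmin >= R - Lpen) continue;          // step (i) failed

      double s_entry;
      double f0 = point_seg_dist(ox, oy, q0x, q0y, q1x, q1y) - R;
      if (f0 < 0.0) {
        s_entry = 0.0;                         // origin already within the capsule
      } else {
        double lo = 0.0, hi = s * L;           // f(lo) > 0 >= f(hi)
        for (int it = 0; it < 60; ++it) {
          double mid = 0.5 * (lo + hi);
          double fm = point_seg_dist(ox + mid * dxn, oy + mid * dyn,
                                     q0x, q0y, q1x, q1y) - R;
          if (fm > 0.0) lo = mid; else hi = mid;
        }
        s_entry = 0.5 * (lo + hi);
      }
      if (best < 0 || s_entry < best_s) {
        best = j;
        best_s = s_entry;
        best_px = ox + s_entry * dxn;
        best_py = oy + s_entry * dyn;
      }
    }
    if (best >= 0) {
      res_needle.push_back(k + 1);
      res_target.push_back(best + 1);
      res_ex.push_back(best_px);
      res_ey.push_back(best_py);
      res_s.push_back(best_s);
    }
  }
  NumericMatrix out(res_needle.size(), 5);
  for (size_t k = 0; k < res_needle.size(); ++k) {
    out(k, 0) = res_needle[k];
    out(k, 1) = res_target[k];
    out(k, 2) = res_ex[k];
    out(k, 3) = res_ey[k];
    out(k, 4) = res_s[k];
  }
  return out;
}

// Smallest gap between a candidate capsule and all placed capsules
// (used by rejection-sampling placement).
// [[Rcpp::export]]
double min_gap_cpp(NumericVector x, NumericVector y,
                   NumericVector ax, NumericVector ay, NumericVector h,
                   double R, double cx, double cy,
                   double cax, double cay, double ch) {
  const int n = x.size();
  double best = R_PosInf;
  double p0x = cx - cax * ch, p0y = cy - cay * ch;
  double p1x = cx + cax * ch, p1y = cy + cay * ch;
  for (int i = 0; i < n; ++i) {
    double q0x = x[i] - ax[i] * h[i], q0y = y[i] - ay[i] * h[i];
    double q1x = x[i] + ax[i] * h[i], q1y = y[i] + ay[i] * h[i];
    double s, t;
    seg_seg_closest(p0x, p0y, p1x, p1y, q0x, q0y, q1x, q1y, s, t);
    double c1x = p0x + s * (p1x - p0x), c1y = p0y + s * (p1y - p0y);
    double c2x = q0x + t * (q1x - q0x), c2y = q0y + t * (q1y - q0y);
    double d = std::sqrt((c2x - c1x) * (c2x - c1x) + (c2y - c1y) * (c2y - c1y)) - 2.0 * R;
    if (d < best) best = d;
  }
  return best;
}
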