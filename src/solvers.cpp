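#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian blur with replicated (Neumann) boundaries.
// sigma is in voxel units per axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector arr, IntegerVector dim,
                        NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + rad];
    }
    for (double &kv : ker) kv /= sum;
    int n[3] = {nx, ny, nz};
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          int c[3] = {i, j, k};
          for (int t = -rad; t <= rad; ++t) {
            int cc[3] = {i, j, k};
            cc[axis] = clampi(c[axis] + t, 0, n[axis] - 1);
            acc += ker[t + rad] * a[idx3(cc[0], cc[1], cc[2], nx, ny)];
          }
          b[idx3(i, j, k, nx, ny)] = acc;
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Number of centres within `radius` of each voxel centre.
// [[Rcpp::export]]
IntegerVector cpp_ball_counts(NumericMatrix centers, NumericVector origin,
                              NumericVector voxel, IntegerVector dim,
                              double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(nx * ny * nz, 0);
  double r2 = radius * radius;
  for (int c = 0; c < centers.nrow(); ++c) {
    double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    int i0 = clampi((int)std::floor((cx - radius - origin[0]) / voxel[0]), 0, nx - 1);
    int i1 = clampi((int)std::ceil((cx + radius - origin[0]) / voxel[0]), 0, nx - 1);
    int j0 = clampi((int)std::floor((cy - radius - origin[1]) / voxel[1]), 0, ny - 1);
    int j1 = clampi((int)std::ceil((cy + radius - origin[1]) / voxel[1]), 0, ny - 1);
    int k0 = clampi((int)std::floor((cz - radius - origin[2]) / voxel[2]), 0, nz - 1);
    int k1 = clampi((int)std::ceil((cz + radius - origin[2]) / voxel[2]), 0, nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * voxel[0] - cx;
          double dy = origin[1] + j * voxel[1] - cy;
          double dz = origin[2] + k * voxel[2] - cz;
          if (dx * dx + dy * dy + dz * dz <= r2) out[idx3(i, j, k, nx, ny)]++;
        }
  }
  return out;
}

// Distance to nearest and second-nearest centre per voxel, and the index
// (1-based) of the nearest centre.
// [[Rcpp::export]]
List cpp_nearest_two(NumericMatrix centers, NumericVector origin,
                     NumericVector voxel, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nv = nx * ny * nz, nc = centers.nrow();
  NumericVector d1(nv, R_PosInf), d2(nv, R_PosInf);
  IntegerVector idx(nv, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double px = origin[0] + i * voxel[0];
        double py = origin[1] + j * voxel[1];
        double pz = origin[2] + k * voxel[2];
        double b1 = R_PosInf, b2 = R_PosInf; int bi = 0;
        for (int c = 0; c < nc; ++c) {
          double dx = centers(c, 0) - px, dy = centers(c, 1) - py,
                 dz = centers(c, 2) - pz;
          double d = dx * dx + dy * dy + dz * dz;
          if (d < b1) { b2 = b1; b1 = d; bi = c + 1; }
          else if (d < b2) b2 = d;
        }
        int v = idx3(i, j, k, nx, ny);
        d1[v] = std::sqrt(b1); d2[v] = std::sqrt(b2); idx[v] = bi;
      }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["idx"] = idx);
}

// Unsigned distance from each grid node to the nearest cloud point.
// [[Rcpp::export]]
NumericVector cpp_distance_field(NumericMatrix pts, NumericVector origin,
                                 NumericVector spacing, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double px = origin[0] + i * spacing[0];
        double py = origin[1] + j * spacing[1];
        double pz = origin[2] + k * spacing[2];
        double best = R_PosInf;
        for (int c = 0; c < np; ++c) {
          double dx = pts(c, 0) - px, dy = pts(c, 1) - py, dz = pts(c, 2) - pz;
          double d = dx * dx + dy * dy + dz * dz;
          if (d < best) best = d;
        }
        out[idx3(i, j, k, nx, ny)] = std::sqrt(best);
      }
  return out;
}

// Generalized subjective-surface evolution
//   du/dt = wa grad(g).grad(u) + wc g |grad u| div(grad u / |grad u|)
// semi-implicit finite-volume scheme on the voxel grid: the curvature term
// is implicit (Evans-Spruck regularized, 7-point stencil, SOR solve per
// step, zero-flux boundaries), the edge-advection term explicit with upwind
// differences.  Returns the steady state, iteration count and a per-step
// trace (max change, min u, max u) so the discrete maximum principle can be
// checked from outside.
// [[Rcpp::export]]
List cpp_gsubsurf_evolve(NumericVector u0, NumericVector g, IntegerVector dim,
                         NumericVector h, double wa, double wc, double tau,
                         double eps, double tol, int max_iter,
                         double sor_omega = 1.2, int sor_sweeps = 200,
                         double sor_tol = 1e-9) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nv = nx * ny * nz;
  std::vector<double> u(u0.begin(), u0.end()), un(nv), gx(nv), gy(nv), gz(nv);
  std::vector<double> gradmag(nv);
  // precompute grad g (central differences, Neumann)
  std::vector<double> dgx(nv), dgy(nv), dgz(nv);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        int ip = idx3(clampi(i + 1, 0, nx - 1), j, k, nx, ny);
        int im = idx3(clampi(i - 1, 0, nx - 1), j, k, nx, ny);
        int jp = idx3(i, clampi(j + 1, 0, ny - 1), k, nx, ny);
        int jm = idx3(i, clampi(j - 1, 0, ny - 1), k, nx, ny);
        int kp = idx3(i, j, clampi(k + 1, 0, nz - 1), nx, ny);
        int km = idx3(i, j, clampi(k - 1, 0, nz - 1), nx, ny);
        dgx[v] = (g[ip] - g[im]) / (2 * h[0]);
        dgy[v] = (g[jp] - g[jm]) / (2 * h[1]);
        dgz[v] = (g[kp] - g[km]) / (2 * h[2]);
      }
  std::vector<double> trace_diff, trace_min, trace_max;
  std::vector<double> rhs(nv), diag(nv);
  std::vector<double> ax(nv), axm(nv), ay(nv), aym(nv), az(nv), azm(nv);
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // node gradients of u^n (central, Neumann) and regularized magnitude
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int v = idx3(i, j, k, nx, ny);
          int ip = idx3(clampi(i + 1, 0, nx - 1), j, k, nx, ny);
          int im = idx3(clampi(i - 1, 0, nx - 1), j, k, nx, ny);
          int jp = idx3(i, clampi(j + 1, 0, ny - 1), k, nx, ny);
          int jm = idx3(i, clampi(j - 1, 0, ny - 1), k, nx, ny);
          int kp = idx3(i, j, clampi(k + 1, 0, nz - 1), nx, ny);
          int km = idx3(i, j, clampi(k - 1, 0, nz - 1), nx, ny);
          gx[v] = (u[ip] - u[im]) / (2 * h[0]);
          gy[v] = (u[jp] - u[jm]) / (2 * h[1]);
          gz[v] = (u[kp] - u[km]) / (2 * h[2]);
          gradmag[v] = std::sqrt(eps * eps + gx[v] * gx[v] + gy[v] * gy[v] +
                                 gz[v] * gz[v]);
        }
    // face coefficients and rhs
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int v = idx3(i, j, k, nx, ny);
          double base = tau * wc * g[v] * gradmag[v];
          auto face = [&](int vn, double du_n, int axis) {
            // face gradient: normal component exact, tangential averaged
            double tx = 0.5 * (gx[v] + gx[vn]);
            double ty = 0.5 * (gy[v] + gy[vn]);
            double tz = 0.5 * (gz[v] + gz[vn]);
            double comp[3] = {tx, ty, tz};
            comp[axis] = du_n;
            double mag = std::sqrt(eps * eps + comp[0] * comp[0] +
                                   comp[1] * comp[1] + comp[2] * comp[2]);
            return base / (h[axis] * h[axis] * mag);
          };
          int ip = (i + 1 < nx) ? idx3(i + 1, j, k, nx, ny) : -1;
          int im = (i - 1 >= 0) ? idx3(i - 1, j, k, nx, ny) : -1;
          int jp = (j + 1 < ny) ? idx3(i, j + 1, k, nx, ny) : -1;
          int jm = (j - 1 >= 0) ? idx3(i, j - 1, k, nx, ny) : -1;
          int kp = (k + 1 < nz) ? idx3(i, j, k + 1, nx, ny) : -1;
          int km = (k - 1 >= 0) ? idx3(i, j, k - 1, nx, ny) : -1;
          ax[v] = ip >= 0 ? face(ip, (u[ip] - u[v]) / h[0], 0) : 0;
          axm[v] = im >= 0 ? face(im, (u[v] - u[im]) / h[0], 0) : 0;
          ay[v] = jp >= 0 ? face(jp, (u[jp] - u[v]) / h[1], 1) : 0;
          aym[v] = jm >= 0 ? face(jm, (u[v] - u[jm]) / h[1], 1) : 0;
          az[v] = kp >= 0 ? face(kp, (u[kp] - u[v]) / h[2], 2) : 0;
          azm[v] = km >= 0 ? face(km, (u[v] - u[km]) / h[2], 2) : 0;
          diag[v] = 1 + ax[v] + axm[v] + ay[v] + aym[v] + az[v] + azm[v];
          // explicit upwind edge advection wa grad(g).grad(u)
          double adv = 0;
          if (wa != 0) {
            double vx = wa * dgx[v], vy = wa * dgy[v], vz = wa * dgz[v];
            double fdx = (ip >= 0 ? (u[ip] - u[v]) : 0) / h[0];
            double bdx = (im >= 0 ? (u[v] - u[im]) : 0) / h[0];
            double fdy = (jp >= 0 ? (u[jp] - u[v]) : 0) / h[1];
            double bdy = (jm >= 0 ? (u[v] - u[jm]) : 0) / h[1];
            double fdz = (kp >= 0 ? (u[kp] - u[v]) : 0) / h[2];
            double bdz = (km >= 0 ? (u[v] - u[km]) : 0) / h[2];
            adv += std::max(vx, 0.0) * fdx + std::min(vx, 0.0) * bdx;
            adv += std::max(vy, 0.0) * fdy + std::min(vy, 0.0) * bdy;
            adv += std::max(vz, 0.0) * fdz + std::min(vz, 0.0) * bdz;
          }
          rhs[v] = u[v] + tau * adv;
        }
    // SOR sweeps for the linear system
    un = u;
    double resid = 0;
    for (int sweep = 0; sweep < sor_sweeps; ++sweep) {
      resid = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int v = idx3(i, j, k, nx, ny);
            double acc = rhs[v];
            if (i + 1 < nx) acc += ax[v] * un[idx3(i + 1, j, k, nx, ny)];
            if (i - 1 >= 0) acc += axm[v] * un[idx3(i - 1, j, k, nx, ny)];
            if (j + 1 < ny) acc += ay[v] * un[idx3(i, j + 1, k, nx, ny)];
            if (j - 1 >= 0) acc += aym[v] * un[idx3(i, j - 1, k, nx, ny)];
            if (k + 1 < nz) acc += az[v] * un[idx3(i, j, k + 1, nx, ny)];
            if (k - 1 >= 0) acc += azm[v] * un[idx3(i, j, k - 1, nx, ny)];
            double unew = un[v] + sor_omega * (acc / diag[v] - un[v]);
            double ch = std::fabs(unew - un[v]);
            if (ch > resid) resid = ch;
            un[v] = unew;
          }
      if (resid < sor_tol) break;
    }
    if (!(resid < 1e4) || !std::isfinite(resid))
      stop("linear solve diverged at step %d (residual %g)", iter, resid);
    double diff = 0, umin = un[0], umax = un[0];
    for (int v = 0; v < nv; ++v) {
      double ch = std::fabs(un[v] - u[v]);
      if (ch > diff) diff = ch;
      if (un[v] < umin) umin = un[v];
      if (un[v] > umax) umax = un[v];
    }
    u = un;
    trace_diff.push_back(diff);
    trace_min.push_back(umin);
    trace_max.push_back(umax);
    if (diff < tol) break;
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["iterations"] = iter,
      _["max_change"] = NumericVector(trace_diff.begin(), trace_diff.end()),
      _["u_min"] = NumericVector(trace_min.begin(), trace_min.end()),
      _["u_max"] = NumericVector(trace_max.begin(), trace_max.end()));
}

// Marching tetrahedra over the voxel grid: extracts the iso-surface of u at
// `iso` as a triangle soup with outward orientation (normals point toward
// u < iso).  Each cube is split into 6 tetrahedra sharing the main diagonal.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector u, IntegerVector dim, NumericVector origin,
                    NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // six tetrahedra around the main diagonal 0-7; opposite cube faces get
  // matching diagonals, so the extracted surface is watertight across cubes
  static const int tets[6][4] = {
      {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
      {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  // cube corner offsets (binary: x + 2y + 4z order chosen for the split)
  static const int corner[8][3] = {
      {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
      {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  std::vector<double> verts;
  std::vector<int> faces;
  auto interp = [&](const double *p0, const double *p1, double v0, double v1,
                    double *out) {
    double t = (iso - v0) / (v1 - v0);
    if (t < 0) t = 0; if (t > 1) t = 1;
    for (int d = 0; d < 3; ++d) out[d] = p0[d] + t * (p1[d] - p0[d]);
  };
  auto add_tri = [&](double *a, double *b, double *c, const double *inside) {
    // orient: normal must point away from the inside point (u >= iso side)
    double u1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double u2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nrm[3] = {u1[1] * u2[2] - u1[2] * u2[1],
                     u1[2] * u2[0] - u1[0] * u2[2],
                     u1[0] * u2[1] - u1[1] * u2[0]};
    double cen[3] = {(a[0] + b[0] + c[0]) / 3, (a[1] + b[1] + c[1]) / 3,
                     (a[2] + b[2] + c[2]) / 3};
    double dot = nrm[0] * (inside[0] - cen[0]) + nrm[1] * (inside[1] - cen[1]) +
                 nrm[2] * (inside[2] - cen[2]);
    int base = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d) verts.push_back(a[d]);
    if (dot > 0) {  // normal points toward inside -> flip winding
      for (int d = 0; d < 3; ++d) verts.push_back(c[d]);
      for (int d = 0; d < 3; ++d) verts.push_back(b[d]);
    } else {
      for (int d = 0; d < 3; ++d) verts.push_back(b[d]);
      for (int d = 0; d < 3; ++d) verts.push_back(c[d]);
    }
    faces.push_back(base + 1); faces.push_back(base + 2); faces.push_back(base + 3);
  };
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cp[8][3], cv[8];
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner[c][0], cj = j + corner[c][1], ck = k + corner[c][2];
          cp[c][0] = origin[0] + ci * spacing[0];
          cp[c][1] = origin[1] + cj * spacing[1];
          cp[c][2] = origin[2] + ck * spacing[2];
          cv[c] = u[idx3(ci, cj, ck, nx, ny)];
        }
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int mask = 0;
          for (int c = 0; c < 4; ++c) if (cv[T[c]] >= iso) mask |= (1 << c);
          if (mask == 0 || mask == 15) continue;
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (mask & (1 << c)) in[ni++] = T[c]; else out[no++] = T[c];
          }
          double inside_cen[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) inside_cen[d] += cp[in[c]][d] / ni;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in[0] : out[0];
            const int *others = (ni == 1) ? out : in;
            double p[3][3];
            for (int c = 0; c < 3; ++c)
              interp(cp[apex], cp[others[c]], cv[apex], cv[others[c]], p[c]);
            add_tri(p[0], p[1], p[2], inside_cen);
          } else {  // ni == 2: quad split into two triangles
            double p[4][3];
            interp(cp[in[0]], cp[out[0]], cv[in[0]], cv[out[0]], p[0]);
            interp(cp[in[0]], cp[out[1]], cv[in[0]], cv[out[1]], p[1]);
            interp(cp[in[1]], cp[out[1]], cv[in[1]], cv[out[1]], p[2]);
            interp(cp[in[1]], cp[out[0]], cv[in[1]], cv[out[0]], p[3]);
            add_tri(p[0], p[1], p[2], inside_cen);
            add_tri(p[0], p[2], p[3], inside_cen);
          }
        }
      }
  NumericMatrix V(verts.size() / 3, 3);
  for (size_t r = 0; r < verts.size() / 3; ++r)
    for (int d = 0; d < 3; ++d) V(r, d) = verts[3 * r + d];
  IntegerMatrix F(faces.size() / 3, 3);
  for (size_t r = 0; r < faces.size() / 3; ++r)
    for (int d = 0; d < 3; ++d) F(r, d) = faces[3 * r + d];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
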