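// Numerical kernels: voxelization, DRR ray casting, exact point-triangle
// distance, particle-filter patch correlation, block matching and warping.
// All geometry in mm; images are R matrices indexed [v+1, u+1] (row = v).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- voxelize

// Interior/exterior labeling by ray-crossing parity along +x for every
// (y, z) voxel-center row. Rays are offset by a tiny deterministic epsilon
// so they cannot graze mesh vertices lying on nice coordinates.
// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                  NumericVector spacing, double bone_value, double air_value,
                  double pad) {
  const int nv = verts.nrow(), nf = faces.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      if (verts(i, k) < lo[k]) lo[k] = verts(i, k);
      if (verts(i, k) > hi[k]) hi[k] = verts(i, k);
    }
  int dim[3];
  double origin[3];
  for (int k = 0; k < 3; ++k) {
    // half-voxel offset keeps voxel centers off mesh planes at nice coords
    origin[k] = lo[k] - pad * spacing[k] + 0.5 * spacing[k];
    dim[k] = (int)std::ceil((hi[k] + pad * spacing[k] - origin[k]) /
                            spacing[k]) + 1;
    if (dim[k] < 1) dim[k] = 1;
  }
  NumericVector vals((R_xlen_t)dim[0] * dim[1] * dim[2], air_value);

  const double eps = 1e-7;  // deterministic ray offset (mm)
  // Precompute triangle vertices
  std::vector<double> tx(3 * nf), ty(3 * nf), tz(3 * nf);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      int vi = faces(f, c) - 1;
      tx[3 * f + c] = verts(vi, 0);
      ty[3 * f + c] = verts(vi, 1);
      tz[3 * f + c] = verts(vi, 2);
    }
  std::vector<double> xs;
  for (int iz = 0; iz < dim[2]; ++iz) {
    double zc = origin[2] + iz * spacing[2] + eps;
    for (int iy = 0; iy < dim[1]; ++iy) {
      double yc = origin[1] + iy * spacing[1] + eps;
      xs.clear();
      for (int f = 0; f < nf; ++f) {
        // Ray (t, yc, zc), direction +x: 2D point-in-triangle in (y, z)
        double y0 = ty[3 * f], y1 = ty[3 * f + 1], y2 = ty[3 * f + 2];
        double z0 = tz[3 * f], z1 = tz[3 * f + 1], z2 = tz[3 * f + 2];
        double d = (y1 - y0) * (z2 - z0) - (z1 - z0) * (y2 - y0);
        if (std::fabs(d) < 1e-14) continue;  // triangle edge-on to the ray
        double b1 = ((yc - y0) * (z2 - z0) - (zc - z0) * (y2 - y0)) / d;
        double b2 = ((y1 - y0) * (zc - z0) - (z1 - z0) * (yc - y0)) / d;
        if (b1 < 0.0 || b2 < 0.0 || b1 + b2 > 1.0) continue;
        double x = tx[3 * f] + b1 * (tx[3 * f + 1] - tx[3 * f]) +
                   b2 * (tx[3 * f + 2] - tx[3 * f]);
        xs.push_back(x);
      }
      if (xs.size() < 2) continue;
      std::sort(xs.begin(), xs.end());
      // fill voxel centers between crossing pairs
      for (size_t m = 0; m + 1 < xs.size(); m += 2) {
        int i0 = (int)std::ceil((xs[m] - origin[0]) / spacing[0]);
        int i1 = (int)std::floor((xs[m + 1] - origin[0]) / spacing[0]);
        if (i0 < 0) i0 = 0;
        if (i1 >= dim[0]) i1 = dim[0] - 1;
        for (int ix = i0; ix <= i1; ++ix) {
          double xc = origin[0] + ix * spacing[0];
          if (xc > xs[m] && xc < xs[m + 1])
            vals[ix + (R_xlen_t)dim[0] * (iy + (R_xlen_t)dim[1] * iz)] =
                bone_value;
        }
      }
    }
  }
  return List::create(_["origin"] = NumericVector::create(origin[0], origin[1],
                                                          origin[2]),
                      _["spacing"] = spacing,
                      _["dim"] = IntegerVector::create(dim[0], dim[1], dim[2]),
                      _["values"] = vals);
}

// ------------------------------------------------------------------- DRR

static inline double trilin(const double *v, const int *dim, double x,
                            double y, double z) {
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  if (i < 0 || j < 0 || k < 0 || i > dim[0] - 2 || j > dim[1] - 2 ||
      k > dim[2] - 2)
    return NA_REAL;
  double fx = x - i, fy = y - j, fz = z - k;
  const R_xlen_t nx = dim[0], nxy = (R_xlen_t)dim[0] * dim[1];
  const double *p = v + i + nx * j + nxy * k;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
  double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

// Line integral of (value - air_value) along source->pixel rays, trilinear
// sampling at fixed step. Rmat/tvec pose the volume (model -> world).
// roi = c(u0, u1, v0, v1), 0-based inclusive; pixels outside roi stay 0.
// [[Rcpp::export]]
NumericMatrix cpp_render_drr(NumericVector values, IntegerVector dim,
                             NumericVector origin, NumericVector spacing,
                             NumericMatrix Rmat, NumericVector tvec,
                             NumericVector source, NumericVector det_origin,
                             NumericVector u_axis, NumericVector v_axis,
                             NumericVector pix_spacing, IntegerVector res,
                             IntegerVector roi, double step,
                             double air_value) {
  const int nu = res[0], nv = res[1];
  NumericMatrix img(nv, nu);
  int u0 = std::max(0, roi[0]), u1 = std::min(nu - 1, roi[1]);
  int v0 = std::max(0, roi[2]), v1 = std::min(nv - 1, roi[3]);
  const double *vol = REAL(values);
  int d[3] = {dim[0], dim[1], dim[2]};
  // source in model frame: sm = R^T (source - t)
  double sm[3];
  for (int k = 0; k < 3; ++k)
    sm[k] = Rmat(0, k) * (source[0] - tvec[0]) +
            Rmat(1, k) * (source[1] - tvec[1]) +
            Rmat(2, k) * (source[2] - tvec[2]);
  // index coords of source
  double si[3];
  for (int k = 0; k < 3; ++k) si[k] = (sm[k] - origin[k]) / spacing[k];
  for (int u = u0; u <= u1; ++u) {
    for (int v = v0; v <= v1; ++v) {
      double pw[3], pm[3], pi[3];
      for (int k = 0; k < 3; ++k)
        pw[k] = det_origin[k] + u * pix_spacing[0] * u_axis[k] +
                v * pix_spacing[1] * v_axis[k];
      for (int k = 0; k < 3; ++k)
        pm[k] = Rmat(0, k) * (pw[0] - tvec[0]) +
                Rmat(1, k) * (pw[1] - tvec[1]) +
                Rmat(2, k) * (pw[2] - tvec[2]);
      for (int k = 0; k < 3; ++k) pi[k] = (pm[k] - origin[k]) / spacing[k];
      // ray in index space
      double dir[3], len2 = 0;
      for (int k = 0; k < 3; ++k) { dir[k] = pi[k] - si[k]; }
      // world-space length per unit ray parameter
      double wlen;
      {
        double dx = pw[0] - source[0], dy = pw[1] - source[1],
               dz = pw[2] - source[2];
        wlen = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      for (int k = 0; k < 3; ++k) len2 += dir[k] * dir[k];
      if (len2 <= 0) continue;
      // slab clip against [0, dim-1] in index space (param s in [0,1] src->pix)
      double smin = 0.0, smax = 1.0;
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        double lim = d[k] - 1.0;
        if (std::fabs(dir[k]) < 1e-14) {
          if (si[k] < 0 || si[k] > lim) { miss = true; break; }
        } else {
          double t1 = (0.0 - si[k]) / dir[k], t2 = (lim - si[k]) / dir[k];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > smin) smin = t1;
          if (t2 < smax) smax = t2;
          if (smin > smax) { miss = true; break; }
        }
      }
      if (miss || smax <= smin) continue;
      double ds = step / wlen;  // param increment per mm
      int nstep = (int)std::ceil((smax - smin) / ds);
      if (nstep < 1) nstep = 1;
      double ds_eff = (smax - smin) / nstep;
      double acc = 0.0;
      for (int n = 0; n < nstep; ++n) {
        double s = smin + (n + 0.5) * ds_eff;
        double x = si[0] + s * dir[0], y = si[1] + s * dir[1],
               z = si[2] + s * dir[2];
        double val = trilin(vol, d, x, y, z);
        if (!ISNA(val)) acc += (val - air_value);
      }
      img(v, u) = acc * ds_eff * wlen;  // mm-weighted line integral
    }
  }
  return img;
}

// ------------------------------------------- exact point-triangle distance

static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  // Ericson, Real-Time Collision Detection: closest point on triangle.
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + t * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * vv + ac[k] * ww;
}

// For each query point: minimum Euclidean distance to the triangulated
// surface and the realizing closest point. Per-triangle AABB pruning.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix points, NumericMatrix verts,
                         IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  std::vector<double> blo(3 * nf), bhi(3 * nf), tv(9 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      int vi = faces(f, c) - 1;
      for (int k = 0; k < 3; ++k) tv[9 * f + 3 * c + k] = verts(vi, k);
    }
    for (int k = 0; k < 3; ++k) {
      double a = tv[9 * f + k], b = tv[9 * f + 3 + k], c2 = tv[9 * f + 6 + k];
      blo[3 * f + k] = std::min(a, std::min(b, c2));
      bhi[3 * f + k] = std::max(a, std::max(b, c2));
    }
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0}, q[3];
    for (int f = 0; f < nf; ++f) {
      // AABB lower bound
      double lb = 0;
      for (int k = 0; k < 3; ++k) {
        double dk = 0;
        if (p[k] < blo[3 * f + k]) dk = blo[3 * f + k] - p[k];
        else if (p[k] > bhi[3 * f + k]) dk = p[k] - bhi[3 * f + k];
        lb += dk * dk;
      }
      if (lb >= best) continue;
      closest_on_tri(p, &tv[9 * f], &tv[9 * f + 3], &tv[9 * f + 6], q);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) d2 += (p[k] - q[k]) * (p[k] - q[k]);
      if (d2 < best) {
        best = d2;
        for (int k = 0; k < 3; ++k) bestpt[k] = q[k];
      }
    }
    dist[i] = std::sqrt(best);
    for (int k = 0; k < 3; ++k) closest(i, k) = bestpt[k];
  }
  return List::create(_["distance"] = dist, _["closest"] = closest);
}

// ---------------------------------------------------- particle patch NCC

static inline double bilin(const NumericMatrix &img, double v, double u) {
  int i = (int)std::floor(v), j = (int)std::floor(u);
  if (i < 0 || j < 0 || i > img.nrow() - 2 || j > img.ncol() - 2)
    return NA_REAL;
  double fv = v - i, fu = u - j;
  return img(i, j) * (1 - fv) * (1 - fu) + img(i + 1, j) * fv * (1 - fu) +
         img(i, j + 1) * (1 - fv) * fu + img(i + 1, j + 1) * fv * fu;
}

// NCC between a fixed template patch (extracted around center in tpl_img)
// and patches of cur sampled under per-particle (du, dv, dtheta deg) rigid
// 2D increments about the template center. Out-of-image samples are dropped
// pairwise from both sums.
// [[Rcpp::export]]
NumericVector cpp_particle_ncc(NumericMatrix tpl_img, NumericMatrix cur,
                               double cu, double cv, int hu, int hv,
                               NumericMatrix particles) {
  const int npart = particles.nrow();
  const int pw = 2 * hu + 1, ph = 2 * hv + 1;
  std::vector<double> tpl(pw * ph);
  for (int b = -hv; b <= hv; ++b)
    for (int a = -hu; a <= hu; ++a)
      tpl[(b + hv) * pw + (a + hu)] = bilin(tpl_img, cv + b, cu + a);
  NumericVector ncc(npart);
  for (int s = 0; s < npart; ++s) {
    double du = particles(s, 0), dv = particles(s, 1);
    double th = particles(s, 2) * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    int n = 0;
    for (int b = -hv; b <= hv; ++b)
      for (int a = -hu; a <= hu; ++a) {
        double x = tpl[(b + hv) * pw + (a + hu)];
        if (ISNA(x)) continue;
        double uu = cu + du + ct * a - st * b;
        double vv = cv + dv + st * a + ct * b;
        double y = bilin(cur, vv, uu);
        if (ISNA(y)) continue;
        sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
        ++n;
      }
    if (n < 9) { ncc[s] = -1.0; continue; }
    double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
    double cxy = sxy - sx * sy / n;
    // zero-variance (featureless) patches carry no match information
    ncc[s] = (vx <= 1e-12 || vy <= 1e-12) ? -1.0
                                          : cxy / std::sqrt(vx * vy);
  }
  return ncc;
}

// --------------------------------------------------------- block matching

// Integer-displacement block matching prev -> next by SAD, with optional
// per-block initial flow. Returns flows and normalized SAD per block.
// [[Rcpp::export]]
List cpp_block_match(NumericMatrix prev, NumericMatrix nxt, int block,
                     int radius, NumericMatrix init_u, NumericMatrix init_v) {
  const int nr = prev.nrow(), nc = prev.ncol();
  const int bru = nc / block, brv = nr / block;
  NumericMatrix fu(brv, bru), fv(brv, bru), cost(brv, bru);
  for (int bi = 0; bi < brv; ++bi) {
    for (int bj = 0; bj < bru; ++bj) {
      int r0 = bi * block, c0 = bj * block;
      int iu = (init_u.nrow() > 0)
                   ? (int)std::round(init_u(std::min(bi, init_u.nrow() - 1),
                                            std::min(bj, init_u.ncol() - 1)))
                   : 0;
      int iv = (init_v.nrow() > 0)
                   ? (int)std::round(init_v(std::min(bi, init_v.nrow() - 1),
                                            std::min(bj, init_v.ncol() - 1)))
                   : 0;
      double best = R_PosInf;
      int bu = iu, bv = iv;
      for (int dv = -radius; dv <= radius; ++dv) {
        for (int du = -radius; du <= radius; ++du) {
          int ou = iu + du, ov = iv + dv;
          double sad = 0;
          int n = 0;
          for (int r = r0; r < r0 + block && r < nr; ++r)
            for (int c = c0; c < c0 + block && c < nc; ++c) {
              int rr = r + ov, cc = c + ou;
              if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
              sad += std::fabs(prev(r, c) - nxt(rr, cc));
              ++n;
            }
          if (n == 0) continue;
          sad /= n;
          // prefer smaller displacement on ties (determinism)
          if (sad < best - 1e-12 ||
              (sad < best + 1e-12 &&
               ou * ou + ov * ov < bu * bu + bv * bv)) {
            best = sad;
            bu = ou;
            bv = ov;
          }
        }
      }
      fu(bi, bj) = bu;
      fv(bi, bj) = bv;
      cost(bi, bj) = best;
    }
  }
  return List::create(_["flow_u"] = fu, _["flow_v"] = fv, _["cost"] = cost);
}

// Backward warp: out(r, c) = img(r + scale*flow_v(r,c), c + scale*flow_u(r,c))
// with bilinear sampling; out-of-range samples clamp to the border.
// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix flow_u,
                       NumericMatrix flow_v, double scale) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double vv = r + scale * flow_v(r, c), uu = c + scale * flow_u(r, c);
      if (vv < 0) vv = 0;
      if (uu < 0) uu = 0;
      if (vv > nr - 1) vv = nr - 1;
      if (uu > nc - 1) uu = nc - 1;
      double val = bilin(img, vv, uu);
      if (ISNA(val)) {
        int ri = std::min(nr - 1, std::max(0, (int)std::round(vv)));
        int ci = std::min(nc - 1, std::max(0, (int)std::round(uu)));
        val = img(ri, ci);
      }
      out(r, c) = val;
    }
  return out;
}
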