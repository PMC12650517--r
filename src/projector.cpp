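#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rotation-based parallel-beam projector with depth-dependent Gaussian blur
// and voxelized attenuation. The transaxial plane (x,y) rotates about the
// body long axis (z); after rotating the volume by the view angle, rays run
// along +y toward the detector. All pieces (bilinear rotation, zero-padded
// symmetric blur, diagonal attenuation) have exact adjoints, so the
// forward/backprojector pair passes an inner-product test to float accuracy.
// Attenuation survival factors depend only on the mu-map and view angle, so
// they are precomputed once per (phase, view) and passed in.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Bilinear in-plane rotation applied to every z slice.
// gather = forward rotation; scatter = exact adjoint (transpose weights).
static void rotate_stack(const double *in, double *out, int nx, int ny,
                         int nz, double ang, bool adjoint) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double ca = std::cos(ang), sa = std::sin(ang);
  const int nxy = nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double xc = i - cx, yc = j - cy;
      const double sx = ca * xc + sa * yc + cx;
      const double sy = -sa * xc + ca * yc + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      const double w01 = (1 - fx) * fy, w11 = fx * fy;
      const bool in00 = x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny;
      const bool in10 = x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny;
      const bool in01 = x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      const bool in11 = x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      if (!in00 && !in10 && !in01 && !in11) {
        if (!adjoint)
          for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = 0.0;
        continue;
      }
      const int base = i + nx * j;
      const int b00 = in00 ? x0 + nx * y0 : 0;
      const int b10 = in10 ? x0 + 1 + nx * y0 : 0;
      const int b01 = in01 ? x0 + nx * (y0 + 1) : 0;
      const int b11 = in11 ? x0 + 1 + nx * (y0 + 1) : 0;
      if (!adjoint) {
        for (int k = 0; k < nz; ++k) {
          const int off = nxy * k;
          double v = 0.0;
          if (in00) v += w00 * in[b00 + off];
          if (in10) v += w10 * in[b10 + off];
          if (in01) v += w01 * in[b01 + off];
          if (in11) v += w11 * in[b11 + off];
          out[base + off] = v;
        }
      } else {
        for (int k = 0; k < nz; ++k) {
          const int off = nxy * k;
          const double v = in[base + off];
          if (v != 0.0) {
            if (in00) out[b00 + off] += w00 * v;
            if (in10) out[b10 + off] += w10 * v;
            if (in01) out[b01 + off] += w01 * v;
            if (in11) out[b11 + off] += w11 * v;
          }
        }
      }
    }
  }
}

// Per-voxel survival factor toward the detector (+y side), half-voxel
// self-attenuation convention: exp(-(cum_mu_to_detector - mu/2) * dl),
// computed in the rotated frame of one view.
// [[Rcpp::export]]
NumericVector cpp_atten_view(NumericVector mu, IntegerVector dim,
                             double ang, double dl) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  std::vector<double> murot(nvox);
  rotate_stack(REAL(mu), murot.data(), nx, ny, nz, ang, false);
  NumericVector A(nvox);
  A.attr("dim") = dim;
  double *a = REAL(A);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double cum = 0.0;
      for (int j = ny - 1; j >= 0; --j) {
        const double m = murot[idx3(i, j, k, nx, ny)];
        cum += m;
        a[idx3(i, j, k, nx, ny)] = std::exp(-(cum - 0.5 * m) * dl);
      }
    }
  return A;
}

// Zero-padded symmetric 1-D Gaussian kernel, normalized to unit sum; the
// implied convolution matrix is symmetric, hence self-adjoint.
static std::vector<double> gauss_kernel(double sigma) {
  if (sigma < 1e-6) return std::vector<double>(1, 1.0);
  const int h = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> w(2 * h + 1);
  double s = 0.0;
  for (int t = -h; t <= h; ++t) {
    w[t + h] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += w[t + h];
  }
  for (size_t t = 0; t < w.size(); ++t) w[t] /= s;
  return w;
}

// per-depth blur kernels (depth measured from the detector side, +y)
static std::vector< std::vector<double> > depth_kernels(
    int ny, double dl, double radius, double c0, double c1) {
  std::vector< std::vector<double> > ks(ny);
  for (int j = 0; j < ny; ++j) {
    const double ycm = (j - 0.5 * (ny - 1)) * dl;
    double depth = radius - ycm;
    if (depth < 0) depth = 0;
    const double fwhm = c0 + c1 * depth;
    ks[j] = gauss_kernel(fwhm / (2.354820045 * dl));
  }
  return ks;
}

// Separable 2-D blur of an (nx x nz) plane, zero padding.
static void blur_plane(const double *in, double *out, int nx, int nz,
                       const std::vector<double> &w, double *tmp) {
  const int h = ((int)w.size() - 1) / 2;
  if (h == 0) {
    std::copy(in, in + nx * nz, out);
    return;
  }
  const double *wc = w.data() + h;
  // along x
  for (int k = 0; k < nz; ++k) {
    const double *row = in + nx * k;
    double *trow = tmp + nx * k;
    for (int i = 0; i < nx; ++i) {
      const int t0 = i - h < 0 ? -i : -h;
      const int t1 = i + h > nx - 1 ? nx - 1 - i : h;
      double v = 0.0;
      for (int t = t0; t <= t1; ++t) v += wc[t] * row[i + t];
      trow[i] = v;
    }
  }
  // along z
  for (int k = 0; k < nz; ++k) {
    const int t0 = k - h < 0 ? -k : -h;
    const int t1 = k + h > nz - 1 ? nz - 1 - k : h;
    double *orow = out + nx * k;
    std::fill(orow, orow + nx, 0.0);
    for (int t = t0; t <= t1; ++t) {
      const double wt = wc[t];
      const double *trow = tmp + nx * (k + t);
      for (int i = 0; i < nx; ++i) orow[i] += wt * trow[i];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_project_view(NumericVector act, SEXP atten,
                               IntegerVector dim, double ang, double dl,
                               double radius, double c0, double c1,
                               bool blur) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const int nxy = nx * ny;
  std::vector<double> arot(nvox);
  rotate_stack(REAL(act), arot.data(), nx, ny, nz, ang, false);
  const bool use_atten = atten != R_NilValue;
  const double *A = use_atten ? REAL(atten) : NULL;
  std::vector< std::vector<double> > ks;
  if (blur) ks = depth_kernels(ny, dl, radius, c0, c1);
  NumericMatrix P(nx, nz);
  double *p = REAL(P);
  std::vector<double> plane(nx * nz), bl(nx * nz), tmp(nx * nz);
  for (int j = 0; j < ny; ++j) {
    const int rowoff = nx * j;
    for (int k = 0; k < nz; ++k) {
      const int off = rowoff + nxy * k;
      double *dst = plane.data() + nx * k;
      const double *src = arot.data() + off;
      if (use_atten) {
        const double *av = A + off;
        for (int i = 0; i < nx; ++i) dst[i] = src[i] * av[i];
      } else {
        std::copy(src, src + nx, dst);
      }
    }
    const double *add = plane.data();
    if (blur) {
      blur_plane(plane.data(), bl.data(), nx, nz, ks[j], tmp.data());
      add = bl.data();
    }
    for (int t = 0; t < nx * nz; ++t) p[t] += add[t];
  }
  for (int t = 0; t < nx * nz; ++t) p[t] *= dl;
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_backproject_view(NumericMatrix pm, SEXP atten,
                                   IntegerVector dim, double ang, double dl,
                                   double radius, double c0, double c1,
                                   bool blur) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const int nxy = nx * ny;
  const bool use_atten = atten != R_NilValue;
  const double *A = use_atten ? REAL(atten) : NULL;
  std::vector< std::vector<double> > ks;
  if (blur) ks = depth_kernels(ny, dl, radius, c0, c1);
  std::vector<double> vrot(nvox, 0.0), bl(nx * nz), tmp(nx * nz);
  const double *p = REAL(pm);
  for (int j = 0; j < ny; ++j) {
    const double *src = p;
    if (blur) {
      blur_plane(p, bl.data(), nx, nz, ks[j], tmp.data());
      src = bl.data();
    }
    const int rowoff = nx * j;
    for (int k = 0; k < nz; ++k) {
      const int off = rowoff + nxy * k;
      const double *srow = src + nx * k;
      double *dst = vrot.data() + off;
      if (use_atten) {
        const double *av = A + off;
        for (int i = 0; i < nx; ++i) dst[i] = srow[i] * av[i] * dl;
      } else {
        for (int i = 0; i < nx; ++i) dst[i] = srow[i] * dl;
      }
    }
  }
  NumericVector out(nvox);
  out.attr("dim") = dim;
  std::fill(REAL(out), REAL(out) + nvox, 0.0);
  rotate_stack(vrot.data(), REAL(out), nx, ny, nz, ang, true);
  return out;
}

// Trilinear warp: out(v) = in(v + d(v)), coordinates clamped to the grid
// (border replication). adjoint = transpose scatter with the same weights.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector dvf,
                       IntegerVector dim, bool adjoint) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nvox = nx * ny * nz;
  const double *d = REAL(dvf);
  NumericVector out(nvox);
  out.attr("dim") = dim;
  std::fill(REAL(out), REAL(out) + nvox, 0.0);
  const double *in = REAL(vol);
  double *o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        double sx = i + d[v], sy = j + d[v + nvox], sz = k + d[v + 2 * nvox];
        if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
        if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
        if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
            z0 = (int)std::floor(sz);
        if (x0 > nx - 2) x0 = nx - 2 >= 0 ? nx - 2 : 0;
        if (y0 > ny - 2) y0 = ny - 2 >= 0 ? ny - 2 : 0;
        if (z0 > nz - 2) z0 = nz - 2 >= 0 ? nz - 2 : 0;
        const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                  z1 = std::min(z0 + 1, nz - 1);
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        const double w[8] = {
          (1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
          (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
          (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
          (1 - fx) * fy * fz,             fx * fy * fz};
        const int c[8] = {
          idx3(x0, y0, z0, nx, ny), idx3(x1, y0, z0, nx, ny),
          idx3(x0, y1, z0, nx, ny), idx3(x1, y1, z0, nx, ny),
          idx3(x0, y0, z1, nx, ny), idx3(x1, y0, z1, nx, ny),
          idx3(x0, y1, z1, nx, ny), idx3(x1, y1, z1, nx, ny)};
        if (!adjoint) {
          double val = 0.0;
          for (int t = 0; t < 8; ++t) val += w[t] * in[c[t]];
          o[v] = val;
        } else {
          const double val = in[v];
          if (val != 0.0)
            for (int t = 0; t < 8; ++t) o[c[t]] += w[t] * val;
        }
      }
  return out;
}
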