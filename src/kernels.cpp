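#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 0-based column-major index into a 3D array
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// trilinear sample at continuous 0-based voxel coordinate; outside -> bg
static double trilinear(const double* v, int nx, int ny, int nz,
                        double x, double y, double z, double bg) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return bg;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz; double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy; double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx; double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double val = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          ? bg : v[idx3(xx, yy, zz, nx, ny)];
        out += wx * wy * wz * val;
      }
    }
  }
  return out;
}

static double nn_sample(const double* v, int nx, int ny, int nz,
                        double x, double y, double z, double bg) {
  int xx = (int)std::lround(x), yy = (int)std::lround(y), zz = (int)std::lround(z);
  if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) return bg;
  return v[idx3(xx, yy, zz, nx, ny)];
}

// Resample `vol` on an output grid of dimension `outdim` under the pull map
// u (output/fixed voxel) -> A (u - center) + center + tr (moving voxel).
// method: 0 trilinear, 1 nearest neighbour.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector voldim,
                                  IntegerVector outdim, NumericMatrix A,
                                  NumericVector tr, NumericVector center,
                                  int method, double bg) {
  int nx = voldim[0], ny = voldim[1], nz = voldim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  double cx = center[0], cy = center[1], cz = center[2];
  double tx = tr[0] + cx, ty = tr[1] + cy, tz = tr[2] + cz;
  R_xlen_t k = 0;
  for (int z = 0; z < oz; ++z) {
    double uz = z - cz;
    for (int y = 0; y < oy; ++y) {
      double uy = y - cy;
      for (int x = 0; x < ox; ++x, ++k) {
        double ux = x - cx;
        double mx = a00*ux + a01*uy + a02*uz + tx;
        double my = a10*ux + a11*uy + a12*uz + ty;
        double mz = a20*ux + a21*uy + a22*uz + tz;
        out[k] = method == 0 ? trilinear(v, nx, ny, nz, mx, my, mz, bg)
                             : nn_sample(v, nx, ny, nz, mx, my, mz, bg);
      }
    }
  }
  out.attr("dim") = outdim;
  return out;
}

// Mean squared difference between fixed and the pulled-back moving image,
// evaluated over every `stride`-th fixed voxel. Voxels mapping outside the
// moving grid contribute with background 0 (keeps the cost basin wide).
// [[Rcpp::export]]
double msd_affine_cpp(NumericVector moving, IntegerVector mdim,
                      NumericVector fixed, IntegerVector fdim,
                      NumericMatrix A, NumericVector tr, NumericVector center,
                      int stride) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double* mv = moving.begin();
  const double* fv = fixed.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  double cx = center[0], cy = center[1], cz = center[2];
  double tx = tr[0] + cx, ty = tr[1] + cy, tz = tr[2] + cz;
  double acc = 0.0; R_xlen_t n = 0;
  for (int z = 0; z < fz; z += stride) {
    double uz = z - cz;
    for (int y = 0; y < fy; y += stride) {
      double uy = y - cy;
      for (int x = 0; x < fx; x += stride) {
        double ux = x - cx;
        double mx = a00*ux + a01*uy + a02*uz + tx;
        double my = a10*ux + a11*uy + a12*uz + ty;
        double mz = a20*ux + a21*uy + a22*uz + tz;
        double d = trilinear(mv, nx, ny, nz, mx, my, mz, 0.0)
                 - fv[idx3(x, y, z, fx, fy)];
        acc += d * d; ++n;
      }
    }
  }
  return n ? acc / n : 0.0;
}

// symmetric mirror reflection of an out-of-range index (repeated, so boxes
// larger than the volume stay in range)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Central-moment features (mean, population sd, skewness, excess kurtosis)
// on cubic boxes centred at every voxel; boxes crossing the volume boundary
// use mirror padding. Returns nvox x (4 * nsizes), voxels in raster order.
// [[Rcpp::export]]
NumericMatrix moment_features_cpp(NumericVector vol, IntegerVector dim,
                                  IntegerVector sizes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ns = sizes.size();
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, 4 * ns);
  const double* v = vol.begin();
  for (int s = 0; s < ns; ++s) {
    int h = (sizes[s] - 1) / 2;
    double nbox = (double)sizes[s] * sizes[s] * sizes[s];
    R_xlen_t k = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++k) {
          double m1 = 0.0;
          for (int dz = -h; dz <= h; ++dz)
            for (int dy = -h; dy <= h; ++dy)
              for (int dx = -h; dx <= h; ++dx)
                m1 += v[idx3(reflect(x+dx,nx), reflect(y+dy,ny), reflect(z+dz,nz), nx, ny)];
          m1 /= nbox;
          double m2 = 0.0, m3 = 0.0, m4 = 0.0;
          for (int dz = -h; dz <= h; ++dz)
            for (int dy = -h; dy <= h; ++dy)
              for (int dx = -h; dx <= h; ++dx) {
                double d = v[idx3(reflect(x+dx,nx), reflect(y+dy,ny), reflect(z+dz,nz), nx, ny)] - m1;
                double d2 = d * d;
                m2 += d2; m3 += d2 * d; m4 += d2 * d2;
              }
          m2 /= nbox; m3 /= nbox; m4 /= nbox;
          // a numerically constant box has m2 at rounding-error level;
          // treat it as zero so the standardized moments stay 0
          double tol = 1e-24 + 1e-20 * m1 * m1;
          double sd = m2 > tol ? std::sqrt(m2) : 0.0;
          out(k, 4*s)     = m1;
          out(k, 4*s + 1) = sd;
          out(k, 4*s + 2) = m2 > tol ? m3 / (m2 * sd) : 0.0;
          out(k, 4*s + 3) = m2 > tol ? m4 / (m2 * m2) - 3.0 : 0.0;
        }
  }
  return out;
}

// The 13 unique 3D unit offsets (half of the 26-neighbourhood).
static const int OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// Haralick features from grey-level co-occurrence matrices. `q` holds
// pre-quantized levels in 0..levels-1. For each voxel a cubic patch of edge
// `box` (clipped at the volume boundary) is scanned; one symmetric GLCM per
// offset, five features per GLCM (energy, contrast, correlation,
// homogeneity = inverse difference moment, entropy in nats), averaged over
// offsets with at least one co-occurring pair.
// [[Rcpp::export]]
NumericMatrix haralick_features_cpp(IntegerVector q, IntegerVector dim,
                                    int box, int levels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int h = (box - 1) / 2;
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, 5);
  const int* qq = q.begin();
  std::vector<double> glcm((size_t)levels * levels);
  R_xlen_t k = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++k) {
        int xlo = std::max(0, x-h), xhi = std::min(nx-1, x+h);
        int ylo = std::max(0, y-h), yhi = std::min(ny-1, y+h);
        int zlo = std::max(0, z-h), zhi = std::min(nz-1, z+h);
        double fen = 0, fco = 0, fcr = 0, fho = 0, fent = 0;
        int used = 0;
        for (int o = 0; o < 13; ++o) {
          int dx = OFF[o][0], dy = OFF[o][1], dz = OFF[o][2];
          std::fill(glcm.begin(), glcm.end(), 0.0);
          double tot = 0.0;
          for (int zz = zlo; zz <= zhi; ++zz) {
            int z2 = zz + dz; if (z2 < zlo || z2 > zhi) continue;
            for (int yy = ylo; yy <= yhi; ++yy) {
              int y2 = yy + dy; if (y2 < ylo || y2 > yhi) continue;
              for (int xx = xlo; xx <= xhi; ++xx) {
                int x2 = xx + dx; if (x2 < xlo || x2 > xhi) continue;
                int a = qq[idx3(xx, yy, zz, nx, ny)];
                int b = qq[idx3(x2, y2, z2, nx, ny)];
                glcm[(size_t)a * levels + b] += 1.0;
                glcm[(size_t)b * levels + a] += 1.0;
                tot += 2.0;
              }
            }
          }
          if (tot == 0.0) continue;
          ++used;
          double en = 0, co = 0, ho = 0, ent = 0;
          double mi = 0, vi = 0;
          for (int a = 0; a < levels; ++a) {
            double pa = 0;
            for (int b = 0; b < levels; ++b) pa += glcm[(size_t)a*levels+b];
            pa /= tot;
            mi += a * pa;
          }
          for (int a = 0; a < levels; ++a) {
            double pa = 0;
            for (int b = 0; b < levels; ++b) pa += glcm[(size_t)a*levels+b];
            pa /= tot;
            vi += (a - mi) * (a - mi) * pa;
          }
          double cr = 0.0;
          for (int a = 0; a < levels; ++a)
            for (int b = 0; b < levels; ++b) {
              double p = glcm[(size_t)a*levels+b] / tot;
              if (p == 0.0) continue;
              en += p * p;
              co += (a - b) * (a - b) * p;
              ho += p / (1.0 + (a - b) * (a - b));
              ent -= p * std::log(p);
              cr += (a - mi) * (b - mi) * p;
            }
          cr = vi > 0 ? cr / vi : 0.0;  // symmetric GLCM: sd_i = sd_j
          fen += en; fco += co; fcr += cr; fho += ho; fent += ent;
        }
        if (used > 0) {
          out(k,0) = fen / used; out(k,1) = fco / used; out(k,2) = fcr / used;
          out(k,3) = fho / used; out(k,4) = fent / used;
        }
      }
  return out;
}

// box sum over inclusive 0-based [lo, hi] from an integral image built on
// the fly; iv has an extra leading zero plane per axis
struct Integral {
  std::vector<double> iv;
  int nx, ny, nz;
  Integral(const double* v, int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_) {
    iv.assign((size_t)(nx+1)*(ny+1)*(nz+1), 0.0);
    for (int z = 1; z <= nz; ++z)
      for (int y = 1; y <= ny; ++y)
        for (int x = 1; x <= nx; ++x)
          at(x,y,z) = v[idx3(x-1,y-1,z-1,nx,ny)]
            + at(x-1,y,z) + at(x,y-1,z) + at(x,y,z-1)
            - at(x-1,y-1,z) - at(x-1,y,z-1) - at(x,y-1,z-1)
            + at(x-1,y-1,z-1);
  }
  double& at(int x, int y, int z) {
    return iv[(size_t)x + (size_t)(nx+1) * ((size_t)y + (size_t)(ny+1) * z)];
  }
  double box(int x0, int y0, int z0, int x1, int y1, int z1) {
    // inclusive voxel coords, assumed clipped to bounds
    ++x1; ++y1; ++z1;
    return at(x1,y1,z1) - at(x0,y1,z1) - at(x1,y0,z1) - at(x1,y1,z0)
         + at(x0,y0,z1) + at(x0,y1,z0) + at(x1,y0,z0) - at(x0,y0,z0);
  }
};

// Haar-like responses: per box size, differences of half-box means along
// each axis plus a centre-minus-surround contrast. Boxes are clipped at the
// volume boundary and each part is normalized by its actual voxel count.
// Columns per size: (x: left-right), (y), (z), centre-surround.
// [[Rcpp::export]]
NumericMatrix haar_features_cpp(NumericVector vol, IntegerVector dim,
                                IntegerVector sizes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Integral I(vol.begin(), nx, ny, nz);
  int ns = sizes.size();
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, 4 * ns);
  for (int s = 0; s < ns; ++s) {
    int h = (sizes[s] - 1) / 2;
    int ie = (sizes[s] + 1) / 2;          // inner cube edge: ~half the box,
    if (ie % 2 == 0) ie -= 1;             // rounded down to odd
    int hin = (ie - 1) / 2;
    R_xlen_t k = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++k) {
          int xlo = std::max(0, x-h), xhi = std::min(nx-1, x+h);
          int ylo = std::max(0, y-h), yhi = std::min(ny-1, y+h);
          int zlo = std::max(0, z-h), zhi = std::min(nz-1, z+h);
          double ny_ = (double)(yhi-ylo+1), nz_ = (double)(zhi-zlo+1);
          double nx_ = (double)(xhi-xlo+1);
          // x split: strictly left of centre vs strictly right
          double rx = 0.0;
          if (x-1 >= xlo && x+1 <= xhi) {
            double sl = I.box(xlo, ylo, zlo, x-1, yhi, zhi);
            double sr = I.box(x+1, ylo, zlo, xhi, yhi, zhi);
            rx = sl / ((x-xlo) * ny_ * nz_) - sr / ((xhi-x) * ny_ * nz_);
          }
          double ry = 0.0;
          if (y-1 >= ylo && y+1 <= yhi) {
            double sl = I.box(xlo, ylo, zlo, xhi, y-1, zhi);
            double sr = I.box(xlo, y+1, zlo, xhi, yhi, zhi);
            ry = sl / ((y-ylo) * nx_ * nz_) - sr / ((yhi-y) * nx_ * nz_);
          }
          double rz = 0.0;
          if (z-1 >= zlo && z+1 <= zhi) {
            double sl = I.box(xlo, ylo, zlo, xhi, yhi, z-1);
            double sr = I.box(xlo, ylo, z+1, xhi, yhi, zhi);
            rz = sl / ((z-zlo) * nx_ * ny_) - sr / ((zhi-z) * nx_ * ny_);
          }
          // centre-minus-surround
          int ixlo = std::max(xlo, x-hin), ixhi = std::min(xhi, x+hin);
          int iylo = std::max(ylo, y-hin), iyhi = std::min(yhi, y+hin);
          int izlo = std::max(zlo, z-hin), izhi = std::min(zhi, z+hin);
          double sin_ = I.box(ixlo, iylo, izlo, ixhi, iyhi, izhi);
          double nin = (double)(ixhi-ixlo+1) * (iyhi-iylo+1) * (izhi-izlo+1);
          double sall = I.box(xlo, ylo, zlo, xhi, yhi, zhi);
          double nall = nx_ * ny_ * nz_;
          double rc = (nall - nin) > 0
            ? sin_ / nin - (sall - sin_) / (nall - nin) : 0.0;
          out(k, 4*s) = rx; out(k, 4*s+1) = ry; out(k, 4*s+2) = rz; out(k, 4*s+3) = rc;
        }
  }
  return out;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// One-hidden-layer sigmoid network trained by minibatch stochastic gradient
// descent on the log-loss. Weight init and epoch shuffles use R's RNG, so
// results are reproducible under set.seed(). Returns the weight list.
// [[Rcpp::export]]
List nn_train_cpp(NumericMatrix X, NumericVector y, int hidden,
                  double lr, int epochs, int batch) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix W1(p, hidden);
  NumericVector b1(hidden), W2(hidden);
  double b2 = 0.0;
  double sc1 = 1.0 / std::sqrt((double)p), sc2 = 1.0 / std::sqrt((double)hidden);
  for (int j = 0; j < hidden; ++j)
    for (int i = 0; i < p; ++i) W1(i, j) = R::runif(-sc1, sc1);
  for (int j = 0; j < hidden; ++j) W2[j] = R::runif(-sc2, sc2);

  std::vector<int> ord(n);
  std::vector<double> hbuf(hidden), dh(hidden);
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    // Fisher-Yates with R RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      int m = end - start;
      // accumulate gradients over the minibatch
      std::vector<double> gW1((size_t)p * hidden, 0.0), gb1(hidden, 0.0),
                          gW2(hidden, 0.0);
      double gb2 = 0.0;
      for (int ii = start; ii < end; ++ii) {
        int r = ord[ii];
        double zo = b2;
        for (int j = 0; j < hidden; ++j) {
          double a = b1[j];
          for (int i = 0; i < p; ++i) a += X(r, i) * W1(i, j);
          hbuf[j] = sigmoid(a);
          zo += W2[j] * hbuf[j];
        }
        double delta = sigmoid(zo) - y[r];  // dLoss/dz_out for log-loss
        gb2 += delta;
        for (int j = 0; j < hidden; ++j) {
          gW2[j] += delta * hbuf[j];
          dh[j] = delta * W2[j] * hbuf[j] * (1.0 - hbuf[j]);
          gb1[j] += dh[j];
        }
        for (int j = 0; j < hidden; ++j)
          for (int i = 0; i < p; ++i) gW1[(size_t)i * hidden + j] += dh[j] * X(r, i);
      }
      double step = lr / m;
      b2 -= step * gb2;
      for (int j = 0; j < hidden; ++j) {
        W2[j] -= step * gW2[j];
        b1[j] -= step * gb1[j];
        for (int i = 0; i < p; ++i) W1(i, j) -= step * gW1[(size_t)i * hidden + j];
      }
    }
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2);
}

// Forward pass of the network above; returns scores in (0,1).
// [[Rcpp::export]]
NumericVector nn_predict_cpp(NumericMatrix X, NumericMatrix W1,
                             NumericVector b1, NumericVector W2, double b2) {
  int n = X.nrow(), p = X.ncol(), hidden = W1.ncol();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double zo = b2;
    for (int j = 0; j < hidden; ++j) {
      double a = b1[j];
      for (int i = 0; i < p; ++i) a += X(r, i) * W1(i, j);
      zo += W2[j] * sigmoid(a);
    }
    out[r] = sigmoid(zo);
  }
  return out;
}

// Sample vol at (x + ux, y + uy, z + uz), trilinear, for demons warping.
// [[Rcpp::export]]
NumericVector sample_displaced_cpp(NumericVector vol, IntegerVector dim,
                                   NumericVector ux, NumericVector uy,
                                   NumericVector uz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  R_xlen_t k = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++k)
        out[k] = trilinear(v, nx, ny, nz, x + ux[k], y + uy[k], z + uz[k], 0.0);
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing (truncated at 3 sigma, reflected boundary).
// [[Rcpp::export]]
NumericVector smooth3_gauss_cpp(NumericVector vol, IntegerVector dim,
                                double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * rad + 1);
  double tot = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    w[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    tot += w[i + rad];
  }
  for (double& x : w) x /= tot;
  NumericVector a = clone(vol), b(n);
  // pass along x, then y, then z
  for (int axis = 0; axis < 3; ++axis) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          for (int i = -rad; i <= rad; ++i) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx = reflect(x + i, nx);
            else if (axis == 1) yy = reflect(y + i, ny);
            else zz = reflect(z + i, nz);
            acc += w[i + rad] * a[idx3(xx, yy, zz, nx, ny)];
          }
          b[idx3(x, y, z, nx, ny)] = acc;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dim;
  return a;
}
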