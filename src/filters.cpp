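// Voxel-level kernels for 3D grey-level volume filtering.
// Volumes are R arrays with dim = c(d1, d2, d3), column-major:
// linear index = i + d1*(j + d2*k), 0-based here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Separable Gaussian blur with replicate boundary. sigma per axis, in voxels.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector src = clone(vol);
  NumericVector dst(n);
  const int dims[3] = {d1, d2, d3};
  // strides for each axis
  const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * rad + 1);
    double sum = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + rad];
    }
    for (auto &w : ker) w /= sum;

    const int nax = dims[ax];
    const R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    const int oa = (ax == 0) ? 1 : 0;          // other axes
    const int ob = (ax == 2) ? 1 : 2;
    const int na = dims[oa], nb = dims[ob];
    const R_xlen_t sa = strides[oa], sb = strides[ob];
    for (int b = 0; b < nb; ++b) {
      for (int a = 0; a < na; ++a) {
        const R_xlen_t base = a * sa + b * sb;
        for (int i = 0; i < nax; ++i) {
          double acc = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = clampi(i + t, nax);
            acc += ker[t + rad] * src[base + (R_xlen_t)ii * st];
          }
          dst[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::copy(dst.begin(), dst.end(), src.begin());
  }
  return src;
}

// Box blur (running mean), `passes` repetitions; replicate or periodic
// (wrap) boundary. radius per axis in voxels. Three passes approximate a
// Gaussian; used for the large-scale random fields of the phantom
// generator, where the periodic boundary keeps the field statistics
// stationary up to the volume faces.
// [[Rcpp::export]]
NumericVector cpp_box_blur(NumericVector vol, IntegerVector dim,
                           IntegerVector radius, int passes, bool wrap) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector src = clone(vol);
  NumericVector dst(n);
  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};
  std::vector<double> line;

  for (int p = 0; p < passes; ++p) {
    for (int ax = 0; ax < 3; ++ax) {
      int rad = radius[ax];
      if (rad <= 0) continue;
      const int nax = dims[ax];
      const R_xlen_t st = strides[ax];
      const int oa = (ax == 0) ? 1 : 0;
      const int ob = (ax == 2) ? 1 : 2;
      const int na = dims[oa], nb = dims[ob];
      const R_xlen_t sa = strides[oa], sb = strides[ob];
      line.resize(nax);
      const double inv = 1.0 / (2 * rad + 1);
      auto bidx = [&](int i) {
        if (wrap) { i %= nax; if (i < 0) i += nax; return i; }
        return clampi(i, nax);
      };
      for (int b = 0; b < nb; ++b) {
        for (int a = 0; a < na; ++a) {
          const R_xlen_t base = a * sa + b * sb;
          for (int i = 0; i < nax; ++i) line[i] = src[base + (R_xlen_t)i * st];
          double acc = 0.0;
          for (int t = -rad; t <= rad; ++t) acc += line[bidx(t)];
          for (int i = 0; i < nax; ++i) {
            dst[base + (R_xlen_t)i * st] = acc * inv;
            acc += line[bidx(i + rad + 1)] - line[bidx(i - rad)];
          }
        }
      }
      std::copy(dst.begin(), dst.end(), src.begin());
    }
  }
  return src;
}

// ---- symmetric 3x3 eigen-decomposition (cyclic Jacobi) -------------------

static void jacobi3(double a[3][3], double w[3], double v[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 24; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        double apq = a[p][q];
        if (std::fabs(apq) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < 3; ++i) w[i] = a[i][i];
}

// Dark-sheet (planarity) filter: Hessian of the (pre-smoothed) volume by
// central differences; eigenvalues sorted by |.| descending as h1,h2,h3.
// A thin dark plane in bright material has h1 large POSITIVE (intensity
// minimum across the plane) and |h2|,|h3| << |h1|.
// score_raw = h1 * exp(-(h2^2 + h3^2) / (2 (alpha h1)^2)) for h1 > 0.
// The plane normal is the eigenvector of h1.
// Returns list(score, nx, ny, nz) -- score unnormalised, derivative units.
// [[Rcpp::export]]
List cpp_sheet_filter(NumericVector vol, IntegerVector dim, double alpha,
                      bool want_normals) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector score(n);
  NumericVector vx, vy, vz;
  if (want_normals) {
    vx = NumericVector(n);
    vy = NumericVector(n);
    vz = NumericVector(n);
  }
  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;

  auto at = [&](int i, int j, int k) -> double {
    return vol[clampi(i, d1) * s1 + clampi(j, d2) * s2 + clampi(k, d3) * s3];
  };

  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        double c0 = at(i, j, k);
        double h11 = at(i + 1, j, k) - 2 * c0 + at(i - 1, j, k);
        double h22 = at(i, j + 1, k) - 2 * c0 + at(i, j - 1, k);
        double h33 = at(i, j, k + 1) - 2 * c0 + at(i, j, k - 1);
        double h12 = 0.25 * (at(i + 1, j + 1, k) - at(i + 1, j - 1, k) -
                             at(i - 1, j + 1, k) + at(i - 1, j - 1, k));
        double h13 = 0.25 * (at(i + 1, j, k + 1) - at(i + 1, j, k - 1) -
                             at(i - 1, j, k + 1) + at(i - 1, j, k - 1));
        double h23 = 0.25 * (at(i, j + 1, k + 1) - at(i, j + 1, k - 1) -
                             at(i, j - 1, k + 1) + at(i, j - 1, k - 1));
        double A[3][3] = {{h11, h12, h13}, {h12, h22, h23}, {h13, h23, h33}};
        double w[3], V[3][3];
        jacobi3(A, w, V);
        // order by |lambda| descending
        int ord[3] = {0, 1, 2};
        std::sort(ord, ord + 3,
                  [&](int a, int b) { return std::fabs(w[a]) > std::fabs(w[b]); });
        double h1 = w[ord[0]], h2 = w[ord[1]], h3 = w[ord[2]];
        R_xlen_t idx = i * s1 + (R_xlen_t)j * s2 + (R_xlen_t)k * s3;
        double sc = 0.0;
        if (h1 > 0) {
          double denom = 2.0 * alpha * alpha * h1 * h1;
          sc = h1 * std::exp(-(h2 * h2 + h3 * h3) / denom);
        }
        score[idx] = sc;
        if (want_normals) {
          double nx0 = V[0][ord[0]], ny0 = V[1][ord[0]], nz0 = V[2][ord[0]];
          // deterministic sign: largest-magnitude component positive
          double m = nx0;
          if (std::fabs(ny0) > std::fabs(m)) m = ny0;
          if (std::fabs(nz0) > std::fabs(m)) m = nz0;
          if (m < 0) { nx0 = -nx0; ny0 = -ny0; nz0 = -nz0; }
          vx[idx] = nx0; vy[idx] = ny0; vz[idx] = nz0;
        }
      }
    }
  }
  if (want_normals)
    return List::create(_["score"] = score, _["nx"] = vx, _["ny"] = vy,
                        _["nz"] = vz);
  return List::create(_["score"] = score);
}

// Planarity-guided bilateral filter.
// weight(p,q) = G(|p-q|; sigma_spatial) * G(score_p - score_q; sigma_score)
//             * G(I_p - I_q; sigma_int)
// Non-finite bandwidths disable the corresponding term (limit -> plain
// truncated-Gaussian smoothing). Only voxels with mask != 0 are filtered;
// others pass through.
// [[Rcpp::export]]
NumericVector cpp_guided_bilateral(NumericVector vol, NumericVector score,
                                   LogicalVector mask, IntegerVector dim,
                                   double radius, double sigma_spatial,
                                   double sigma_score, double sigma_int) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out = clone(vol);
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;

  // precompute neighbourhood offsets within Euclidean radius
  int irad = (int)std::floor(radius);
  std::vector<int> di, dj, dk;
  std::vector<double> wsp;
  const double inv2ss = 0.5 / (sigma_spatial * sigma_spatial);
  for (int c = -irad; c <= irad; ++c)
    for (int b = -irad; b <= irad; ++b)
      for (int a = -irad; a <= irad; ++a) {
        double r2 = (double)a * a + (double)b * b + (double)c * c;
        if (r2 > radius * radius) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
        wsp.push_back(std::exp(-r2 * inv2ss));
      }
  const size_t m = di.size();
  const bool use_score = R_finite(sigma_score);
  const bool use_int = R_finite(sigma_int);
  const double inv2sc = use_score ? 0.5 / (sigma_score * sigma_score) : 0.0;
  const double inv2si = use_int ? 0.5 / (sigma_int * sigma_int) : 0.0;

  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)j * s2 + (R_xlen_t)k * s3;
        if (!mask[idx]) continue;
        double sp = score[idx], ip = vol[idx];
        double acc = 0.0, wacc = 0.0;
        for (size_t t = 0; t < m; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
            continue;
          R_xlen_t q = ii + (R_xlen_t)jj * s2 + (R_xlen_t)kk * s3;
          double w = wsp[t];
          if (use_score) {
            double ds = score[q] - sp;
            w *= std::exp(-ds * ds * inv2sc);
          }
          if (use_int) {
            double dv = vol[q] - ip;
            w *= std::exp(-dv * dv * inv2si);
          }
          acc += w * vol[q];
          wacc += w;
        }
        out[idx] = acc / wacc;
      }
    }
  }
  return out;
}
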