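#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Voxel-wise radiomics kernels: per-patch first-order statistics, gray level
// co-occurrence (GLCM) and gray level run length (GLRLM) texture features.
// Quantization is linear min-max binning within the patch; a constant patch
// maps to level 1. Degenerate values (0*log0, zero-variance moments, zero
// marginal variance) are defined as 0 so every feature is finite.
// ---------------------------------------------------------------------------

static const int N_FO = 13, N_GLCM = 21, N_GLRLM = 8;

static inline double xlog2(double p) { return (p > 0.0) ? p * std::log2(p) : 0.0; }

static void quantize_patch(const std::vector<double> &x, int n_levels,
                           std::vector<int> &q) {
  const size_t n = x.size();
  q.resize(n);
  double lo = x[0], hi = x[0];
  for (size_t i = 1; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  if (hi <= lo || n_levels == 1) {
    std::fill(q.begin(), q.end(), 1);
    return;
  }
  const double w = (hi - lo);
  for (size_t i = 0; i < n; ++i) {
    int lev = 1 + (int)std::floor((x[i] - lo) / w * n_levels);
    if (lev > n_levels) lev = n_levels;  // x == hi
    if (lev < 1) lev = 1;
    q[i] = lev;
  }
}

static void first_order(const std::vector<double> &x, const std::vector<int> &q,
                        int n_levels, double *out) {
  const size_t n = x.size();
  double s = 0.0, s2 = 0.0;
  double mn = x[0], mx = x[0];
  for (size_t i = 0; i < n; ++i) {
    s += x[i];
    s2 += x[i] * x[i];
    if (x[i] < mn) mn = x[i];
    if (x[i] > mx) mx = x[i];
  }
  const double mean = s / n;
  double m2 = 0.0, m3 = 0.0, m4 = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const double d = x[i] - mean;
    m2 += d * d;
    m3 += d * d * d;
    m4 += d * d * d * d;
  }
  m2 /= n; m3 /= n; m4 /= n;  // population moments
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  const double median = (n % 2 == 1) ? xs[n / 2]
                                     : 0.5 * (xs[n / 2 - 1] + xs[n / 2]);
  // histogram of quantized levels
  std::vector<double> h(n_levels, 0.0);
  double qsum = 0.0;
  for (size_t i = 0; i < n; ++i) { h[q[i] - 1] += 1.0; qsum += q[i]; }
  double entropy = 0.0, uniformity = 0.0;
  for (int k = 0; k < n_levels; ++k) {
    const double p = h[k] / n;
    entropy -= xlog2(p);
    uniformity += p * p;
  }
  out[0] = mean;
  out[1] = std::sqrt(m2);                       // sd (population)
  out[2] = median;
  out[3] = mn;
  out[4] = mx;
  out[5] = m2;                                  // variance (population)
  out[6] = (m2 > 0.0) ? m3 / std::pow(m2, 1.5) : 0.0;  // skewness
  out[7] = (m2 > 0.0) ? m4 / (m2 * m2) : 0.0;          // kurtosis (Pearson)
  out[8] = s2;                                  // energy
  out[9] = entropy;                             // bits
  out[10] = uniformity;
  out[11] = std::sqrt(s2 / n);                  // root mean square
  out[12] = qsum / n;                           // mean gray level
}

// GLCM over a box patch: counts of level pairs at each integer offset,
// symmetrized, summed over offsets, normalized to sum 1.
static void glcm_accumulate(const std::vector<int> &q, const int bd[3],
                            const int (*offs)[3], int n_off, int n_levels,
                            std::vector<double> &P) {
  P.assign((size_t)n_levels * n_levels, 0.0);
  double total = 0.0;
  for (int o = 0; o < n_off; ++o) {
    const int dx = offs[o][0], dy = offs[o][1], dz = offs[o][2];
    for (int z = 0; z < bd[2]; ++z) {
      const int z2 = z + dz;
      if (z2 < 0 || z2 >= bd[2]) continue;
      for (int y = 0; y < bd[1]; ++y) {
        const int y2 = y + dy;
        if (y2 < 0 || y2 >= bd[1]) continue;
        for (int x = 0; x < bd[0]; ++x) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= bd[0]) continue;
          const int a = q[(size_t)z * bd[0] * bd[1] + (size_t)y * bd[0] + x] - 1;
          const int b = q[(size_t)z2 * bd[0] * bd[1] + (size_t)y2 * bd[0] + x2] - 1;
          P[(size_t)a * n_levels + b] += 1.0;  // symmetrized below
          P[(size_t)b * n_levels + a] += 1.0;
          total += 2.0;
        }
      }
    }
  }
  if (total > 0.0)
    for (size_t i = 0; i < P.size(); ++i) P[i] /= total;
}

static void glcm_features(const std::vector<double> &P, int ng, double *out) {
  std::vector<double> px(ng, 0.0);
  std::vector<double> pxy(2 * ng, 0.0);   // p_{x+y}(k), k = i+j, 2..2ng -> idx k-2
  std::vector<double> pxd(ng, 0.0);       // p_{x-y}(k), k = |i-j|, 0..ng-1
  double autoc = 0, contrast = 0, dissim = 0, energy = 0, entropy = 0;
  double hom_m = 0, hom_p = 0, idn = 0, maxp = 0, sum_ij = 0;
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      const double p = P[(size_t)i * ng + j];
      px[i] += p;
      pxy[i + j] += p;
      pxd[std::abs(i - j)] += p;
      if (p > maxp) maxp = p;
      const double gi = i + 1, gj = j + 1, ad = std::abs(i - j);
      autoc += gi * gj * p;
      sum_ij += gi * gj * p;
      contrast += (gi - gj) * (gi - gj) * p;
      dissim += ad * p;
      energy += p * p;
      entropy -= xlog2(p);
      hom_m += p / (1.0 + ad);
      hom_p += p / (1.0 + ad * ad);
      idn += p / (1.0 + ad / ng);
    }
  double mux = 0, sx2 = 0;
  for (int i = 0; i < ng; ++i) mux += (i + 1) * px[i];
  for (int i = 0; i < ng; ++i) sx2 += (i + 1 - mux) * (i + 1 - mux) * px[i];
  const double sx = std::sqrt(sx2);
  // symmetric matrix: marginals equal, mu_y = mu_x, sigma_y = sigma_x
  double corr_m = 0.0;
  if (sx2 > 0.0) {
    for (int i = 0; i < ng; ++i)
      for (int j = 0; j < ng; ++j)
        corr_m += (i + 1 - mux) * (j + 1 - mux) * P[(size_t)i * ng + j];
    corr_m /= (sx * sx);
  }
  const double corr_p = (sx2 > 0.0) ? (sum_ij - mux * mux) / (sx * sx) : 0.0;
  double cshade = 0, cprom = 0, sosq = 0;
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      const double p = P[(size_t)i * ng + j];
      const double t = (i + 1) + (j + 1) - 2.0 * mux;
      cshade += t * t * t * p;
      cprom += t * t * t * t * p;
      sosq += (i + 1 - mux) * (i + 1 - mux) * p;
    }
  double sum_avg = 0, sum_ent = 0;
  for (int k = 0; k < 2 * ng; ++k) {
    sum_avg += (k + 2) * pxy[k];
    sum_ent -= xlog2(pxy[k]);
  }
  double sum_var = 0;
  for (int k = 0; k < 2 * ng; ++k)
    sum_var += ((k + 2) - sum_avg) * ((k + 2) - sum_avg) * pxy[k];
  double dmu = 0, diff_ent = 0;
  for (int k = 0; k < ng; ++k) { dmu += k * pxd[k]; diff_ent -= xlog2(pxd[k]); }
  double diff_var = 0;
  for (int k = 0; k < ng; ++k) diff_var += (k - dmu) * (k - dmu) * pxd[k];
  // information measures of correlation
  double hx = 0, hxy1 = 0, hxy2 = 0;
  for (int i = 0; i < ng; ++i) hx -= xlog2(px[i]);
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) {
      const double pp = px[i] * px[j];
      if (pp > 0.0) {
        hxy1 -= P[(size_t)i * ng + j] * std::log2(pp);
        hxy2 -= pp * std::log2(pp);
      }
    }
  const double imc1 = (hx > 0.0) ? (entropy - hxy1) / hx : 0.0;
  double imc2arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  const double imc2 = std::sqrt(imc2arg > 0.0 ? imc2arg : 0.0);

  out[0] = autoc;       out[1] = contrast;   out[2] = corr_m;
  out[3] = corr_p;      out[4] = cprom;      out[5] = cshade;
  out[6] = dissim;      out[7] = energy;     out[8] = entropy;
  out[9] = hom_m;       out[10] = hom_p;     out[11] = sosq;
  out[12] = sum_avg;    out[13] = sum_var;   out[14] = sum_ent;
  out[15] = diff_var;   out[16] = diff_ent;  out[17] = imc1;
  out[18] = imc2;       out[19] = idn;       out[20] = maxp;
}

// GLRLM: maximal same-level runs along each direction, summed over directions.
// R is ng x lmax; lmax = longest possible run in the box.
static void glrlm_accumulate(const std::vector<int> &q, const int bd[3],
                             const int (*dirs)[3], int n_dir, int n_levels,
                             std::vector<double> &R, int &lmax_out) {
  const int lmax = std::max(bd[0], std::max(bd[1], bd[2]));
  lmax_out = lmax;
  R.assign((size_t)n_levels * lmax, 0.0);
  for (int d = 0; d < n_dir; ++d) {
    const int dx = dirs[d][0], dy = dirs[d][1], dz = dirs[d][2];
    for (int z = 0; z < bd[2]; ++z)
      for (int y = 0; y < bd[1]; ++y)
        for (int x = 0; x < bd[0]; ++x) {
          // start of a scan line: predecessor outside the box
          const int px_ = x - dx, py_ = y - dy, pz_ = z - dz;
          if (px_ >= 0 && px_ < bd[0] && py_ >= 0 && py_ < bd[1] &&
              pz_ >= 0 && pz_ < bd[2])
            continue;
          int cx = x, cy = y, cz = z;
          int cur = q[(size_t)cz * bd[0] * bd[1] + (size_t)cy * bd[0] + cx];
          int len = 0;
          while (cx >= 0 && cx < bd[0] && cy >= 0 && cy < bd[1] &&
                 cz >= 0 && cz < bd[2]) {
            const int v = q[(size_t)cz * bd[0] * bd[1] + (size_t)cy * bd[0] + cx];
            if (v == cur) {
              ++len;
            } else {
              R[(size_t)(cur - 1) * lmax + (len - 1)] += 1.0;
              cur = v;
              len = 1;
            }
            cx += dx; cy += dy; cz += dz;
          }
          R[(size_t)(cur - 1) * lmax + (len - 1)] += 1.0;
        }
  }
}

static void glrlm_features(const std::vector<double> &R, int ng, int lmax,
                           double n_voxels, int n_dir, double *out) {
  double nr = 0, sre = 0, lre = 0, lgle = 0, hgle = 0;
  std::vector<double> rg(ng, 0.0), rl(lmax, 0.0);
  for (int g = 0; g < ng; ++g)
    for (int l = 0; l < lmax; ++l) {
      const double r = R[(size_t)g * lmax + l];
      if (r == 0.0) continue;
      nr += r;
      const double gl = g + 1, ll = l + 1;
      sre += r / (ll * ll);
      lre += r * ll * ll;
      lgle += r / (gl * gl);
      hgle += r * gl * gl;
      rg[g] += r;
      rl[l] += r;
    }
  double gln = 0, rln = 0;
  for (int g = 0; g < ng; ++g) gln += rg[g] * rg[g];
  for (int l = 0; l < lmax; ++l) rln += rl[l] * rl[l];
  const double np = n_voxels * n_dir;
  out[0] = sre / nr;
  out[1] = lre / nr;
  out[2] = gln / nr;
  out[3] = nr / np;      // run percentage
  out[4] = rln / nr;
  out[5] = lgle / nr;
  out[6] = hgle / nr;
  out[7] = rln / (nr * nr);  // run length non-uniformity normalized
}

// the 13 unique 3D directions at Chebyshev distance 1
static const int DIRS13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// ---- exported single-patch kernels (wrapped and documented in R) ----------

// [[Rcpp::export]]
IntegerVector cpp_quantize(NumericVector x, int n_levels) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> q;
  quantize_patch(xv, n_levels, q);
  IntegerVector out(q.begin(), q.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_first_order(NumericVector x, int n_levels) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> q;
  quantize_patch(xv, n_levels, q);
  NumericVector out(N_FO);
  first_order(xv, q, n_levels, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector q, IntegerVector boxdim, int n_levels,
                       IntegerMatrix offsets) {
  std::vector<int> qv(q.begin(), q.end());
  const int bd[3] = {boxdim[0], boxdim[1], boxdim[2]};
  const int n_off = offsets.nrow();
  std::vector<int> buf(n_off * 3);
  for (int o = 0; o < n_off; ++o)
    for (int k = 0; k < 3; ++k) buf[o * 3 + k] = offsets(o, k);
  std::vector<double> P;
  glcm_accumulate(qv, bd, (const int(*)[3])buf.data(), n_off, n_levels, P);
  NumericMatrix out(n_levels, n_levels);
  for (int i = 0; i < n_levels; ++i)
    for (int j = 0; j < n_levels; ++j)
      out(i, j) = P[(size_t)i * n_levels + j];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glcm_features(NumericMatrix P) {
  const int ng = P.nrow();
  std::vector<double> Pv((size_t)ng * ng);
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j) Pv[(size_t)i * ng + j] = P(i, j);
  NumericVector out(N_GLCM);
  glcm_features(Pv, ng, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector q, IntegerVector boxdim, int n_levels,
                        IntegerMatrix directions) {
  std::vector<int> qv(q.begin(), q.end());
  const int bd[3] = {boxdim[0], boxdim[1], boxdim[2]};
  const int n_dir = directions.nrow();
  std::vector<int> buf(n_dir * 3);
  for (int d = 0; d < n_dir; ++d)
    for (int k = 0; k < 3; ++k) buf[d * 3 + k] = directions(d, k);
  std::vector<double> R;
  int lmax = 0;
  glrlm_accumulate(qv, bd, (const int(*)[3])buf.data(), n_dir, n_levels, R, lmax);
  NumericMatrix out(n_levels, lmax);
  for (int g = 0; g < n_levels; ++g)
    for (int l = 0; l < lmax; ++l) out(g, l) = R[(size_t)g * lmax + l];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm_features(NumericMatrix R, double n_voxels, int n_dir) {
  const int ng = R.nrow(), lmax = R.ncol();
  std::vector<double> Rv((size_t)ng * lmax);
  for (int g = 0; g < ng; ++g)
    for (int l = 0; l < lmax; ++l) Rv[(size_t)g * lmax + l] = R(g, l);
  NumericVector out(N_GLRLM);
  glrlm_features(Rv, ng, lmax, n_voxels, n_dir, REAL(out));
  return out;
}

// ---- bulk voxel-wise extraction ------------------------------------------

// volumes: list of 3D numeric arrays sharing `dim`; voxels: 1-based linear
// indices of mask voxels; window: odd cube side; returns n_voxels x
// (n_modalities * 42) feature matrix (13 first-order + 21 GLCM + 8 GLRLM
// per modality). Edge patches use the intersection of the window with the
// volume.
// [[Rcpp::export]]
NumericMatrix cpp_voxelwise_features(List volumes, IntegerVector dim,
                                     NumericVector voxels, int window,
                                     int n_levels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nmod = volumes.size();
  const R_xlen_t nvox = voxels.size();
  const int per_mod = N_FO + N_GLCM + N_GLRLM;
  NumericMatrix out(nvox, (R_xlen_t)nmod * per_mod);
  const int half = window / 2;

  std::vector<const double *> vols(nmod);
  for (int m = 0; m < nmod; ++m) {
    NumericVector v = volumes[m];
    vols[m] = REAL(v);
  }

  std::vector<double> patch;
  std::vector<int> q;
  std::vector<double> P, R;
  double fo[N_FO], gf[N_GLCM], rf[N_GLRLM];

  for (R_xlen_t vi = 0; vi < nvox; ++vi) {
    const R_xlen_t lin = (R_xlen_t)voxels[vi] - 1;
    const int x = (int)(lin % nx);
    const int y = (int)((lin / nx) % ny);
    const int z = (int)(lin / ((R_xlen_t)nx * ny));
    const int x0 = std::max(0, x - half), x1 = std::min(nx - 1, x + half);
    const int y0 = std::max(0, y - half), y1 = std::min(ny - 1, y + half);
    const int z0 = std::max(0, z - half), z1 = std::min(nz - 1, z + half);
    const int bd[3] = {x1 - x0 + 1, y1 - y0 + 1, z1 - z0 + 1};
    const size_t np = (size_t)bd[0] * bd[1] * bd[2];
    patch.resize(np);
    for (int m = 0; m < nmod; ++m) {
      const double *v = vols[m];
      size_t k = 0;
      for (int zz = z0; zz <= z1; ++zz)
        for (int yy = y0; yy <= y1; ++yy)
          for (int xx = x0; xx <= x1; ++xx)
            patch[k++] = v[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
      quantize_patch(patch, n_levels, q);
      first_order(patch, q, n_levels, fo);
      glcm_accumulate(q, bd, DIRS13, 13, n_levels, P);
      glcm_features(P, n_levels, gf);
      int lmax = 0;
      glrlm_accumulate(q, bd, DIRS13, 13, n_levels, R, lmax);
      glrlm_features(R, n_levels, lmax, (double)np, 13, rf);
      const R_xlen_t c0 = (R_xlen_t)m * per_mod;
      for (int k2 = 0; k2 < N_FO; ++k2) out(vi, c0 + k2) = fo[k2];
      for (int k2 = 0; k2 < N_GLCM; ++k2) out(vi, c0 + N_FO + k2) = gf[k2];
      for (int k2 = 0; k2 < N_GLRLM; ++k2)
        out(vi, c0 + N_FO + N_GLCM + k2) = rf[k2];
    }
    if (vi % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
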