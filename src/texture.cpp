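#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 13 unique 3D directions (half of the 26-neighborhood, one per axis pair)
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Separable 3D convolution with edge replication. Kernels are applied along
// x, y, z in turn; pass a length-1 kernel c(1) to skip an axis.
// [[Rcpp::export]]
NumericVector cpp_sep_conv3d(NumericVector vol, IntegerVector dim,
                             NumericVector kx, NumericVector ky,
                             NumericVector kz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector a(clone(vol)), b(vol.size());
  const NumericVector* kers[3] = {&kx, &ky, &kz};
  for (int axis = 0; axis < 3; ++axis) {
    const NumericVector& k = *kers[axis];
    int kn = k.size(), half = (kn - 1) / 2;
    if (kn == 1 && k[0] == 1.0) continue;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = 0; t < kn; ++t) {
            int xx = x, yy = y, zz = z, off = t - half;
            if (axis == 0) xx = std::min(std::max(x + off, 0), nx - 1);
            else if (axis == 1) yy = std::min(std::max(y + off, 0), ny - 1);
            else zz = std::min(std::max(z + off, 0), nz - 1);
            s += k[t] * a[idx3(xx, yy, zz, nx, ny)];
          }
          b[idx3(x, y, z, nx, ny)] = s;
        }
    std::swap(a, b);
  }
  return a;
}

// type-7 quantile on a sorted vector
static double q7(const std::vector<double>& s, double p) {
  int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  double frac = h - lo;
  if (lo + 1 >= n) return s[n - 1];
  return s[lo] * (1 - frac) + s[lo + 1] * frac;
}

// 19 first-order statistics of the in-mask 3x3x3 neighborhood of every mask
// voxel. Entropy/uniformity are computed on the discretized values `binned`
// (1..nbins inside the ROI). Rows with fewer than 2 in-mask neighbors are NA.
// Column order must match local_feature_names() on the R side.
// [[Rcpp::export]]
List cpp_local_stats(NumericVector vol, IntegerVector binned,
                     IntegerVector mask, IntegerVector dim,
                     double voxel_volume, int nbins, int half_window) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> vox;
  for (int i = 0; i < mask.size(); ++i) if (mask[i]) vox.push_back(i);
  int n = vox.size();
  NumericMatrix out(n, 19);
  IntegerVector nin(n);
  std::vector<double> vals, svals;
  std::vector<int> bins, cnt(nbins + 1);
  for (int v = 0; v < n; ++v) {
    int i = vox[v];
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    vals.clear(); bins.clear();
    for (int dz = -half_window; dz <= half_window; ++dz)
      for (int dy = -half_window; dy <= half_window; ++dy)
        for (int dx = -half_window; dx <= half_window; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (mask[j]) { vals.push_back(vol[j]); bins.push_back(binned[j]); }
        }
    int m = vals.size();
    nin[v] = m;
    if (m < 2) {
      for (int c = 0; c < 19; ++c) out(v, c) = NA_REAL;
      continue;
    }
    svals = vals;
    std::sort(svals.begin(), svals.end());
    double sum = 0, sum2 = 0;
    for (double u : vals) { sum += u; sum2 += u * u; }
    double mean = sum / m;
    double var = sum2 / m - mean * mean;
    if (var < 0) var = 0;
    double m3 = 0, m4 = 0, mad = 0;
    for (double u : vals) {
      double d = u - mean;
      m3 += d * d * d; m4 += d * d * d * d; mad += std::fabs(d);
    }
    m3 /= m; m4 /= m; mad /= m;
    double p10 = q7(svals, 0.10), p25 = q7(svals, 0.25), p50 = q7(svals, 0.50),
           p75 = q7(svals, 0.75), p90 = q7(svals, 0.90);
    double rsum = 0; int rn = 0;
    for (double u : vals) if (u >= p10 && u <= p90) { rsum += u; ++rn; }
    double rmad = 0;
    if (rn > 0) {
      double rmean = rsum / rn;
      for (double u : vals) if (u >= p10 && u <= p90) rmad += std::fabs(u - rmean);
      rmad /= rn;
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int b : bins) if (b >= 1 && b <= nbins) cnt[b]++;
    double ent = 0, uni = 0;
    for (int b = 1; b <= nbins; ++b) if (cnt[b]) {
      double p = (double)cnt[b] / m;
      ent -= p * std::log2(p); uni += p * p;
    }
    double sd = std::sqrt(var);
    out(v, 0) = sum2;                     // energy
    out(v, 1) = sum2 * voxel_volume;      // total energy
    out(v, 2) = ent;                      // entropy
    out(v, 3) = svals[0];                 // minimum
    out(v, 4) = p10;
    out(v, 5) = p90;
    out(v, 6) = svals[m - 1];             // maximum
    out(v, 7) = mean;
    out(v, 8) = p50;                      // median
    out(v, 9) = p75 - p25;                // IQR
    out(v, 10) = svals[m - 1] - svals[0]; // range
    out(v, 11) = mad;
    out(v, 12) = rmad;
    out(v, 13) = std::sqrt(sum2 / m);     // RMS
    out(v, 14) = sd;
    out(v, 15) = var > 0 ? m3 / (var * sd) : 0.0;   // skewness
    out(v, 16) = var > 0 ? m4 / (var * var) : 0.0;  // kurtosis
    out(v, 17) = var;
    out(v, 18) = uni;
  }
  return List::create(_["stats"] = out, _["n_in"] = nin,
                      _["index"] = wrap(vox));
}

// GLCM: nbins x nbins x 13 array of symmetric co-occurrence counts,
// one slab per direction (distance 1).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector binned, IntegerVector dim, int nbins) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(nbins * nbins * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* slab = &out[d * nbins * nbins];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!binned[i]) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (!binned[j]) continue;
          int a = binned[i] - 1, b = binned[j] - 1;
          slab[a + nbins * b] += 1.0;
          slab[b + nbins * a] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nbins, nbins, 13);
  return out;
}

// GLRLM: nbins x maxlen x 13 run-length counts per direction.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector binned, IntegerVector dim, int nbins) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(nbins * maxlen * 13);
  std::vector<char> seen(binned.size());
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* slab = &out[d * nbins * maxlen];
    std::fill(seen.begin(), seen.end(), 0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!binned[i] || seen[i]) continue;
          // only start a run at a voxel with no valid predecessor
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && py >= 0 && pz >= 0 && px < nx && py < ny && pz < nz) {
            int pj = idx3(px, py, pz, nx, ny);
            if (binned[pj] == binned[i]) continue;
          }
          int level = binned[i], len = 0;
          int cx = x, cy = y, cz = z;
          while (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny &&
                 cz < nz) {
            int j = idx3(cx, cy, cz, nx, ny);
            if (binned[j] != level) break;
            seen[j] = 1; ++len;
            cx += dx; cy += dy; cz += dz;
          }
          slab[(level - 1) + nbins * (len - 1)] += 1.0;
        }
    std::fill(seen.begin(), seen.end(), 0);
  }
  out.attr("dim") = IntegerVector::create(nbins, maxlen, 13);
  return out;
}

// GLSZM zones: connected components (26-connectivity) of equal gray level.
// Returns a 2-column matrix (level, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector binned, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> seen(binned.size(), 0);
  std::vector<int> levels, sizes, stack;
  for (int i = 0; i < binned.size(); ++i) {
    if (!binned[i] || seen[i]) continue;
    int level = binned[i], size = 0;
    stack.clear(); stack.push_back(i); seen[i] = 1;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back(); ++size;
      int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                zz >= nz)
              continue;
            int k = idx3(xx, yy, zz, nx, ny);
            if (!seen[k] && binned[k] == level) { seen[k] = 1; stack.push_back(k); }
          }
    }
    levels.push_back(level); sizes.push_back(size);
  }
  IntegerMatrix out(levels.size(), 2);
  for (size_t r = 0; r < levels.size(); ++r) {
    out(r, 0) = levels[r]; out(r, 1) = sizes[r];
  }
  return out;
}

// GLDM: nbins x 27 dependence matrix; dependence = 1 + number of 26-neighbors
// whose binned level differs from the center by at most alpha.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector binned, IntegerVector dim, int nbins,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nbins, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!binned[i]) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz)
                continue;
              int j = idx3(xx, yy, zz, nx, ny);
              if (binned[j] && std::abs(binned[j] - binned[i]) <= alpha) ++dep;
            }
        out(binned[i] - 1, dep) += 1.0;
      }
  return out;
}

// NGTDM: per gray level, voxel count n_i and summed absolute difference s_i
// between the level and the mean of its in-ROI 26-neighbors.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector binned, IntegerVector dim, int nbins) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(nbins, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!binned[i]) continue;
        double nb = 0, sum = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz)
                continue;
              int j = idx3(xx, yy, zz, nx, ny);
              if (binned[j]) { nb += 1.0; sum += binned[j]; }
            }
        out(binned[i] - 1, 0) += 1.0;
        if (nb > 0) out(binned[i] - 1, 1) += std::fabs(binned[i] - sum / nb);
      }
  return out;
}

// valid-mode 2D convolution of one image with K filters; ReLU then global
// mean and max pooling per filter. Returns c(mean1, max1, mean2, max2, ...).
// [[Rcpp::export]]
NumericVector cpp_conv_relu_pool(NumericMatrix img, List filters) {
  int K = filters.size();
  NumericVector out(2 * K);
  int nr = img.nrow(), nc = img.ncol();
  for (int k = 0; k < K; ++k) {
    NumericMatrix f = filters[k];
    int fr = f.nrow(), fc = f.ncol();
    int or_ = nr - fr + 1, oc = nc - fc + 1;
    double sum = 0.0, mx = 0.0;
    for (int j = 0; j < oc; ++j)
      for (int i = 0; i < or_; ++i) {
        double s = 0.0;
        for (int b = 0; b < fc; ++b)
          for (int a = 0; a < fr; ++a)
            s += f(a, b) * img(i + a, j + b);
        if (s < 0) s = 0;
        sum += s;
        if (s > mx) mx = s;
      }
    out[2 * k] = sum / (or_ * oc);
    out[2 * k + 1] = mx;
  }
  return out;
}

static inline double xlog2c(double p) { return p > 0 ? p * std::log2(p) : 0.0; }

// All 22 GLCM features for each direction slab of a ng x ng x 13 count
// array. Column order matches glcm_feature_names() on the R side.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_features(NumericVector glcm, int nbins) {
  int nd = glcm.size() / (nbins * nbins);
  NumericMatrix out(22, nd);
  std::vector<int> keep;
  std::vector<double> P, px, pd, ps;
  for (int d = 0; d < nd; ++d) {
    const double* slab = &glcm[d * nbins * nbins];
    double tot = 0;
    keep.clear();
    for (int r = 0; r < nbins; ++r) {
      double rs = 0;
      for (int c = 0; c < nbins; ++c) rs += slab[r + nbins * c];
      if (rs > 0) keep.push_back(r);
      tot += rs;
    }
    int ng = keep.size();
    if (tot == 0 || ng == 0) {
      for (int f = 0; f < 22; ++f) out(f, d) = 0.0;
      out(5, d) = 1.0;  // correlation
      continue;
    }
    P.assign(ng * ng, 0.0);
    px.assign(ng, 0.0);
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b) {
        P[a + ng * b] = slab[keep[a] + nbins * keep[b]] / tot;
        px[a] += P[a + ng * b];
      }
    // levels are 1-based gray values
    double mu = 0;
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b) mu += (keep[a] + 1) * P[a + ng * b];
    double sig2 = 0, autoc = 0, cp = 0, cs = 0, ct = 0, contrast = 0;
    double id = 0, idm = 0, idmn = 0, idn = 0, invvar = 0;
    double je = 0, hxy = 0, maxp = 0, hxy1 = 0, hxy2 = 0;
    int maxdiff = 0;
    for (int a = 0; a < ng; ++a) {
      int i = keep[a] + 1;
      sig2 += (i - mu) * (i - mu) * px[a];
      for (int b = 0; b < ng; ++b) {
        int j = keep[b] + 1;
        double p = P[a + ng * b];
        int dd = std::abs(i - j);
        if (dd > maxdiff) maxdiff = dd;
        autoc += (double)i * j * p;
        double s2m = i + j - 2 * mu;
        cp += s2m * s2m * s2m * s2m * p;
        cs += s2m * s2m * s2m * p;
        ct += s2m * s2m * p;
        contrast += dd * dd * p;
        id += p / (1 + dd);
        idm += p / (1 + dd * dd);
        idmn += p / (1 + (double)dd * dd / ((double)ng * ng));
        idn += p / (1 + (double)dd / ng);
        if (dd) invvar += p / ((double)dd * dd);
        je += p * p;
        hxy -= xlog2c(p);
        if (p > maxp) maxp = p;
        double pp = px[a] * px[b];
        if (pp > 0) hxy1 -= p * std::log2(pp);
        hxy2 -= xlog2c(pp);
      }
    }
    pd.assign(maxdiff + 1, 0.0);
    ps.assign(2 * nbins + 1, 0.0);
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b) {
        pd[std::abs(keep[a] - keep[b])] += P[a + ng * b];
        ps[keep[a] + keep[b] + 2] += P[a + ng * b];
      }
    double da = 0, de = 0, dv = 0, se = 0;
    for (size_t k = 0; k < pd.size(); ++k) { da += k * pd[k]; de -= xlog2c(pd[k]); }
    for (size_t k = 0; k < pd.size(); ++k) dv += (k - da) * (k - da) * pd[k];
    for (size_t k = 0; k < ps.size(); ++k) se -= xlog2c(ps[k]);
    double hx = 0;
    for (int a = 0; a < ng; ++a) hx -= xlog2c(px[a]);
    double imc1 = hx > 0 ? (hxy - hxy1) / hx : 0.0;
    double e2 = 1 - std::exp(-2 * (hxy2 - hxy));
    double imc2 = e2 > 0 ? std::sqrt(e2) : 0.0;
    double corr = sig2 > 0 ? (autoc - mu * mu) / sig2 : 1.0;
    double vals[22] = {autoc, cp, cs, ct, contrast, corr, da, de, dv,
                       id, idm, idmn, idn, imc1, imc2, invvar, mu, je,
                       hxy, maxp, se, sig2};
    for (int f = 0; f < 22; ++f) out(f, d) = vals[f];
  }
  return out;
}

// The 16 run-length-style features for each direction slab of a
// nbins x maxlen x nd count array. Order matches the R naming vectors.
// [[Rcpp::export]]
NumericMatrix cpp_run_features(NumericVector arr, int nbins, int maxlen,
                               double np) {
  int nd = arr.size() / (nbins * maxlen);
  NumericMatrix out(16, nd);
  for (int d = 0; d < nd; ++d) {
    const double* slab = &arr[d * nbins * maxlen];
    double nr = 0;
    for (int k = 0; k < nbins * maxlen; ++k) nr += slab[k];
    if (nr == 0) continue;
    double sre = 0, lre = 0, gln = 0, rln = 0, glv = 0, rv = 0, re = 0;
    double lgl = 0, hgl = 0, srl = 0, srh = 0, lrl = 0, lrh = 0;
    double mui = 0, mul = 0;
    for (int i = 0; i < nbins; ++i) {
      double ri = 0;
      for (int l = 0; l < maxlen; ++l) ri += slab[i + nbins * l];
      gln += ri * ri;
      for (int l = 0; l < maxlen; ++l) {
        double v = slab[i + nbins * l];
        if (v == 0) continue;
        double gl = i + 1, ln = l + 1, p = v / nr;
        mui += gl * p; mul += ln * p;
        sre += v / (ln * ln); lre += v * ln * ln;
        lgl += v / (gl * gl); hgl += v * gl * gl;
        srl += v / (gl * gl * ln * ln); srh += v * gl * gl / (ln * ln);
        lrl += v * ln * ln / (gl * gl); lrh += v * gl * gl * ln * ln;
        re -= xlog2c(p);
      }
    }
    for (int l = 0; l < maxlen; ++l) {
      double cl = 0;
      for (int i = 0; i < nbins; ++i) cl += slab[i + nbins * l];
      rln += cl * cl;
    }
    for (int i = 0; i < nbins; ++i)
      for (int l = 0; l < maxlen; ++l) {
        double v = slab[i + nbins * l];
        if (v == 0) continue;
        double p = v / nr;
        glv += (i + 1 - mui) * (i + 1 - mui) * p;
        rv += (l + 1 - mul) * (l + 1 - mul) * p;
      }
    double vals[16] = {sre / nr, lre / nr, gln / nr, gln / (nr * nr),
                       rln / nr, rln / (nr * nr), nr / np, glv, rv, re,
                       lgl / nr, hgl / nr, srl / nr, srh / nr, lrl / nr,
                       lrh / nr};
    for (int f = 0; f < 16; ++f) out(f, d) = vals[f];
  }
  return out;
}
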