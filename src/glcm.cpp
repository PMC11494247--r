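#include <Rcpp.h>
using namespace Rcpp;

// 13 unique unit 3-D offsets: the lexicographically-positive half of the
// 26-neighbourhood. Symmetric accumulation below counts both directions.
static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {-1, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {-1, 0, 1}, {0, 1, 1}, {0, -1, 1},
  {1, 1, 1}, {-1, 1, 1}, {1, -1, 1}, {-1, -1, 1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Accumulate the symmetric co-occurrence counts for one window centred at
// (cx,cy,cz); both pair members must lie in the window, the grid and the mask.
static double window_glcm(const IntegerVector& bins, const LogicalVector& mask,
                          int nx, int ny, int nz, int cx, int cy, int cz,
                          int radius, int nlev, std::vector<double>& counts) {
  std::fill(counts.begin(), counts.end(), 0.0);
  const int x0 = std::max(0, cx - radius), x1 = std::min(nx - 1, cx + radius);
  const int y0 = std::max(0, cy - radius), y1 = std::min(ny - 1, cy + radius);
  const int z0 = std::max(0, cz - radius), z1 = std::min(nz - 1, cz + radius);
  double total = 0.0;
  for (int z = z0; z <= z1; ++z)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        const int ia = idx3(x, y, z, nx, ny);
        if (!mask[ia]) continue;
        const int ga = bins[ia];
        for (int o = 0; o < 13; ++o) {
          const int xb = x + OFFS[o][0], yb = y + OFFS[o][1], zb = z + OFFS[o][2];
          if (xb < x0 || xb > x1 || yb < y0 || yb > y1 || zb < z0 || zb > z1)
            continue;
          const int ib = idx3(xb, yb, zb, nx, ny);
          if (!mask[ib]) continue;
          const int gb = bins[ib];
          counts[ga + nlev * gb] += 1.0;
          counts[gb + nlev * ga] += 1.0;
          total += 2.0;
        }
      }
  return total;
}

static void haralick4(const std::vector<double>& p, int nlev, double total,
                      double* out) {
  double energy = 0.0, entropy = 0.0, contrast = 0.0, homog = 0.0;
  for (int j = 0; j < nlev; ++j)
    for (int i = 0; i < nlev; ++i) {
      const double q = p[i + nlev * j] / total;
      if (q > 0.0) {
        energy += q * q;
        entropy -= q * std::log(q);
        contrast += (double)(i - j) * (i - j) * q;
        homog += q / (1.0 + std::abs(i - j));
      }
    }
  out[0] = energy; out[1] = entropy; out[2] = contrast; out[3] = homog;
}

// [[Rcpp::export]]
List cpp_texture_maps(IntegerVector bins, LogicalVector mask, IntegerVector dims,
                      int radius, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> vox;
  for (int i = 0; i < mask.size(); ++i) if (mask[i]) vox.push_back(i);
  const int n = (int)vox.size();
  NumericMatrix feats(n, 4);
  LogicalVector degen(n);
  std::vector<double> counts(nlev * nlev);
  double out[4];
  for (int v = 0; v < n; ++v) {
    const int i = vox[v];
    const int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    const double total = window_glcm(bins, mask, nx, ny, nz, x, y, z,
                                     radius, nlev, counts);
    if (total <= 0.0) {
      degen[v] = true;
      feats(v, 0) = NA_REAL; feats(v, 1) = NA_REAL;
      feats(v, 2) = NA_REAL; feats(v, 3) = NA_REAL;
    } else {
      degen[v] = false;
      haralick4(counts, nlev, total, out);
      for (int k = 0; k < 4; ++k) feats(v, k) = out[k];
    }
  }
  colnames(feats) = CharacterVector::create("Energy", "Entropy",
                                            "Contrast", "Homogeneity");
  return List::create(_["features"] = feats, _["degenerate"] = degen,
                      _["voxel_index"] = IntegerVector(vox.begin(), vox.end()));
}

// Single-voxel normalized GLCM, exposed for oracle tests. center is 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_voxel_glcm(IntegerVector bins, LogicalVector mask,
                             IntegerVector dims, IntegerVector center,
                             int radius, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> counts(nlev * nlev);
  const double total = window_glcm(bins, mask, nx, ny, nz,
                                   center[0] - 1, center[1] - 1, center[2] - 1,
                                   radius, nlev, counts);
  NumericMatrix p(nlev, nlev);
  if (total > 0.0)
    for (int j = 0; j < nlev; ++j)
      for (int i = 0; i < nlev; ++i)
        p(i, j) = counts[i + nlev * j] / total;
  return p;
}
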