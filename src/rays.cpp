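#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray sampling convention (shared with the R reference implementation):
// in-plane (axial, fixed z) rays from a center voxel, sampled at unit steps
// t = 1..floor(radius); sample voxel = (x + floor(t*cos(a)+0.5),
// y + floor(t*sin(a)+0.5)) (nearest voxel; floor(v+0.5) avoids R's banker's
// rounding). Out-of-bounds samples are dropped; an empty ray contributes the
// background value 0. The per-ray mean intensity is normalized as
// (m - hmin)/(hmax - hmin) and clipped to [0, 1].

static inline int round_half_up(double v) {
  return (int)std::floor(v + 0.5);
}

static double ray_mean_one(const NumericVector& vol, int nx, int ny,
                           int cx, int cy, int cz,
                           double angle, double radius,
                           double hmin, double hmax) {
  int nsteps = (int)std::floor(radius + 1e-9);
  double ca = std::cos(angle), sa = std::sin(angle);
  double sum = 0.0;
  int cnt = 0;
  for (int t = 1; t <= nsteps; ++t) {
    int x = cx + round_half_up(t * ca);
    int y = cy + round_half_up(t * sa);
    if (x < 0 || x >= nx || y < 0 || y >= ny) continue;
    sum += vol[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * cz)];
    ++cnt;
  }
  if (cnt == 0) return 0.0;
  double m = (sum / cnt - hmin) / (hmax - hmin);
  if (m < 0.0) m = 0.0;
  if (m > 1.0) m = 1.0;
  return m;
}

// [[Rcpp::export(name = ".ray_mean_cpp")]]
double ray_mean_cpp(NumericVector vol, IntegerVector dims,
                    IntegerVector center, double angle, double radius,
                    double hmin, double hmax) {
  // center is 1-based (R convention)
  return ray_mean_one(vol, dims[0], dims[1],
                      center[0] - 1, center[1] - 1, center[2] - 1,
                      angle, radius, hmin, hmax);
}

// Pooled ray features for many voxels: for each voxel, average the per-ray
// normalized means within each radius band (bands given per radius as
// 1-based indices). Returns an n_voxel x n_band matrix.
// [[Rcpp::export(name = ".ray_band_features_cpp")]]
NumericMatrix ray_band_features_cpp(NumericVector vol, IntegerVector dims,
                                    IntegerMatrix voxels,   // n x 3, 1-based
                                    NumericVector angles,
                                    NumericVector radii,
                                    IntegerVector band_of_radius, // 1-based
                                    int n_bands,
                                    double hmin, double hmax) {
  int n = voxels.nrow();
  int nx = dims[0], ny = dims[1];
  NumericMatrix out(n, n_bands);
  std::vector<int> band_count(n_bands, 0);
  for (int r = 0; r < radii.size(); ++r)
    band_count[band_of_radius[r] - 1] += angles.size();
  for (int i = 0; i < n; ++i) {
    int cx = voxels(i, 0) - 1, cy = voxels(i, 1) - 1, cz = voxels(i, 2) - 1;
    std::vector<double> acc(n_bands, 0.0);
    for (int r = 0; r < radii.size(); ++r) {
      int b = band_of_radius[r] - 1;
      for (int a = 0; a < angles.size(); ++a)
        acc[b] += ray_mean_one(vol, nx, ny, cx, cy, cz,
                               angles[a], radii[r], hmin, hmax);
    }
    for (int b = 0; b < n_bands; ++b)
      out(i, b) = band_count[b] > 0 ? acc[b] / band_count[b] : 0.0;
  }
  return out;
}
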