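#include <Rcpp.h>
using namespace Rcpp;

// Straight-track, constant-LET electron transport on a labeled voxel grid.
//
// Each history samples a decay site uniformly within the thyroid voxels and an
// isotropic direction, then marks energy deposition along a straight track of
// length equal to the CSDA range.  The absorbed fraction of one history is the
// fraction of track midpoints lying in thyroid-labeled voxels, which converges
// to min(range, inside path length)/range.  Histories are accumulated into
// n_batch equal batches so the caller can form a batch-means standard error.
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
//
// labels:  integer voxel labels, column-major (x fastest), thyroid == 2
// dims:    grid dimensions (nx, ny, nz)
// thy_idx: 0-based linear indices of thyroid voxels (decay sites)
// [[Rcpp::export]]
NumericVector cpp_track_batch_fractions(IntegerVector labels, IntegerVector dims,
                                        double voxel_mm, IntegerVector thy_idx,
                                        double range_mm, int n, int n_batch,
                                        int n_sub) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_thy = thy_idx.size();
  if (n_thy == 0) stop("phantom has no thyroid voxels");
  if (n < 1) stop("n must be >= 1");
  if (n_batch < 1 || n_batch > n) n_batch = 1;

  NumericVector batch_sum(n_batch);
  IntegerVector batch_n(n_batch);
  const double ds = range_mm / n_sub;
  const long long sxy = (long long)nx * ny;

  for (int h = 0; h < n; ++h) {
    int b = (int)(((double)h * n_batch) / n);
    if (b >= n_batch) b = n_batch - 1;

    int t = (int)(unif_rand() * n_thy);
    if (t >= n_thy) t = n_thy - 1;
    const long long lin = thy_idx[t];
    const int iz = (int)(lin / sxy);
    const long long rem = lin - (long long)iz * sxy;
    const int iy = (int)(rem / nx);
    const int ix = (int)(rem - (long long)iy * nx);

    const double px = (ix + unif_rand()) * voxel_mm;
    const double py = (iy + unif_rand()) * voxel_mm;
    const double pz = (iz + unif_rand()) * voxel_mm;

    const double cu = 2.0 * unif_rand() - 1.0;
    const double su = std::sqrt(std::max(0.0, 1.0 - cu * cu));
    const double ph = 2.0 * M_PI * unif_rand();
    const double dx = su * std::cos(ph), dy = su * std::sin(ph), dz = cu;

    int inside = 0;
    for (int k = 0; k < n_sub; ++k) {
      const double s = (k + 0.5) * ds;
      const int jx = (int)std::floor((px + s * dx) / voxel_mm);
      const int jy = (int)std::floor((py + s * dy) / voxel_mm);
      const int jz = (int)std::floor((pz + s * dz) / voxel_mm);
      if (jx >= 0 && jx < nx && jy >= 0 && jy < ny && jz >= 0 && jz < nz &&
          labels[jx + (long long)nx * jy + sxy * jz] == 2)
        ++inside;
    }
    batch_sum[b] += (double)inside / n_sub;
    batch_n[b] += 1;
  }

  NumericVector out(n_batch);
  for (int b = 0; b < n_batch; ++b)
    out[b] = batch_n[b] > 0 ? batch_sum[b] / batch_n[b] : NA_REAL;
  return out;
}
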