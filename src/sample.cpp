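#include <Rcpp.h>
using namespace Rcpp;

// Resampling kernels shared by apply_rigid() and the registration cost
// function. Points are continuous 0-based voxel indices into a 3-D array
// stored in R's column-major order; anything outside the index domain
// [0, dim-1] maps to `fill`.

static inline double get_vox(const double *v, const int *d, int i, int j, int k) {
  return v[(size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k)];
}

// [[Rcpp::export]]
NumericVector c_sample_trilinear(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts, double fill) {
  const int n = pts.nrow();
  const double *v = vol.begin();
  const int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    if (!(x >= 0.0 && x <= d[0] - 1 && y >= 0.0 && y <= d[1] - 1 &&
          z >= 0.0 && z <= d[2] - 1)) {
      out[r] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    // clamp so a point exactly on the upper face interpolates within the array
    if (i0 > d[0] - 2) i0 = d[0] - 2; if (i0 < 0) i0 = 0;
    if (j0 > d[1] - 2) j0 = d[1] - 2; if (j0 < 0) j0 = 0;
    if (k0 > d[2] - 2) k0 = d[2] - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = get_vox(v, d, i0, j0, k0),     c100 = get_vox(v, d, i0 + 1, j0, k0);
    double c010 = get_vox(v, d, i0, j0 + 1, k0), c110 = get_vox(v, d, i0 + 1, j0 + 1, k0);
    double c001 = get_vox(v, d, i0, j0, k0 + 1), c101 = get_vox(v, d, i0 + 1, j0, k0 + 1);
    double c011 = get_vox(v, d, i0, j0 + 1, k0 + 1), c111 = get_vox(v, d, i0 + 1, j0 + 1, k0 + 1);
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[r] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector c_sample_nearest(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts, double fill) {
  const int n = pts.nrow();
  const double *v = vol.begin();
  const int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || i >= d[0] || j < 0 || j >= d[1] || k < 0 || k >= d[2]) {
      out[r] = fill;
    } else {
      out[r] = get_vox(v, d, i, j, k);
    }
  }
  return out;
}

// Joint histogram of two equal-length value vectors over nbins x nbins
// equal-width bins spanning [alo, ahi] x [blo, bhi]; values are clamped
// into range. Samples are deposited with a first-order B-spline (linear)
// Parzen window along both axes, which removes the hard-binning
// discretization artifacts that otherwise displace the MI optimum.
// [[Rcpp::export]]
NumericMatrix c_joint_hist(NumericVector a, NumericVector b, int nbins,
                           double alo, double ahi, double blo, double bhi) {
  const int n = a.size();
  NumericMatrix h(nbins, nbins);
  const double aw = (ahi - alo), bw = (bhi - blo);
  if (aw <= 0 || bw <= 0) return h;
  for (int r = 0; r < n; ++r) {
    double av = a[r], bv = b[r];
    if (NumericVector::is_na(av) || NumericVector::is_na(bv)) continue;
    // continuous bin coordinate: bin centers at 0 .. nbins-1
    double ua = (av - alo) / aw * nbins - 0.5;
    double ub = (bv - blo) / bw * nbins - 0.5;
    if (ua < 0) ua = 0; if (ua > nbins - 1) ua = nbins - 1;
    if (ub < 0) ub = 0; if (ub > nbins - 1) ub = nbins - 1;
    int ia = (int)std::floor(ua), ib = (int)std::floor(ub);
    if (ia > nbins - 2) ia = nbins - 2; if (ia < 0) ia = 0;
    if (ib > nbins - 2) ib = nbins - 2; if (ib < 0) ib = 0;
    double fa = ua - ia, fb = ub - ib;
    h(ia, ib)         += (1 - fa) * (1 - fb);
    h(ia + 1, ib)     += fa * (1 - fb);
    h(ia, ib + 1)     += (1 - fa) * fb;
    h(ia + 1, ib + 1) += fa * fb;
  }
  return h;
}
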