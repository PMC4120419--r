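// Fourier-domain slice translation and weighted-SSD translation estimation.
//
// Images are nx x ny matrices (axis 1 = right->left, axis 2 = ventral->dorsal).
// A shift (dx, dy) moves image content by +dx along axis 1 and +dy along
// axis 2, using the band-limited (FFT phase-ramp) interpolant, i.e.
// out(x) = img(x - d) evaluated with periodic sinc interpolation.
//
// All transforms use FFTW real-to-complex plans cached per image size.
// Column-major arma storage maps onto a row-major FFTW transform with the
// dimensions swapped, so the half-spectrum is (nx/2+1) x ny.

#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>
#include <utility>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Plans {
  fftw_plan r2c;
  fftw_plan c2r;
};

static Plans& get_plans(int nx, int ny) {
  static std::map<std::pair<int, int>, Plans> cache;
  auto key = std::make_pair(nx, ny);
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  mat rbuf(nx, ny);
  cx_mat cbuf(nx / 2 + 1, ny);
  Plans pp;
  pp.r2c = fftw_plan_dft_r2c_2d(ny, nx, rbuf.memptr(),
                                reinterpret_cast<fftw_complex*>(cbuf.memptr()),
                                FFTW_MEASURE | FFTW_UNALIGNED);
  pp.c2r = fftw_plan_dft_c2r_2d(ny, nx,
                                reinterpret_cast<fftw_complex*>(cbuf.memptr()),
                                rbuf.memptr(), FFTW_MEASURE | FFTW_UNALIGNED);
  return cache.emplace(key, pp).first->second;
}

// forward transform to the half-spectrum (nx/2+1 rows)
static cx_mat rfft2(const mat& x) {
  mat tmp = x; // FFTW_ESTIMATE r2c may not preserve input; copy anyway
  cx_mat out(x.n_rows / 2 + 1, x.n_cols);
  fftw_execute_dft_r2c(get_plans(x.n_rows, x.n_cols).r2c, tmp.memptr(),
                       reinterpret_cast<fftw_complex*>(out.memptr()));
  return out;
}

// inverse of the half-spectrum; normalised. Destroys its copy, not `f`.
static mat irfft2(const cx_mat& f, int nx, int ny) {
  cx_mat tmp = f;
  mat out(nx, ny);
  fftw_execute_dft_c2r(get_plans(nx, ny).c2r,
                       reinterpret_cast<fftw_complex*>(tmp.memptr()),
                       out.memptr());
  return out / double(nx) / double(ny);
}

static cx_vec phase_ramp(unsigned int n, unsigned int n_keep, double shift) {
  // exp(-2*pi*i*k*shift/n) on FFT bins k = 0..n_keep-1 mapped to signed
  // frequencies; the Nyquist bin (even n) is kept real so real input
  // stays real after shifting.
  cx_vec ramp(n_keep);
  const double two_pi = 2.0 * datum::pi;
  for (unsigned int k = 0; k < n_keep; ++k) {
    double freq = (k <= n / 2) ? (double)k : (double)k - (double)n;
    if (n % 2 == 0 && k == n / 2) {
      ramp(k) = cx_double(std::cos(two_pi * freq * shift / n), 0.0);
    } else {
      double ang = -two_pi * freq * shift / n;
      ramp(k) = cx_double(std::cos(ang), std::sin(ang));
    }
  }
  return ramp;
}

// shift image content by (dx, dy) given its half-spectrum
static mat shift_from_spectrum(const cx_mat& F, int nx, int ny,
                               double dx, double dy) {
  cx_vec rx = phase_ramp(nx, F.n_rows, dx);
  cx_vec ry = phase_ramp(ny, F.n_cols, dy);
  cx_mat G = F;
  G.each_col() %= rx;
  G.each_row() %= ry.st();
  return irfft2(G, nx, ny);
}

// [[Rcpp::export]]
arma::mat cpp_fourier_shift(const arma::mat& img, double dx, double dy) {
  return shift_from_spectrum(rfft2(img), img.n_rows, img.n_cols, dx, dy);
}

// [[Rcpp::export]]
arma::cube cpp_shift_stack(const arma::cube& series,
                           const arma::vec& dx, const arma::vec& dy) {
  cube out(size(series));
  for (unsigned int t = 0; t < series.n_slices; ++t) {
    if (dx(t) == 0.0 && dy(t) == 0.0) {
      out.slice(t) = series.slice(t);
    } else {
      out.slice(t) = cpp_fourier_shift(series.slice(t), dx(t), dy(t));
    }
  }
  return out;
}

// Weighted SSD between the target T and the moving image M shifted back by
// a candidate displacement d:
//   f(d) = sum_x w(x) * (M(x + d) - T(x))^2
// which is minimised at d equal to the displacement of M relative to T
// (moving = target content moved by +d).
static double weighted_ssd(const cx_mat& Fmov, int nx, int ny,
                           const mat& target, const mat& weights,
                           double dx, double dy) {
  mat shifted = shift_from_spectrum(Fmov, nx, ny, -dx, -dy);
  shifted -= target;
  return accu(weights % square(shifted));
}

// [[Rcpp::export]]
double cpp_weighted_ssd(const arma::mat& moving, const arma::mat& target,
                        const arma::mat& weights, double dx, double dy) {
  return weighted_ssd(rfft2(moving), moving.n_rows, moving.n_cols,
                      target, weights, dx, dy);
}

// 1-D parabolic vertex through three equally spaced samples; clamped
static double parabola_vertex(double fm, double f0, double fp, double step) {
  double denom = fp + fm - 2.0 * f0;
  if (denom <= 0.0) return 0.0;
  double delta = 0.5 * step * (fm - fp) / denom;
  if (delta > step) delta = step;
  if (delta < -step) delta = -step;
  return delta;
}

// Estimate, for every volume of a slice time series, the in-plane
// translation of that volume relative to the target image: the (dx, dy)
// minimising the weighted SSD above. Integer search is exhaustive over
// |dx|,|dy| <= max_shift via FFT cross-correlation identities; the 3x3
// SSD neighbourhood of the integer optimum seeds a quadratic sub-voxel
// estimate, refined by coordinate-wise parabolic line search on the
// continuous (Fourier-interpolated) objective.
// [[Rcpp::export]]
arma::mat cpp_estimate_stack(const arma::cube& series, const arma::mat& target,
                             const arma::mat& weights, int max_shift,
                             int n_refine) {
  const int nx = series.n_rows, ny = series.n_cols;
  const unsigned int nt = series.n_slices;
  mat est(nt, 2, fill::zeros);

  // f(d) = b(d) - 2 c(d) + const, with
  //   c(d) = sum_x w(x) T(x) M(x + d)  (correlation of w*T with M)
  //   b(d) = sum_x w(x) M(x + d)^2     (correlation of w with M^2)
  // Circular correlations evaluated via FFT; the weight kernel decays to
  // ~0 away from the cord so wrap-around contributions are negligible.
  cx_mat FwT = conj(rfft2(weights % target));
  cx_mat Fw = conj(rfft2(weights));

  auto wrap = [](int i, int n) { return (i % n + n) % n; };

  for (unsigned int t = 0; t < nt; ++t) {
    const mat M = series.slice(t);
    cx_mat Fm = rfft2(M);
    cx_mat Fm2 = rfft2(mat(square(M)));
    mat fmap = irfft2(cx_mat(Fw % Fm2), nx, ny) * 1.0;
    fmap -= 2.0 * irfft2(cx_mat(FwT % Fm), nx, ny);

    double best = datum::inf;
    int bi = 0, bj = 0;
    for (int i = -max_shift; i <= max_shift; ++i) {
      for (int j = -max_shift; j <= max_shift; ++j) {
        double f = fmap(wrap(i, nx), wrap(j, ny));
        // strict < keeps the first (lowest-index) minimum on exact ties
        if (f < best) {
          best = f;
          bi = i;
          bj = j;
        }
      }
    }

    // free sub-voxel seed from the integer SSD neighbourhood
    double d[2];
    d[0] = bi + parabola_vertex(fmap(wrap(bi - 1, nx), wrap(bj, ny)), best,
                                fmap(wrap(bi + 1, nx), wrap(bj, ny)), 1.0);
    d[1] = bj + parabola_vertex(fmap(wrap(bi, nx), wrap(bj - 1, ny)), best,
                                fmap(wrap(bi, nx), wrap(bj + 1, ny)), 1.0);

    // refinement on the exact continuous objective
    double fcur = weighted_ssd(Fm, nx, ny, target, weights, d[0], d[1]);
    double step = 0.25;
    for (int it = 0; it < n_refine; ++it) {
      for (int ax = 0; ax < 2; ++ax) {
        double dp[2] = {d[0], d[1]}, dm[2] = {d[0], d[1]};
        dp[ax] += step;
        dm[ax] -= step;
        double fp = weighted_ssd(Fm, nx, ny, target, weights, dp[0], dp[1]);
        double fm = weighted_ssd(Fm, nx, ny, target, weights, dm[0], dm[1]);
        double delta = parabola_vertex(fm, fcur, fp, step);
        if (delta == 0.0) delta = (fp < fm) ? step : -step;
        double cand[2] = {d[0], d[1]};
        cand[ax] += delta;
        double fc = weighted_ssd(Fm, nx, ny, target, weights, cand[0], cand[1]);
        if (fc < fcur) {
          d[0] = cand[0];
          d[1] = cand[1];
          fcur = fc;
        } else if (fp < fcur) {
          d[0] = dp[0];
          d[1] = dp[1];
          fcur = fp;
        } else if (fm < fcur) {
          d[0] = dm[0];
          d[1] = dm[1];
          fcur = fm;
        }
      }
      step *= 0.5;
    }
    est(t, 0) = d[0];
    est(t, 1) = d[1];
  }
  return est;
}

// [[Rcpp::export]]
arma::vec cpp_row_medians(const arma::mat& x) {
  // median over columns for each row
  return median(x, 1);
}

// ---- matrix-layout helpers (voxels x time, avoiding R-side reshapes) ----

// [[Rcpp::export]]
arma::mat cpp_slice_matrix(const Rcpp::NumericVector& vol, int nx, int ny,
                           int ns, int nt, int s) {
  // extract slice s (1-based) of an [nx, ny, ns, nt] array as voxels x time
  mat out(nx * ny, nt);
  const double* src = vol.begin();
  const size_t plane = (size_t)nx * ny;
  for (int t = 0; t < nt; ++t) {
    std::memcpy(out.colptr(t), src + plane * ((size_t)(s - 1) + (size_t)ns * t),
                plane * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
void cpp_set_slice(Rcpp::NumericVector vol, const arma::mat& M, int nx,
                   int ny, int ns, int nt, int s) {
  // overwrite slice s of a (freshly allocated) [nx, ny, ns, nt] array
  double* dst = vol.begin();
  const size_t plane = (size_t)nx * ny;
  for (int t = 0; t < nt; ++t) {
    std::memcpy(dst + plane * ((size_t)(s - 1) + (size_t)ns * t), M.colptr(t),
                plane * sizeof(double));
  }
}

// [[Rcpp::export]]
arma::mat cpp_shift_mat(const arma::mat& M, int nx, int ny,
                        const arma::vec& dx, const arma::vec& dy) {
  // shift each column (one image in voxel-major layout) by (dx, dy)
  mat out(M.n_rows, M.n_cols);
  for (unsigned int t = 0; t < M.n_cols; ++t) {
    if (dx(t) == 0.0 && dy(t) == 0.0) {
      out.col(t) = M.col(t);
    } else {
      mat img(const_cast<double*>(M.colptr(t)), nx, ny, false, true);
      mat sh = shift_from_spectrum(rfft2(img), nx, ny, dx(t), dy(t));
      std::memcpy(out.colptr(t), sh.memptr(), (size_t)nx * ny * sizeof(double));
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_estimate_mat(const arma::mat& M, int nx, int ny,
                           int target_index, const arma::mat& weights,
                           int max_shift, int n_refine) {
  cube series(nx, ny, M.n_cols);
  for (unsigned int t = 0; t < M.n_cols; ++t) {
    std::memcpy(series.slice(t).memptr(), M.colptr(t),
                (size_t)nx * ny * sizeof(double));
  }
  mat target(const_cast<double*>(M.colptr(target_index - 1)), nx, ny, false,
             true);
  return cpp_estimate_stack(series, mat(target), weights, max_shift, n_refine);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_render_motion(const Rcpp::NumericVector& vol, int nx,
                                      int ny, int ns, int nt,
                                      const arma::cube& trans) {
  // trans is [ns, nt, 2]; shifts each slice-volume by its translation
  Rcpp::NumericVector out = Rcpp::clone(vol);
  double* dst = out.begin();
  const size_t plane = (size_t)nx * ny;
  for (int s = 0; s < ns; ++s) {
    for (int t = 0; t < nt; ++t) {
      double dx = trans(s, t, 0), dy = trans(s, t, 1);
      if (dx == 0.0 && dy == 0.0) continue;
      size_t off = plane * ((size_t)s + (size_t)ns * t);
      mat img(dst + off, nx, ny, false, true);
      mat sh = shift_from_spectrum(rfft2(img), nx, ny, dx, dy);
      std::memcpy(dst + off, sh.memptr(), plane * sizeof(double));
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(nx, ny, ns, nt);
  return out;
}
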