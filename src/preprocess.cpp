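// Per-slice preprocessing core: not-spine PCA regression, two-pass
// weighted motion correction, RETROICOR regression, CSF PCA regression,
// white-matter eigenvector regression, TSNR bookkeeping and zero-phase
// band-pass filtering — one call per slice on the voxels x time matrix.
//
// The component-selection and regression semantics mirror the R-level
// operations (pca_components, select_k, regress_out); those remain the
// reference implementations and are tested against this fast path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// declared in translation.cpp
arma::mat cpp_estimate_stack(const arma::cube& series, const arma::mat& target,
                             const arma::mat& weights, int max_shift,
                             int n_refine);
arma::mat cpp_shift_mat(const arma::mat& M, int nx, int ny,
                        const arma::vec& dx, const arma::vec& dy);
arma::vec cpp_row_medians(const arma::mat& x);

struct Pca {
  vec values;  // normalised eigenvalues, descending
  mat vectors; // nt x k time-course eigenvectors
};

static Pca pca_idx(const mat& M, const uvec& idx, int max_vec) {
  mat Y = M.rows(idx);
  Y.each_col() -= mean(Y, 1);
  mat C = Y.t() * Y;
  vec ev;
  mat V;
  eig_sym(ev, V, C);
  ev = reverse(ev);
  V = fliplr(V);
  ev = clamp(ev, 0.0, datum::inf);
  double tot = accu(ev);
  if (tot <= 0) Rcpp::stop("zero total variance inside the mask");
  int keep = std::min((int)idx.n_elem, (int)ev.n_elem);
  Pca out;
  out.values = ev.head(keep) / tot;
  int kv = std::min(keep, max_vec);
  out.vectors = V.head_cols(kv);
  for (int k = 0; k < kv; ++k) {
    vec c = out.vectors.col(k);
    double mx = abs(c).max();
    for (unsigned int i = 0; i < c.n_elem; ++i) {
      if (std::abs(c(i)) > 1e-8 * mx) {
        if (c(i) < 0) out.vectors.col(k) *= -1.0;
        break;
      }
    }
  }
  return out;
}

static int select_k_cpp(const vec& values, double cap, double gap,
                        bool relative, int max_k) {
  int K = values.n_elem;
  double cum = 0.0;
  for (int k = 0; k < K; ++k) {
    cum += values(k);
    if (cum >= cap - 1e-12) return std::min(k + 1, max_k);
    if (k + 1 < K) {
      double d = values(k) - values(k + 1);
      if (relative && values(k) > 0) d /= values(k);
      if (d < gap) return std::min(k + 1, max_k);
    }
  }
  return std::min(K, max_k);
}

// OLS residuals of the rows `idx` of M against [1 | X], means re-added
static void regress_idx(mat& M, const mat& X, const uvec& idx) {
  mat D(X.n_rows, X.n_cols + 1);
  D.col(0).ones();
  D.cols(1, X.n_cols) = X;
  mat Q, R;
  if (!qr_econ(Q, R, D) || std::abs(R(R.n_rows - 1, R.n_cols - 1)) < 1e-10) {
    Rcpp::stop("rank-deficient nuisance design");
  }
  mat Y = M.rows(idx);
  vec mu = mean(Y, 1);
  Y -= (Y * Q) * Q.t();
  Y.each_col() += mu;
  M.rows(idx) = Y;
}

static vec tsnr_idx(const mat& M, const uvec& idx) {
  mat Y = M.rows(idx);
  vec mu = mean(Y, 1);
  Y.each_col() -= mu;
  vec sd = sqrt(sum(square(Y), 1) / double(Y.n_cols - 1));
  vec out(idx.n_elem);
  for (unsigned int i = 0; i < idx.n_elem; ++i) {
    out(i) = sd(i) > 0 ? mu(i) / sd(i) : datum::nan;
  }
  return out;
}

static mat median_filter_trace(const mat& tr, int window) {
  int n = tr.n_rows, h = (window - 1) / 2;
  mat out(n, tr.n_cols);
  for (unsigned int c = 0; c < tr.n_cols; ++c) {
    for (int i = 0; i < n; ++i) {
      vec w(window);
      for (int j = 0; j < window; ++j) {
        int p = i - h + j;
        if (p < 0) p = 0;
        if (p >= n) p = n - 1;
        w(j) = tr(p, c);
      }
      out(i, c) = median(w);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_preprocess_slice(
    const arma::mat& M_in, int nx, int ny,
    const arma::uvec& notspine_idx, const arma::uvec& csf_idx,
    const arma::uvec& wm_reg_idx, const arma::uvec& cord_idx,
    const arma::uvec& gm_idx, const arma::uvec& spine_idx,
    const arma::mat& weights, const arma::mat& retro,
    const arma::mat& filter_op_t, double notspine_cap, double csf_cap,
    double gap, bool gap_relative, int max_components, bool do_motion,
    int max_shift, int n_refine, int median_window, bool use_csf,
    bool use_wm) {
  mat M = M_in;
  const int nt = M.n_cols;
  const uvec all_idx = regspace<uvec>(0, M.n_rows - 1);

  // step 3: not-spine PCA regression of every voxel in the slice
  Pca pns = pca_idx(M, notspine_idx, max_components);
  int k_ns = select_k_cpp(pns.values, notspine_cap, gap, gap_relative,
                          max_components);
  regress_idx(M, pns.vectors.head_cols(k_ns), all_idx);

  // steps 4-5: target selection, weighted estimation, median filter,
  // single re-application to the uncorrected series
  mat trace_raw, trace_filt;
  int target = 0;
  if (do_motion) {
    vec med = cpp_row_medians(M);
    vec err(nt);
    for (int t = 0; t < nt; ++t) err(t) = accu(square(M.col(t) - med));
    target = err.index_min();
    cube series(nx, ny, nt);
    for (int t = 0; t < nt; ++t) {
      std::memcpy(series.slice(t).memptr(), M.colptr(t),
                  (size_t)nx * ny * sizeof(double));
    }
    trace_raw = cpp_estimate_stack(series, series.slice(target), weights,
                                   max_shift, n_refine);
    trace_filt = median_filter_trace(trace_raw, median_window);
    M = cpp_shift_mat(M, nx, ny, -trace_filt.col(0), -trace_filt.col(1));
  }

  // step 6: RETROICOR
  if (retro.n_cols > 0) regress_idx(M, retro, all_idx);

  vec tsnr_pre = tsnr_idx(M, gm_idx);

  // step 11: CSF PCA regression of cord voxels
  int k_csf = 0;
  if (use_csf) {
    Pca pcsf = pca_idx(M, csf_idx, max_components);
    k_csf = select_k_cpp(pcsf.values, csf_cap, gap, gap_relative,
                         max_components);
    regress_idx(M, pcsf.vectors.head_cols(k_csf), cord_idx);
  }

  // step 12: white-matter first eigenvector regressed from gray+white
  double wm_frac = datum::nan;
  if (use_wm) {
    Pca pwm = pca_idx(M, wm_reg_idx, 1);
    wm_frac = pwm.values(0);
    regress_idx(M, pwm.vectors.head_cols(1), cord_idx);
  }

  vec tsnr_post = tsnr_idx(M, gm_idx);

  // step 13: zero-phase band-pass of spine voxels (demeaned)
  mat Y = M.rows(spine_idx);
  Y.each_col() -= mean(Y, 1);
  M.rows(spine_idx) = Y * filter_op_t;

  return Rcpp::List::create(
      Rcpp::Named("M") = M, Rcpp::Named("k_notspine") = k_ns,
      Rcpp::Named("k_csf") = k_csf, Rcpp::Named("wm_var_fraction") = wm_frac,
      Rcpp::Named("tsnr_pre") = tsnr_pre, Rcpp::Named("tsnr_post") = tsnr_post,
      Rcpp::Named("trace_raw") = trace_raw,
      Rcpp::Named("trace_filtered") = trace_filt,
      Rcpp::Named("target") = target + 1);
}
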