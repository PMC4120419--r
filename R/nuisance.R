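# Data-driven "regressors of no interest" and their removal: principal
# components of not-spine and CSF voxels (selected by cumulative-variance
# and eigenvalue-gap rules), RETROICOR cardiac/respiratory Fourier
# regressors, the global white-matter eigenvector, and ordinary
# least-squares removal with an intercept.

#' Principal components of a masked voxel set
#'
#' Eigen-decomposition of the temporal covariance of all voxels inside a
#' mask: time-course eigenvectors (unit norm, sign fixed so the first
#' non-negligible element is positive) and eigenvalues normalised to the
#' total variance (they sum to 1). Voxel series are demeaned, not variance
#' normalised.
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @param mask logical matrix selecting voxels.
#' @return list with `values` (normalised eigenvalues, descending),
#'   `vectors` (matrix `[n_volumes, k]`), `total_var` (a.u.).
#' @export
pca_components <- function(series, mask) {
  dm <- dim(series)
  if (sum(mask) < 2L) stopf("PCA mask must contain at least 2 voxels")
  .pca_mat(matrix(series, dm[1] * dm[2], dm[3]), which(mask))
}

# matrix-centric core: M is voxels x time, idx the voxel rows to use.
# Works on the nt x nt temporal covariance, so cost scales with the small
# time dimension.
.pca_mat <- function(M, idx) {
  Y <- M[idx, , drop = FALSE]
  Y <- Y - rowMeans(Y)
  total <- sum(Y * Y)
  if (total <= 0) stopf("zero total variance inside the mask")
  C <- crossprod(Y) # nt x nt temporal covariance (summed over voxels)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- seq_len(min(length(idx), ncol(C)))
  lam <- lam[keep] / sum(lam)
  U <- eg$vectors[, keep, drop = FALSE]
  for (k in seq_len(ncol(U))) {
    nz <- which(abs(U[, k]) > 1e-8 * max(abs(U[, k])))[1]
    if (!is.na(nz) && U[nz, k] < 0) U[, k] <- -U[, k]
  }
  list(values = lam, vectors = U, total_var = total)
}

#' Eigenvalue selection rule
#'
#' @param cap cumulative-variance cap (fraction of total variance).
#' @param gap successive-eigenvalue difference threshold (fraction of total
#'   variance).
#' @param gap_rule `"absolute"` compares the difference of normalised
#'   eigenvalues against `gap`; `"relative"` compares the difference as a
#'   fraction of the preceding eigenvalue.
#' @param max_k hard cap on the number of components.
#' @return an `eig_selection_rule` object.
#' @export
eig_selection_rule <- function(cap = 0.80, gap = 0.02,
                               gap_rule = c("absolute", "relative"),
                               max_k = 10L) {
  if (cap <= 0 || cap > 1) stopf("cap must lie in (0, 1]")
  if (gap <= 0 || gap >= 1) stopf("gap threshold must lie in (0, 1)")
  structure(list(cap = cap, gap = gap, gap_rule = match.arg(gap_rule),
                 max_k = as.integer(max_k)), class = "eig_selection_rule")
}

#' Select the number of principal components to keep
#'
#' The smallest k such that the cumulative normalised variance reaches the
#' cap, or such that the drop from eigenvalue k to k+1 falls below the gap
#' threshold; always at least 1 and never more than `max_k`.
#'
#' @param values normalised eigenvalues, sorted descending.
#' @param rule an [eig_selection_rule()].
#' @return integer k.
#' @export
select_k <- function(values, rule) {
  if (!length(values)) stopf("empty eigenvalue spectrum")
  K <- length(values)
  cum <- cumsum(values)
  for (k in seq_len(K)) {
    if (cum[k] >= rule$cap - 1e-12) return(min(k, rule$max_k))
    if (k < K) {
      d <- values[k] - values[k + 1]
      if (rule$gap_rule == "relative" && values[k] > 0) d <- d / values[k]
      if (d < rule$gap) return(min(k, rule$max_k))
    }
  }
  min(K, rule$max_k)
}

# -- RETROICOR ---------------------------------------------------------------

# indices of local maxima above a fraction of the trace's dynamic range,
# separated by at least min_dist samples
find_peaks <- function(x, min_dist = 1L, min_height = NULL) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!is.null(min_height)) cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(cand)
  keep <- integer(0)
  last <- -Inf
  for (i in cand[order(-x[cand])]) keep <- c(keep, i) # greedy by height
  keep <- sort(keep)
  out <- integer(0)
  for (i in keep) {
    if (!length(out) || i - out[length(out)] >= min_dist) {
      out <- c(out, i)
    } else if (x[i] > x[out[length(out)]]) {
      out[length(out)] <- i
    }
  }
  out
}

# cardiac phase at times t from detected peak times: 2*pi * elapsed fraction
# of the current beat; extrapolated with the mean beat interval outside the
# detected range
cardiac_phase <- function(t, peak_times) {
  if (length(peak_times) < 2L) stopf("need at least 2 cardiac peaks")
  ibi <- mean(diff(peak_times))
  lo <- peak_times[1]
  hi <- peak_times[length(peak_times)]
  ext <- c(seq(lo - ibi * ceiling(max(0, (lo - min(t))) / ibi + 1), lo - ibi, by = ibi),
           peak_times,
           seq(hi + ibi, hi + ibi * ceiling(max(0, (max(t) - hi)) / ibi + 1), by = ibi))
  idx <- findInterval(t, ext)
  idx[idx < 1L] <- 1L
  idx[idx >= length(ext)] <- length(ext) - 1L
  prev <- ext[idx]
  nxt <- ext[idx + 1L]
  2 * pi * (t - prev) / (nxt - prev)
}

# respiratory phase by amplitude-histogram equalisation with the sign of
# the derivative (Glover-style): phase in (-pi, pi], inspiration positive
resp_phase <- function(t, time, trace, n_bins = 100L) {
  r <- stats::approx(time, trace, xout = t, rule = 2)$y
  drdt <- stats::approx(time[-1] - diff(time) / 2, diff(trace) / diff(time),
                        xout = t, rule = 2)$y
  br <- seq(min(trace), max(trace), length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(r, br, all.inside = TRUE), 1L), n_bins),
                nbins = n_bins)
  htab <- tabulate(pmin(pmax(findInterval(trace, br, all.inside = TRUE), 1L), n_bins),
                   nbins = n_bins)
  cdf <- cumsum(htab) / sum(htab)
  bin <- pmin(pmax(findInterval(r, br, all.inside = TRUE), 1L), n_bins)
  pi * cdf[bin] * sign(ifelse(drdt == 0, 1, drdt))
}

#' RETROICOR cardiac and respiratory phase regressors
#'
#' Low-order Fourier expansions of the cardiac and respiratory phases
#' evaluated at one slice's acquisition times. Cardiac phase advances
#' linearly between successive detected pulse peaks; respiratory phase uses
#' amplitude-histogram equalisation signed by the derivative of the
#' respiratory trace.
#'
#' @param physio a [physio_record()] with acquisition times.
#' @param slice slice index (selects the acquisition-time row).
#' @param order Fourier expansion order (2 gives 8 columns).
#' @return matrix `[n_volumes, 4 * order]` with labelled columns
#'   (`retroicor-c1cos`, ..., `retroicor-r2sin`).
#' @export
retroicor_regressors <- function(physio, slice, order = 2L) {
  if (is.null(physio$acq_times)) stopf("physio record lacks acquisition times")
  t <- physio$acq_times[slice, ]
  min_dist <- max(1L, floor(0.25 * physio$rate))
  thr <- min(physio$cardiac) + 0.5 * diff(range(physio$cardiac))
  pk <- find_peaks(physio$cardiac, min_dist = min_dist, min_height = thr)
  if (length(pk) < 2L) stopf("fewer than 2 cardiac peaks detected")
  phi_c <- cardiac_phase(t, physio$time[pk])
  phi_r <- resp_phase(t, physio$time, physio$resp)
  cols <- list()
  labs <- character(0)
  for (m in seq_len(order)) {
    cols <- c(cols, list(cos(m * phi_c), sin(m * phi_c)))
    labs <- c(labs, sprintf("retroicor-c%dcos", m), sprintf("retroicor-c%dsin", m))
  }
  for (m in seq_len(order)) {
    cols <- c(cols, list(cos(m * phi_r), sin(m * phi_r)))
    labs <- c(labs, sprintf("retroicor-r%dcos", m), sprintf("retroicor-r%dsin", m))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labs
  X
}

#' Global white-matter eigenvector
#'
#' First time-course eigenvector of the voxels in the designated mask:
#' plain white matter, a combined white+gray mask, or a slightly eroded
#' white-matter mask (with the standard radius fallback).
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @param masks a [tissue_masks()] object.
#' @param slice slice index.
#' @param variant `"wm"`, `"wm+gm"` or `"wm-eroded"`.
#' @param erode_radius radius for the eroded variant.
#' @return list with `vector` (length n_volumes), `var_fraction`
#'   (explained-variance fraction) and `label`.
#' @export
wm_eigenvector <- function(series, masks, slice,
                           variant = c("wm", "wm+gm", "wm-eroded"),
                           erode_radius = 1) {
  variant <- match.arg(variant)
  m <- switch(variant,
    "wm" = mask_slice(masks, slice, "wm"),
    "wm+gm" = mask_slice(masks, slice, "cord"),
    "wm-eroded" = erode_subregion(mask_slice(masks, slice, "wm"), erode_radius)$mask
  )
  if (!any(m)) stopf("empty mask for white-matter eigenvector (slice %d)", slice)
  p <- pca_components(series, m)
  list(vector = p$vectors[, 1], var_fraction = p$values[1], label = "wm-eig1")
}

#' Assemble a nuisance regressor set
#'
#' A per-slice design matrix with an intercept and uniquely labelled
#' nuisance columns.
#'
#' @param n_volumes number of time points.
#' @return a `regressor_set` with only the intercept.
#' @export
regressor_set <- function(n_volumes) {
  X <- matrix(1, n_volumes, 1)
  colnames(X) <- "intercept"
  structure(list(X = X), class = "regressor_set")
}

#' Add columns to a regressor set
#'
#' @param rs a `regressor_set`.
#' @param cols numeric matrix or vector of nuisance series.
#' @param labels unique column labels.
#' @return the extended `regressor_set`.
#' @export
rs_add <- function(rs, cols, labels) {
  cols <- as.matrix(cols)
  if (nrow(cols) != nrow(rs$X)) stopf("regressor length mismatch")
  if (length(labels) != ncol(cols)) stopf("one label per column required")
  if (any(labels %in% colnames(rs$X))) stopf("duplicate regressor labels")
  if (any(!is.finite(cols))) stopf("regressor columns must be finite")
  colnames(cols) <- labels
  rs$X <- cbind(rs$X, cols)
  rs
}

#' Regress nuisance series out of voxel time courses
#'
#' Ordinary-least-squares residuals of every voxel inside the scope mask
#' against the regressor set (intercept included), with the voxel mean
#' re-added. Residuals are exactly orthogonal to every regressor column.
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @param regressors a `regressor_set` or plain numeric matrix
#'   `[n_volumes, k]` (an intercept is appended if absent).
#' @param scope logical matrix of voxels to clean (default: all).
#' @return the cleaned 3-D array.
#' @export
regress_out <- function(series, regressors, scope = NULL) {
  dm <- dim(series)
  X <- if (inherits(regressors, "regressor_set")) regressors$X else {
    X0 <- as.matrix(regressors)
    if (is.null(colnames(X0))) colnames(X0) <- paste0("reg", seq_len(ncol(X0)))
    if (!any(apply(X0, 2, function(c) all(c == c[1]) && c[1] != 0))) {
      X0 <- cbind(intercept = 1, X0)
    }
    X0
  }
  if (is.null(scope)) scope <- matrix(TRUE, dm[1], dm[2])
  idx <- which(scope)
  if (!length(idx)) return(series)
  M <- matrix(series, dm[1] * dm[2], dm[3])
  M <- .regress_mat(M, X, idx)
  out <- array(M, dm)
  attr(out, "tr") <- attr(series, "tr")
  attr(out, "voxel_mm") <- attr(series, "voxel_mm")
  out
}

# matrix-centric OLS residualisation: M is voxels x time, X the design
# (columns must be labelled), idx the voxel rows in scope.
.regress_mat <- function(M, X, idx) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient nuisance design; collinear columns: %s",
          paste(drop, collapse = ", "))
  }
  Q <- qr.Q(qrX)
  Y <- M[idx, , drop = FALSE]
  mu <- rowMeans(Y)
  M[idx, ] <- Y - (Y %*% Q) %*% t(Q) + mu
  M
}
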