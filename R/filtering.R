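# Zero-phase Chebyshev Type II band-pass filtering, temporal
# signal-to-noise ratio maps, and ROI power spectra with band-power
# summaries.

#' Band-pass filter specification
#'
#' Chebyshev Type II design with the passband stated in Hz; the stopband
#' edges sit at half the low edge and 1.25 times the high edge. Applied
#' forward-backward (zero phase) with odd-reflection padding.
#'
#' @param band passband edges in Hz (default 0.01-0.08).
#' @param tr sampling interval in seconds (volume acquisition time).
#' @param order analogue prototype order (the band-pass IIR has twice as
#'   many poles).
#' @param atten_db stopband attenuation in dB.
#' @return a `filter_spec` object (includes the designed coefficients).
#' @export
filter_spec <- function(band = c(0.01, 0.08), tr = 3.6, order = 5L,
                        atten_db = 30) {
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stopf("band edges must satisfy 0 < low < high")
  }
  if (band[2] >= nyq) {
    stopf("band [%g, %g] Hz infeasible: Nyquist is %.4f Hz at TR %.3g s",
          band[1], band[2], nyq, tr)
  }
  if (atten_db <= 0) stopf("stopband attenuation must be positive")
  stop_lo <- 0.5 * band[1]
  stop_hi <- min(1.25 * band[2], 0.999 * nyq)
  w <- c(stop_lo, stop_hi) / nyq
  ba <- signal::cheby2(order, atten_db, w, type = "pass")
  structure(list(band = band, tr = tr, order = as.integer(order),
                 atten_db = atten_db, stopband = c(stop_lo, stop_hi),
                 b = ba$b, a = ba$a), class = "filter_spec")
}

# forward-backward filtering with odd-reflection padding; input may be a
# vector or a time-by-series matrix
zerophase_filter <- function(x, spec) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(X)
  nf <- max(length(spec$b), length(spec$a))
  if (n <= 3L * spec$order) stopf("series too short for the filter order")
  p <- min(n - 1L, 10L * nf)
  one_pass <- function(M) {
    apply(M, 2L, function(col) {
      as.numeric(signal::filter(spec$b, spec$a, col))
    })
  }
  pad <- rbind(
    2 * matrix(X[1L, ], p, ncol(X), byrow = TRUE) - X[(p + 1L):2L, , drop = FALSE],
    X,
    2 * matrix(X[n, ], p, ncol(X), byrow = TRUE) - X[(n - 1L):(n - p), , drop = FALSE]
  )
  y <- one_pass(pad)
  y <- one_pass(y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(p + 1L):(p + n), , drop = FALSE]
  if (vec) as.numeric(y) else y
}

# the zero-phase filter is linear: build its n x n operator once (applied
# to demeaned series) so whole-slice filtering is one matrix product
filter_operator <- function(spec, n) {
  key <- sprintf("%g_%g_%g_%d_%g_%d", spec$band[1], spec$band[2], spec$tr,
                 spec$order, spec$atten_db, n)
  cached <- filter_op_cache[[key]]
  if (!is.null(cached)) return(cached)
  Fop <- zerophase_filter(diag(n), spec)
  filter_op_cache[[key]] <- Fop
  Fop
}
filter_op_cache <- new.env(parent = emptyenv())

#' Effective degrees of freedom admitted by a band-pass filter
#'
#' After zero-phase filtering, a white-noise series has covariance
#' `C = F F'` (with `F` the filter operator on demeaned series); the
#' effective sample size of a correlation between two such series is
#' `trace(C)^2 / trace(C^2)`. No filtered series can exceed this, so it
#' caps the data-driven effective-dof estimate, which is biased upward on
#' short band-limited series by spectral leakage.
#'
#' @param spec a [filter_spec()].
#' @param n series length.
#' @return effective degrees of freedom admitted by the filter.
#' @export
filter_dof <- function(spec, n) {
  key <- sprintf("dof_%g_%g_%g_%d_%g_%d", spec$band[1], spec$band[2],
                 spec$tr, spec$order, spec$atten_db, n)
  cached <- filter_op_cache[[key]]
  if (!is.null(cached)) return(cached)
  Fop <- filter_operator(spec, n)
  Fc <- Fop - matrix(colMeans(Fop), n, n, byrow = TRUE) # centred input
  C <- tcrossprod(Fc)
  out <- sum(diag(C))^2 / sum(C * C)
  filter_op_cache[[key]] <- out
  out
}

#' Zero-phase band-pass filter
#'
#' Removes the temporal mean, then applies the Chebyshev Type II filter
#' forward and backward (no group delay). Accepts a vector, a
#' time-by-series matrix, or a 3-D/4-D voxel array (time last), optionally
#' restricted to a mask.
#'
#' @param x series to filter (time along the first dimension for matrices,
#'   last for arrays).
#' @param spec a [filter_spec()].
#' @param mask optional logical mask (in-plane, or `[nx, ny, n_slices]` for
#'   4-D input) of voxels to filter; unmasked voxels pass through
#'   unchanged.
#' @return filtered object of the same shape.
#' @export
bandpass <- function(x, spec, mask = NULL) {
  if (is.null(dim(x))) {
    return(as.numeric(zerophase_filter(x - mean(x), spec)))
  }
  dm <- dim(x)
  if (length(dm) == 2L) {
    return(zerophase_filter(sweep(x, 2L, colMeans(x)), spec))
  }
  nt <- dm[length(dm)]
  Fop <- filter_operator(spec, nt)
  nvox <- prod(dm[-length(dm)])
  M <- matrix(x, nvox, nt)
  idx <- if (is.null(mask)) seq_len(nvox) else which(mask)
  Y <- t(M[idx, , drop = FALSE])
  Y <- sweep(Y, 2L, colMeans(Y))
  M[idx, ] <- t(Fop %*% Y)
  out <- array(M, dm)
  out
}

# per-voxel TSNR over selected rows of a voxels x time matrix
.tsnr_vec <- function(M, idx) {
  Y <- M[idx, , drop = FALSE]
  mu <- rowMeans(Y)
  s <- sqrt(rowSums((Y - mu)^2) / (ncol(Y) - 1))
  ifelse(s > 0, mu / s, NA_real_)
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean divided by temporal standard deviation inside a
#' mask; voxels with zero temporal variance are excluded from the median.
#'
#' @param series 3-D array `[nx, ny, n_volumes]`.
#' @param mask logical matrix of voxels to evaluate.
#' @return list with `map` (matrix, NA outside the mask and at
#'   zero-variance voxels) and `median`.
#' @export
tsnr_map <- function(series, mask) {
  dm <- dim(series)
  if (dm[3] < 2L) stopf("TSNR needs at least 2 volumes")
  if (!any(mask)) stopf("empty TSNR mask")
  M <- matrix(series, dm[1] * dm[2], dm[3])[which(mask), , drop = FALSE]
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (dm[3] - 1))
  t <- ifelse(s > 0, mu / s, NA_real_)
  map <- matrix(NA_real_, dm[1], dm[2])
  map[which(mask)] <- t
  list(map = map, median = median(t[is.finite(t)]))
}

#' One-sided periodogram
#'
#' Rectangular-window (no taper) periodogram of a demeaned series, scaled
#' so the powers sum exactly to the series' population variance
#' (`sum((x - mean(x))^2) / n`).
#'
#' @param x numeric vector.
#' @param tr sampling interval (s).
#' @return list with `freq` (Hz, from 0 to Nyquist) and `power`.
#' @export
periodogram <- function(x, tr) {
  n <- length(x)
  x <- x - mean(x)
  X <- fft(x)
  half <- floor(n / 2)
  p <- Mod(X[seq_len(half + 1L)])^2 / n^2
  if (n %% 2 == 0) {
    if (half >= 2) p[2:half] <- 2 * p[2:half]
  } else {
    if (half >= 1) p[2:(half + 1L)] <- 2 * p[2:(half + 1L)]
  }
  list(freq = (0:half) / (n * tr), power = p)
}

#' ROI power-spectrum summary
#'
#' Periodograms of ROI-mean series grouped into classes (e.g. gray vs white
#' matter), reduced to the median power across series (slices and subjects)
#' at each frequency, plus total in-band power per class and pairwise
#' band-power ratios.
#'
#' @param series_by_class named list; each element a matrix
#'   `[n_volumes, n_series]` of equal-length ROI mean series.
#' @param tr sampling interval (s).
#' @param band frequency band (Hz) over which band power is summed.
#' @return a `power_spectrum_summary`: `freq`, `median_power` (matrix
#'   frequency x class), `band_power` (named vector), `ratio` (matrix of
#'   class-pair ratios).
#' @export
roi_power_spectrum <- function(series_by_class, tr, band = c(0.01, 0.08)) {
  lens <- unique(vapply(series_by_class, nrow, integer(1)))
  if (length(lens) != 1L) stopf("all series must have equal length")
  n <- lens
  freq <- periodogram(numeric(n) + seq_len(n), tr)$freq
  med <- sapply(series_by_class, function(M) {
    P <- apply(M, 2L, function(col) periodogram(col, tr)$power)
    apply(P, 1L, median)
  })
  in_band <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  bp <- colSums(med[in_band, , drop = FALSE])
  ratio <- outer(bp, bp, "/")
  structure(list(freq = freq, median_power = med, band_power = bp,
                 ratio = ratio, band = band),
            class = "power_spectrum_summary")
}
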