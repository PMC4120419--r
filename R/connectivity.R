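# Voxel- and ROI-level correlation analysis: Pearson correlation, Fisher
# r-to-z with autocorrelation-corrected effective degrees of freedom,
# seed-based z maps with cluster-extent thresholds, and per-slice 8x8
# sub-region connectivity matrices.

R_CLAMP <- 1 - 1e-7 # |r| ceiling before atanh, keeps z finite

#' Pearson correlation of two series
#'
#' @param a,b numeric vectors of equal length (at least 4), neither
#'   constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 4L) {
    stopf("series must have equal length >= 4")
  }
  if (sd(a) == 0 || sd(b) == 0) stopf("correlation undefined for constant series")
  cor(a, b)
}

#' Effective degrees of freedom under temporal autocorrelation
#'
#' Discounts the sample size so the Fisher z of the correlation between
#' two autocorrelated series is approximately standard normal under the
#' null.
#'
#' The default `"bartlett-sum"` method uses the Bartlett variance formula
#' over all estimable lags,
#' `dof = N / (1 + 2 * sum_k w_k * ra(k) * rb(k))`,
#' with sample autocorrelations up to lag `N/3` under a triangular taper
#' `w_k = 1 - k/(K+1)`; this calibrates band-limited (e.g. band-passed)
#' series, whose autocorrelation extends far beyond lag 1. The
#' `"bartlett-lag1"` method is the classical first-order form
#' `dof = N * (1 - r1a*r1b) / (1 + r1a*r1b)`, exact for AR(1) processes.
#' The two agree for AR(1) noise; both are clamped to `[4, N]`.
#'
#' @param a,b numeric vectors (length at least 8).
#' @param method `"bartlett-sum"` (default) or `"bartlett-lag1"`.
#' @return effective degrees of freedom.
#' @export
effective_dof <- function(a, b, method = c("bartlett-sum", "bartlett-lag1")) {
  n <- length(a)
  if (n < 8L) stopf("need at least 8 time points")
  method <- match.arg(method)
  if (method == "bartlett-lag1") {
    r1 <- lag1_autocor(a) * lag1_autocor(b)
    dof <- n * (1 - r1) / (1 + r1)
  } else {
    K <- max(1L, floor(n / 3))
    w <- 1 - seq_len(K) / (K + 1)
    denom <- max(1, 1 + 2 * sum(w * autocor_lags(a, K) * autocor_lags(b, K)))
    dof <- n / denom
  }
  min(max(dof, 4), n)
}

# sample autocorrelations at lags 1..K (denominator-n convention)
autocor_lags <- function(x, K) {
  x <- x - mean(x)
  den <- sum(x * x)
  if (den <= 0) return(numeric(K))
  n <- length(x)
  vapply(seq_len(K), function(k) {
    sum(x[seq_len(n - k)] * x[(k + 1):n]) / den
  }, numeric(1))
}

#' Fisher r-to-z score
#'
#' `z = atanh(r) * sqrt(dof - 3)`, approximately standard normal under the
#' null when `dof` reflects the effective sample size. `|r|` is clamped at
#' `1 - 1e-7` so degenerate (identical) series give a large finite score.
#'
#' @param r correlation in \[-1, 1\].
#' @param dof effective degrees of freedom (>= 4).
#' @return z score.
#' @export
fisher_z <- function(r, dof) {
  if (any(abs(r) > 1 + 1e-12)) stopf("|r| must not exceed 1")
  if (any(dof < 4)) stopf("dof must be at least 4")
  r <- pmin(pmax(r, -R_CLAMP), R_CLAMP)
  atanh(r) * sqrt(dof - 3)
}

#' Full correlation-to-z chain for a pair of series
#'
#' @param a,b numeric vectors.
#' @param nuisance_p number of nuisance regressors (including the
#'   intercept) already projected out of the series. Regression spends
#'   degrees of freedom as in an ordinary GLM; the effective dof is
#'   scaled by `(1 - nuisance_p / N)`, the fraction of dimensions the
#'   design leaves free.
#' @param max_dof independent upper bound on the effective degrees of
#'   freedom, e.g. [filter_dof()] for band-passed series (the data-driven
#'   estimate is leakage-biased upward and cannot exceed what the filter
#'   admits).
#' @return list with `r`, `r1a`, `r1b`, `dof`, `z`.
#' @export
correlation_stats <- function(a, b, nuisance_p = 0, max_dof = Inf) {
  r <- pearson_r(a, b)
  dof <- max(min(effective_dof(a, b) * (1 - nuisance_p / length(a)),
                 max_dof), 4)
  list(r = r, r1a = lag1_autocor(a), r1b = lag1_autocor(b), dof = dof,
       z = fisher_z(r, dof))
}

#' Label connected components of a binary map
#'
#' Breadth-first connected-component labelling of a 3-D logical array.
#' Contiguity is face-only 6-connectivity by default, or in-plane
#' 8-connectivity (no between-slice links).
#'
#' @param mask logical 3-D array (a matrix is treated as one slice).
#' @param connectivity `"face3d"` or `"inplane8"`.
#' @return integer array of component labels (0 = background), with the
#'   number of components as attribute `n`.
#' @export
label_clusters <- function(mask, connectivity = c("face3d", "inplane8")) {
  connectivity <- match.arg(connectivity)
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  dm <- dim(mask)
  offs <- if (connectivity == "face3d") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(i = -1:1, j = -1:1, k = 0))[-5, ] # drop (0,0,0)
  }
  labels <- array(0L, dm)
  nlab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    labels[start] <- nlab
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k0 <- (v - 1L) %/% (dm[1] * dm[2])
      rem <- (v - 1L) %% (dm[1] * dm[2])
      j0 <- rem %/% dm[1]
      i0 <- rem %% dm[1]
      for (o in seq_len(nrow(offs))) {
        i <- i0 + offs[o, 1]
        j <- j0 + offs[o, 2]
        k <- k0 + offs[o, 3]
        if (i < 0 || i >= dm[1] || j < 0 || j >= dm[2] || k < 0 || k >= dm[3]) next
        w <- 1L + i + dm[1] * (j + dm[2] * k)
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- nlab
          queue <- c(queue, w)
        }
      }
    }
  }
  attr(labels, "n") <- nlab
  labels
}

#' Seed-based correlation z map
#'
#' Correlates a seed voxel's time course with every voxel inside the cord
#' mask (across all slices), converts to z via the autocorrelation-corrected
#' Fisher transform, thresholds, and removes suprathreshold components
#' smaller than the minimum cluster extent.
#'
#' @param series 4-D array `[nx, ny, n_slices, n_volumes]`.
#' @param seed integer `c(x, y, slice)` of the seed voxel (must lie inside
#'   the cord mask).
#' @param masks a [tissue_masks()] object (the cord = GM + WM defines the
#'   analysis domain).
#' @param threshold z threshold (default 3.29, the two-tailed 99.9%
#'   confidence bound).
#' @param tails 2 keeps `|z| >` threshold, 1 keeps `z >` threshold only.
#' @param min_cluster minimum number of contiguous suprathreshold voxels.
#' @param connectivity contiguity rule, see [label_clusters()].
#' @return a `seed_map`: `z` (array, NA outside the cord), `surviving`
#'   (logical array), `clusters` (label array), plus the thresholds used.
#' @export
seed_correlation_map <- function(series, seed, masks, threshold = 3.29,
                                 tails = 2, min_cluster = 9,
                                 connectivity = "face3d", nuisance_p = 0,
                                 max_dof = Inf) {
  dm <- dim(series)
  cord <- masks$labels == 1L | masks$labels == 2L
  if (!cord[seed[1], seed[2], seed[3]]) stopf("seed voxel lies outside the cord mask")
  s_ts <- series[seed[1], seed[2], seed[3], ]
  zarr <- array(NA_real_, dm[1:3])
  for (sl in seq_len(dm[3])) {
    idx <- which(cord[, , sl])
    if (!length(idx)) next
    M <- matrix(series[, , sl, ], dm[1] * dm[2], dm[4])[idx, , drop = FALSE]
    Y <- t(M)
    Yc <- sweep(Y, 2L, colMeans(Y))
    sc <- s_ts - mean(s_ts)
    denom <- sqrt(colSums(Yc^2) * sum(sc^2))
    r <- as.numeric(crossprod(Yc, sc)) / pmax(denom, 1e-300)
    # tapered all-lag Bartlett effective dof, vectorised over voxels
    n <- dm[4]
    K <- max(1L, floor(n / 3))
    rs <- autocor_lags(sc, K)
    den_v <- pmax(colSums(Yc^2), 1e-300)
    acc <- numeric(ncol(Yc))
    for (k in seq_len(K)) {
      rv_k <- colSums(Yc[seq_len(n - k), , drop = FALSE] *
                        Yc[(k + 1):n, , drop = FALSE]) / den_v
      acc <- acc + (1 - k / (K + 1)) * rs[k] * rv_k
    }
    dof <- pmin(pmax(pmin(n / pmax(1, 1 + 2 * acc) * (1 - nuisance_p / n),
                          max_dof), 4), n)
    z <- atanh(pmin(pmax(r, -R_CLAMP), R_CLAMP)) * sqrt(dof - 3)
    plane <- matrix(NA_real_, dm[1], dm[2])
    plane[idx] <- z
    zarr[, , sl] <- plane
  }
  supra <- if (tails == 2) abs(zarr) > threshold else zarr > threshold
  supra[is.na(supra)] <- FALSE
  labels <- label_clusters(supra, connectivity)
  surviving <- supra
  if (min_cluster > 0 && attr(labels, "n") > 0) {
    sizes <- tabulate(labels[labels > 0L], nbins = attr(labels, "n"))
    small <- which(sizes < min_cluster)
    if (length(small)) surviving[labels %in% small] <- FALSE
  }
  structure(list(z = zarr, surviving = surviving, clusters = labels,
                 seed = seed, threshold = threshold, tails = tails,
                 min_cluster = min_cluster),
            class = "seed_map")
}

#' Per-slice 8x8 sub-region connectivity matrix
#'
#' Averages voxel time courses within each eroded sub-region mask and
#' computes the autocorrelation-corrected Fisher z between every pair of
#' ROI means. The matrix is symmetric with zeros on the (unused) diagonal;
#' rows/columns follow [subregion_names()].
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @param sub a `subregion_masks` object for that slice.
#' @param nuisance_p number of nuisance regressors (including the
#'   intercept) already regressed out of the series; subtracted from the
#'   effective degrees of freedom.
#' @return a list of class `slice_connectivity`: `z` (8x8 matrix), `r`
#'   (8x8), `means` (matrix `[n_volumes, 8]`), `slice`.
#' @export
roi_connectivity <- function(series, sub, nuisance_p = 0, max_dof = Inf) {
  dm <- dim(series)
  .roi_connectivity_mat(matrix(series, dm[1] * dm[2], dm[3]), sub,
                        nuisance_p, max_dof)
}

# matrix-layout core: M is voxels x time
.roi_connectivity_mat <- function(M, sub, nuisance_p = 0, max_dof = Inf) {
  nm <- subregion_names()
  means <- sapply(nm, function(k) {
    idx <- which(sub$masks[[k]])
    if (!length(idx)) stopf("empty sub-region '%s' on slice %s", k, sub$slice)
    colMeans(M[idx, , drop = FALSE])
  })
  z <- matrix(0, 8, 8, dimnames = list(nm, nm))
  r <- matrix(0, 8, 8, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in 1:7) {
    for (j in (i + 1):8) {
      st <- correlation_stats(means[, i], means[, j], nuisance_p, max_dof)
      z[i, j] <- z[j, i] <- st$z
      r[i, j] <- r[j, i] <- st$r
    }
  }
  structure(list(z = z, r = r, means = means, slice = sub$slice),
            class = "slice_connectivity")
}
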