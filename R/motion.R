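# Slice-wise in-plane motion correction: automatic target-volume selection,
# weighted-SSD translation estimation (integer FFT search plus sub-voxel
# refinement), 5-point median filtering of the motion trace, and a single
# final band-limited resampling of the raw data. An optional simplified
# slice-wise affine stage (translation + bounded scale/shear, Hellinger
# cost) is provided but disabled by default.

#' Select the motion-correction target volume for a slice
#'
#' Computes the voxel-wise median image over time and returns the index of
#' the volume closest to it in the least-squares sense; ties go to the
#' lowest index.
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @return integer volume index.
#' @export
select_target_volume <- function(series) {
  dm <- dim(series)
  if (length(dm) != 3L || dm[3] < 3L) stopf("need a [nx, ny, >=3] slice series")
  m <- matrix(series, dm[1] * dm[2], dm[3])
  med <- cpp_row_medians(m)
  err <- colSums((m - as.vector(med))^2)
  which.min(err) # which.min takes the first (lowest-index) minimum on ties
}

#' Estimate the in-plane translation of an image relative to a target
#'
#' Returns the displacement `(dx, dy)` (voxels) of the moving image's
#' content relative to the target, i.e. the shift minimising the
#' weight-multiplied sum of squared differences between the shifted-back
#' moving image and the target. Exhaustive integer search (via FFT
#' cross-correlation) is refined by coordinate-wise parabolic sub-voxel
#' optimisation of the continuous, band-limited-interpolated objective.
#'
#' @param moving,target numeric matrices of identical shape.
#' @param weights a [make_weight_kernel()] object or a numeric weight
#'   matrix.
#' @param max_shift integer search radius (voxels).
#' @param n_refine number of sub-voxel refinement sweeps (each halves the
#'   step, starting at 0.5 voxel).
#' @return numeric `c(dx, dy)`.
#' @export
estimate_translation <- function(moving, target, weights, max_shift = 8L,
                                 n_refine = 2L) {
  w <- if (inherits(weights, "weight_kernel")) weights$weights else weights
  if (!all(dim(moving) == dim(target)) || !all(dim(w) == dim(target))) {
    stopf("moving, target and weights must share one shape")
  }
  if (sd(as.vector(moving)) == 0 || sd(as.vector(target)) == 0) {
    stopf("cannot register a flat (zero-variance) image")
  }
  est <- cpp_estimate_stack(array(moving, c(dim(moving), 1L)), target, w,
                            as.integer(max_shift), as.integer(n_refine))
  c(dx = est[1, 1], dy = est[1, 2])
}

# estimate translations for every volume of one slice against its target
estimate_translation_stack <- function(series, target_index, weights,
                                       max_shift = 8L, n_refine = 2L) {
  w <- if (inherits(weights, "weight_kernel")) weights$weights else weights
  target <- series[, , target_index]
  est <- cpp_estimate_stack(series, target, w, as.integer(max_shift),
                            as.integer(n_refine))
  colnames(est) <- c("dx", "dy")
  est
}

#' Median-filter a motion trace
#'
#' Running median (default 5-point window) applied independently to each
#' translation component, suppressing single-volume spikes from sporadic
#' artifacts such as swallowing. Edges are handled by nearest-value
#' replication.
#'
#' @param trace numeric matrix `[n_volumes, 2]` (columns dx, dy) or vector.
#' @param window odd window length.
#' @return filtered trace of the same shape.
#' @export
filter_motion_trace <- function(trace, window = 5L) {
  if (window %% 2 == 0) stopf("median-filter window must be odd")
  filt1 <- function(x) {
    n <- length(x)
    if (n == 0L) return(x)
    h <- (window - 1L) %/% 2L
    padded <- c(rep(x[1], h), x, rep(x[n], h))
    vapply(seq_len(n), function(i) median(padded[i:(i + window - 1L)]),
           numeric(1))
  }
  if (is.matrix(trace)) apply(trace, 2L, filt1) else filt1(trace)
}

#' Apply a translation trace to a slice series
#'
#' Shifts each volume by the negated trace (undoing the estimated motion)
#' with band-limited (Fourier/sinc) interpolation; this is the single
#' resampling of the raw data in the two-pass correction scheme. Optionally
#' upsamples each corrected volume to a finer grid by an integer factor
#' (Fourier zero-padding), emulating resampling from native to interpolated
#' resolution.
#'
#' @param series 3-D array `[nx, ny, n_volumes]`.
#' @param trace matrix `[n_volumes, 2]` of estimated (dx, dy).
#' @param upsample integer upsampling factor (1 = none).
#' @return corrected (and possibly upsampled) 3-D array.
#' @export
apply_translation <- function(series, trace, upsample = 1L) {
  dm <- dim(series)
  if (nrow(trace) != dm[3]) stopf("trace length must match the number of volumes")
  out <- if (all(trace == 0)) series else {
    cpp_shift_stack(series, -trace[, 1], -trace[, 2])
  }
  if (upsample > 1L) {
    up <- array(0, dim = c(dm[1] * upsample, dm[2] * upsample, dm[3]))
    for (t in seq_len(dm[3])) up[, , t] <- fourier_upsample(out[, , t], upsample)
    out <- up
  }
  out
}

# 2-D Fourier zero-padding interpolation by an integer factor; exact for
# constants and band-limited content.
fourier_upsample <- function(img, factor) {
  nx <- nrow(img)
  ny <- ncol(img)
  f <- fft(img)
  nx2 <- nx * factor
  ny2 <- ny * factor
  g <- matrix(0 + 0i, nx2, ny2)
  hx <- floor(nx / 2)
  hy <- floor(ny / 2)
  ix_lo <- seq_len(hx + 1L)
  ix_hi <- if (hx >= 1) (nx - hx + 1L):nx else integer(0)
  iy_lo <- seq_len(hy + 1L)
  iy_hi <- if (hy >= 1) (ny - hy + 1L):ny else integer(0)
  g[ix_lo, iy_lo] <- f[ix_lo, iy_lo]
  g[ix_lo, ny2 - length(iy_hi) + seq_along(iy_hi)] <- f[ix_lo, iy_hi]
  g[nx2 - length(ix_hi) + seq_along(ix_hi), iy_lo] <- f[ix_hi, iy_lo]
  g[nx2 - length(ix_hi) + seq_along(ix_hi),
    ny2 - length(iy_hi) + seq_along(iy_hi)] <- f[ix_hi, iy_hi]
  Re(fft(g, inverse = TRUE)) * factor^2 / (nx2 * ny2)
}

#' Two-pass slice-wise motion correction
#'
#' The full correction scheme for one slice: select the target volume,
#' estimate per-volume translations with the cord-weighted SSD criterion,
#' median-filter the estimates, and re-apply the filtered trace to the
#' original (uncorrected) series with a single band-limited resampling.
#'
#' @param series 3-D array `[nx, ny, n_volumes]` for one slice.
#' @param weights weight kernel (see [make_weight_kernel()]).
#' @param window median-filter window.
#' @param max_shift integer search radius (voxels).
#' @return list with `corrected` (array), `trace_raw`, `trace_filtered`
#'   (matrices `[n_volumes, 2]`) and `target` (volume index).
#' @export
correct_motion_slice <- function(series, weights, window = 5L, max_shift = 8L) {
  target <- select_target_volume(series)
  raw <- estimate_translation_stack(series, target, weights,
                                    max_shift = max_shift)
  filt <- filter_motion_trace(raw, window = window)
  corrected <- apply_translation(series, filt)
  list(corrected = corrected, trace_raw = raw, trace_filtered = filt,
       target = target)
}

# matrix-layout variant used by the pipeline: M is voxels x time
.correct_motion_mat <- function(M, nx, ny, weights, window = 5L,
                                max_shift = 8L, n_refine = 2L) {
  w <- if (inherits(weights, "weight_kernel")) weights$weights else weights
  med <- cpp_row_medians(M)
  target <- which.min(colSums((M - as.vector(med))^2))
  raw <- cpp_estimate_mat(M, nx, ny, target, w, as.integer(max_shift),
                          as.integer(n_refine))
  colnames(raw) <- c("dx", "dy")
  filt <- filter_motion_trace(raw, window = window)
  corrected <- cpp_shift_mat(M, nx, ny, -filt[, 1], -filt[, 2])
  list(corrected = corrected, trace_raw = raw, trace_filtered = filt,
       target = target)
}

#' Simplified slice-wise affine registration (optional stage)
#'
#' Registers a functional target slice to an anatomical slice with an
#' in-plane affine constrained to translation, axis scaling (bounded) and
#' shear (bounded), minimising the Bhattacharyya overlap of the joint
#' intensity histogram with the product of its marginals (i.e. maximising
#' the Hellinger dependence between the images). Off by default in the
#' phantom pipeline, whose data are generated pre-aligned.
#'
#' @param moving,anatomical numeric matrices of identical shape.
#' @param weights weight kernel or matrix (voxels contributing to the
#'   histogram).
#' @param max_scale_x,max_scale_y maximum fractional scaling per axis
#'   (defaults 1% read, 5% phase-encode).
#' @param max_shear maximum shear fraction.
#' @param max_shift translation bound (voxels).
#' @param n_bins histogram bins per axis.
#' @return list with `params` (tx, ty, sx, sy, shear) and `cost`.
#' @export
register_affine_slice <- function(moving, anatomical, weights,
                                  max_scale_x = 0.01, max_scale_y = 0.05,
                                  max_shear = 0.05, max_shift = 5,
                                  n_bins = 32L) {
  w <- if (inherits(weights, "weight_kernel")) weights$weights else weights
  if (sd(as.vector(moving)) == 0 || sd(as.vector(anatomical)) == 0) {
    stopf("degenerate (flat) image: histogram cost undefined")
  }
  nx <- nrow(moving)
  ny <- ncol(moving)
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  # Both images are sampled with bilinear interpolation on a grid shifted
  # by an irrational sub-voxel offset, so no candidate transform is ever
  # grid-aligned: interpolation smoothing is then uniform across the
  # search space instead of dipping at integer alignments (the classic
  # joint-histogram artifact).
  delta <- 0.5 * (3 - sqrt(5))
  gx <- seq_len(nx - 1L) + delta
  gy <- seq_len(ny - 1L) + delta
  XG <- matrix(gx, length(gx), length(gy))
  YG <- matrix(gy, length(gx), length(gy), byrow = TRUE)
  wsamp <- bilinear_sample(w, XG, YG)
  sel <- which(wsamp > 0.05)
  a_samp <- bilinear_sample(anatomical, XG, YG)[sel]
  amin <- min(a_samp)
  amax <- max(a_samp)
  ba_sel <- pmin(pmax(1L, 1L + floor((a_samp - amin) / (amax - amin + 1e-12) * n_bins)), n_bins)
  mmin <- min(moving)
  mmax <- max(moving)
  xg <- XG - cx
  yg <- YG - cy
  cost <- function(par) {
    mx <- (1 + par[3]) * xg + par[5] * yg + par[1] + cx
    my <- (1 + par[4]) * yg + par[2] + cy
    vals <- bilinear_sample(moving, mx, my)[sel]
    bm <- pmin(pmax(1L, 1L + floor((vals - mmin) / (mmax - mmin + 1e-12) * n_bins)), n_bins)
    cell <- bm + (ba_sel - 1L) * n_bins
    h <- numeric(n_bins * n_bins)
    acc <- rowsum(rep(1, length(cell)), cell)
    h[as.integer(rownames(acc))] <- acc[, 1]
    pm <- matrix(h / sum(h), n_bins, n_bins)
    q <- outer(rowSums(pm), colSums(pm))
    sum(sqrt(pm * q)) # Bhattacharyya overlap; small when images are dependent
  }
  lower <- c(-max_shift, -max_shift, -max_scale_x, -max_scale_y, -max_shear)
  upper <- c(max_shift, max_shift, max_scale_x, max_scale_y, max_shear)
  wrap <- function(par) cost(pmin(pmax(par, lower), upper))
  fit <- optim(c(0, 0, 0, 0, 0), wrap, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  par <- pmin(pmax(fit$par, lower), upper)
  # the cost surface is nearly separable and very shallow for sub-percent
  # scale changes; a bounded line search per parameter sharpens the optimum
  best <- wrap(par)
  for (sweep in 1:3) {
    for (k in seq_along(par)) {
      o <- optimize(function(v) {
        p2 <- par
        p2[k] <- v
        wrap(p2)
      }, lower = lower[k], upper = upper[k], tol = 1e-5)
      if (o$objective < best) {
        par[k] <- o$minimum
        best <- o$objective
      }
    }
  }
  names(par) <- c("tx", "ty", "sx", "sy", "shear")
  list(params = par, cost = best)
}

# bilinear interpolation with edge clamping
bilinear_sample <- function(img, xs, ys) {
  nx <- nrow(img)
  ny <- ncol(img)
  xs <- pmin(pmax(xs, 1), nx)
  ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1)
  y0 <- pmin(floor(ys), ny - 1)
  fx <- xs - x0
  fy <- ys - y0
  x0v <- as.vector(x0)
  y0v <- as.vector(y0)
  v <- (1 - fx) * (1 - fy) * img[cbind(x0v, y0v)] +
    fx * (1 - fy) * img[cbind(x0v + 1, y0v)] +
    (1 - fx) * fy * img[cbind(x0v, y0v + 1)] +
    fx * fy * img[cbind(x0v + 1, y0v + 1)]
  if (is.matrix(xs)) matrix(as.vector(v), nrow(xs), ncol(xs)) else as.vector(v)
}
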