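# Synthetic spinal-cord resting-state phantom.
#
# A "butterfly" gray-matter column (two ventral and two dorsal horns joined
# by a central commissural band) sits inside a white-matter ellipse,
# surrounded by a CSF annulus and, beyond a dark gap, non-spine neck tissue.
# Low-frequency signals shared between left/right ventral horns and between
# left/right dorsal horns are planted with known Pearson correlations;
# quasi-periodic cardiac and respiratory confounds (strongest in CSF),
# structured slow fluctuations, slice-wise bulk-intensity "swallow" events,
# slow in-plane translations and thermal noise complete the model.

#' Configuration of the synthetic spinal-cord phantom
#'
#' Builds and validates the parameter set that defines one simulated
#' resting-state acquisition. Defaults emulate the study conditions of a
#' 7 T cervical-cord protocol: 12 contiguous 4-mm axial slices, 150 volumes
#' at a volume acquisition time of 3.6 s, analysed on an interpolated
#' 0.31 x 0.31 mm in-plane grid cropped to a 64 x 64 window around the cord.
#'
#' @param grid in-plane grid size in voxels (square window around the cord).
#' @param n_slices number of axial slices.
#' @param n_volumes number of volumes (time points); at least 20.
#' @param tr volume acquisition time in seconds.
#' @param voxel_mm voxel dimensions in mm (x, y, slice thickness).
#' @param baselines named vector of tissue baseline intensities (a.u.) for
#'   `gm`, `wm`, `csf`, `notspine`.
#' @param rho_vv,rho_dd planted Pearson correlation between the left/right
#'   ventral horn signals and between the left/right dorsal horn signals,
#'   each in \[0, 1\].
#' @param rho_vd planted correlation between the shared ventral and shared
#'   dorsal components, in \[0, 1\]. The implied ventral-dorsal horn
#'   correlation is `sqrt(rho_vv * rho_dd) * rho_vd`.
#' @param signal_band frequency band (Hz) carrying the planted neural
#'   signals and the slow structured confounds.
#' @param signal_amp amplitude (a.u., per unit-variance series) of the horn
#'   signals.
#' @param sigma_thermal standard deviation of white thermal noise (a.u.),
#'   added to every voxel including background.
#' @param cardiac_freq,resp_freq cardiac and respiratory fundamental
#'   frequencies (Hz).
#' @param cardiac_amp,resp_amp named per-tissue amplitudes (a.u.).
#' @param csf_slow_amp per-tissue amplitude of a band-limited CSF-driven
#'   pulsatility residual (dominant in CSF, weaker in cord tissue).
#' @param csf_slow2_amp amplitude of a second, CSF-confined slow
#'   pulsatility mode (real CSF flow shows several spatial/temporal modes).
#' @param cord_global_amp per-tissue amplitude of a band-limited global cord
#'   fluctuation (dominant in white matter).
#' @param neck_slow_amp amplitudes of additional independent slow
#'   fluctuations confined to neck tissue (muscle tension, large-vessel
#'   pulsation), one component per element.
#' @param gain_cv spatial coefficient of variation of the per-voxel
#'   coupling gain of each structured confound (coil sensitivity and tissue
#'   heterogeneity make every noise source load differently on different
#'   voxels; this is what lets a PCA separate them).
#' @param bulk_rate expected number of bulk-intensity (swallowing-like)
#'   events per run; events are brief (1-2 volume) multiplicative intensity
#'   excursions affecting cord and neck tissue alike.
#' @param bulk_amp fractional intensity excursion of a bulk event.
#' @param motion_amp amplitude (voxels) of the slow in-plane translation
#'   drift per slice.
#' @param jump_prob per-volume probability of a single-volume translation
#'   spike (sporadic motion such as swallowing).
#' @param physio_rate sampling rate (Hz) of the recorded cardiac and
#'   respiratory traces.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   phantoms.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid = 64L, n_slices = 12L, n_volumes = 150L,
                           tr = 3.6, voxel_mm = c(0.31, 0.31, 4),
                           baselines = c(gm = 1000, wm = 950, csf = 1100, notspine = 850),
                           rho_vv = 0.5, rho_dd = 0.35, rho_vd = 0,
                           signal_band = c(0.01, 0.08), signal_amp = 8,
                           sigma_thermal = 25,
                           cardiac_freq = 1.05,
                           cardiac_amp = c(gm = 6, wm = 6, csf = 25, notspine = 12),
                           resp_freq = 0.3,
                           resp_amp = c(gm = 5, wm = 5, csf = 15, notspine = 20),
                           csf_slow_amp = c(gm = 12, wm = 12, csf = 30, notspine = 0),
                           csf_slow2_amp = 12,
                           cord_global_amp = c(gm = 15, wm = 18, csf = 0, notspine = 0),
                           neck_slow_amp = c(14, 10),
                           gain_cv = 1,
                           bulk_rate = 3, bulk_amp = 0.03,
                           motion_amp = 0.3, jump_prob = 0.02,
                           physio_rate = 50, seed = 1L) {
  grid <- as.integer(grid)
  n_slices <- as.integer(n_slices)
  n_volumes <- as.integer(n_volumes)
  if (grid < 16L) stopf("grid must be at least 16 voxels (got %d)", grid)
  if (n_slices < 1L) stopf("n_slices must be positive")
  if (n_volumes < 20L) stopf("n_volumes must be at least 20 (got %d)", n_volumes)
  if (tr <= 0) stopf("tr must be positive")
  for (rho in list(rho_vv = rho_vv, rho_dd = rho_dd, rho_vd = rho_vd)) {
    if (rho < 0 || rho > 1) stopf("planted correlations must lie in [0, 1]")
  }
  if (length(signal_band) != 2L || signal_band[1] <= 0 ||
      signal_band[1] >= signal_band[2]) {
    stopf("signal_band must be increasing positive frequencies")
  }
  tissues <- c("gm", "wm", "csf", "notspine")
  for (nm in c("baselines", "cardiac_amp", "resp_amp", "csf_slow_amp",
               "cord_global_amp")) {
    v <- get(nm)
    if (!all(tissues %in% names(v))) stopf("%s must name all of gm/wm/csf/notspine", nm)
    if (any(v < 0)) stopf("%s must be non-negative", nm)
  }
  if (sigma_thermal < 0 || signal_amp < 0 || bulk_amp < 0 || motion_amp < 0 ||
      csf_slow2_amp < 0 || any(neck_slow_amp < 0)) {
    stopf("amplitudes must be non-negative")
  }
  if (jump_prob < 0 || jump_prob > 1) stopf("jump_prob must be a probability")
  structure(list(
    grid = grid, n_slices = n_slices, n_volumes = n_volumes, tr = tr,
    voxel_mm = voxel_mm, baselines = baselines,
    rho_vv = rho_vv, rho_dd = rho_dd, rho_vd = rho_vd,
    signal_band = signal_band, signal_amp = signal_amp,
    sigma_thermal = sigma_thermal,
    cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
    resp_freq = resp_freq, resp_amp = resp_amp,
    csf_slow_amp = csf_slow_amp, csf_slow2_amp = csf_slow2_amp,
    cord_global_amp = cord_global_amp, neck_slow_amp = neck_slow_amp,
    gain_cv = gain_cv,
    bulk_rate = bulk_rate, bulk_amp = bulk_amp,
    motion_amp = motion_amp, jump_prob = jump_prob,
    physio_rate = physio_rate, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Parametric butterfly geometry, scaled to the grid (reference scale 64).
# Returns an integer label array: 0 background, 1 GM, 2 WM, 3 CSF,
# 4 not-spine; identical across slices.
butterfly_labels <- function(grid, n_slices, scale_ref = 64) {
  u <- grid / scale_ref
  cx <- (grid + 1) / 2
  cy <- (grid + 1) / 2
  x <- matrix(seq_len(grid), grid, grid)
  y <- matrix(seq_len(grid), grid, grid, byrow = TRUE)
  inside_ellipse <- function(x0, y0, a, b) {
    ((x - x0) / a)^2 + ((y - y0) / b)^2 <= 1
  }
  wm_ell <- inside_ellipse(cx, cy, 20 * u, 14 * u)
  csf_out <- inside_ellipse(cx, cy, 27 * u, 20 * u)
  # GM butterfly: ventral (anterior, small y) and dorsal horns + commissure
  gm <- inside_ellipse(cx - 6.5 * u, cy - 6 * u, 4.5 * u, 6.5 * u) |
    inside_ellipse(cx + 6.5 * u, cy - 6 * u, 4.5 * u, 6.5 * u) |
    inside_ellipse(cx - 4.5 * u, cy + 7 * u, 3.5 * u, 7 * u) |
    inside_ellipse(cx + 4.5 * u, cy + 7 * u, 3.5 * u, 7 * u) |
    (abs(x - cx) <= 7 * u & abs(y - cy) <= 2 * u)
  gm <- gm & wm_ell
  neck <- ((x - cx) / (27 * u))^2 + ((y - cy) / (20 * u))^2 > 1.44
  lab <- matrix(0L, grid, grid)
  lab[neck] <- 4L
  lab[csf_out & !wm_ell] <- 3L
  lab[wm_ell & !gm] <- 2L
  lab[gm] <- 1L
  array(lab, dim = c(grid, grid, n_slices))
}

#' Tissue masks container
#'
#' Wraps an integer label array (0 background, 1 gray matter, 2 white
#' matter, 3 CSF, 4 not-spine) with voxel dimensions. Masks are pairwise
#' disjoint by construction of the label map.
#'
#' @param labels integer array `[nx, ny, n_slices]` of tissue codes.
#' @param voxel_mm voxel dimensions in mm.
#' @return an object of class `tissue_masks`.
#' @export
tissue_masks <- function(labels, voxel_mm = c(0.31, 0.31, 4)) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  if (!all(labels %in% 0:4)) stopf("labels must use codes 0..4")
  structure(list(labels = labels, dim = dim(labels), voxel_mm = voxel_mm,
                 codes = c(background = 0L, gm = 1L, wm = 2L, csf = 3L,
                           notspine = 4L)),
            class = "tissue_masks")
}

#' Extract one tissue mask for a slice
#'
#' @param masks a `tissue_masks` object.
#' @param slice slice index (1-based).
#' @param tissue one of `"gm"`, `"wm"`, `"csf"`, `"notspine"`, `"cord"`
#'   (GM and WM) or `"spine"` (cord plus CSF).
#' @return logical matrix.
#' @export
mask_slice <- function(masks, slice, tissue) {
  lab <- masks$labels[, , slice]
  switch(tissue,
    gm = lab == 1L,
    wm = lab == 2L,
    csf = lab == 3L,
    notspine = lab == 4L,
    cord = lab == 1L | lab == 2L,
    spine = lab >= 1L & lab <= 3L,
    stopf("unknown tissue '%s'", tissue)
  )
}

# Quadrant membership of GM voxels used when planting horn signals; mirrors
# the subdivision rule used in the analysis (central band excluded).
horn_membership <- function(lab, central_halfwidth = 2) {
  nx <- nrow(lab)
  ny <- ncol(lab)
  gm <- lab == 1L
  cord <- lab == 1L | lab == 2L
  idx <- which(cord, arr.ind = TRUE)
  cx <- mean(idx[, 1])
  cy <- mean(idx[, 2])
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  central <- abs(x - cx) <= central_halfwidth
  list(
    lv = gm & !central & x > cx & y < cy,
    rv = gm & !central & x < cx & y < cy,
    ld = gm & !central & x > cx & y >= cy,
    rd = gm & !central & x < cx & y >= cy
  )
}

# Draw the planted component time courses for one phantom realisation.
# For pairs with a planted rho > 0 the shared and independent series are
# Gram-Schmidt orthonormalised, so cor(lv, rv) == rho_vv to machine
# precision before any noise is added; series of unplanted (rho = 0) pairs
# are left as independent draws, so their sample correlations sit at
# chance level as independent signals should.
plant_signals <- function(config) {
  n <- config$n_volumes
  tr <- config$tr
  basis <- band_limited_series(n, tr, config$signal_band, n_draw = 7L)
  std <- function(x) {
    x <- x - mean(x)
    x / sd(x)
  }
  # shared ventral/dorsal components (orthonormalised so a nonzero rho_vd
  # is exact; at rho_vd = 0 this leaves s_v, s_d exactly uncorrelated,
  # which only affects the shared components, not the horn-pair nulls)
  shared <- orthonormalize_series(basis[, 1:3])
  s_c <- shared[, 1]
  a <- sqrt(config$rho_vd)
  s_v <- a * s_c + sqrt(1 - config$rho_vd) * shared[, 2]
  s_d <- a * s_c + sqrt(1 - config$rho_vd) * shared[, 3]
  pair <- function(shared_s, e1, e2, rho) {
    if (rho > 0) {
      # orthonormalise the pair's independent parts against the shared
      # series and each other: the sample correlation equals rho exactly
      o <- orthonormalize_series(cbind(shared_s, e1, e2))
      cbind(sqrt(rho) * o[, 1] + sqrt(1 - rho) * o[, 2],
            sqrt(rho) * o[, 1] + sqrt(1 - rho) * o[, 3])
    } else {
      cbind(std(e1), std(e2))
    }
  }
  vv <- pair(s_v, basis[, 4], basis[, 5], config$rho_vv)
  dd <- pair(s_d, basis[, 6], basis[, 7], config$rho_dd)
  horns <- cbind(lv = vv[, 1], rv = vv[, 2], ld = dd[, 1], rd = dd[, 2])
  # analytic planted correlation matrix among the four horn signals
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- config$rho_vv
  rho[3, 4] <- rho[4, 3] <- config$rho_dd
  cross <- sqrt(config$rho_vv * config$rho_dd) * config$rho_vd
  rho[1, 3] <- rho[3, 1] <- rho[1, 4] <- rho[4, 1] <- cross
  rho[2, 3] <- rho[3, 2] <- rho[2, 4] <- rho[4, 2] <- cross
  dimnames(rho) <- list(colnames(horns), colnames(horns))
  # slow structured confounds, band-limited like the neural signals
  n_neck <- length(config$neck_slow_amp)
  slow <- band_limited_series(n, tr, config$signal_band, n_draw = 3L + n_neck)
  slow <- sweep(slow, 2L, apply(slow, 2L, sd), "/")
  list(horns = horns, shared_ventral = s_v, shared_dorsal = s_d,
       planted_rho = rho, csf_slow = slow[, 1], csf_slow2 = slow[, 2],
       cord_global = slow[, 3],
       neck_slow = slow[, 3L + seq_len(n_neck), drop = FALSE])
}

# continuous physiological waveforms (a.u., zero mean up to a constant)
cardiac_waveform <- function(t, freq, phase, kappa = 3) {
  exp(kappa * (cos(2 * pi * freq * t + phase) - 1))
}
resp_waveform <- function(t, freq, phase) {
  sin(2 * pi * freq * t + phase) + 0.3 * sin(4 * pi * freq * t + 2 * phase + 1)
}

#' Generate a synthetic spinal-cord resting-state acquisition
#'
#' Draws one phantom realisation: a 4-D intensity volume (motion-free; see
#' [render_motion()] to apply the planted translations), tissue masks, a
#' physiological recording and the full ground truth (planted correlations,
#' component time courses, translation traces).
#'
#' @param config a [phantom_config()] object.
#' @return a list with elements `volume` (array `[nx, ny, n_slices,
#'   n_volumes]` with attributes `voxel_mm` and `tr`), `masks`
#'   (a `tissue_masks` object), `physio` (a `physio_record`) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stopf("config must be a phantom_config")
  with_preserved_seed(config$seed, {
    nx <- config$grid
    ns <- config$n_slices
    nt <- config$n_volumes
    tr <- config$tr
    labels <- butterfly_labels(nx, ns)
    masks <- tissue_masks(labels, config$voxel_mm)
    sig <- plant_signals(config)

    # acquisition timing: slices acquired sequentially within each volume
    vol_times <- (seq_len(nt) - 1) * tr
    slice_offsets <- (seq_len(ns) - 1) * tr / ns
    acq_times <- outer(slice_offsets, vol_times, "+") # ns x nt

    # physiological recording over the scan duration (half-open grid:
    # rate x duration samples)
    duration <- nt * tr
    t_phys <- seq(0, by = 1 / config$physio_rate,
                  length.out = round(duration * config$physio_rate))
    phase_c <- runif(1, 0, 2 * pi)
    phase_r <- runif(1, 0, 2 * pi)
    card_trace <- cardiac_waveform(t_phys, config$cardiac_freq, phase_c)
    resp_trace <- resp_waveform(t_phys, config$resp_freq, phase_r)
    physio <- physio_record(time = t_phys, cardiac = card_trace,
                            resp = resp_trace, acq_times = acq_times,
                            rate = config$physio_rate)

    # bulk "swallow" events: brief multiplicative excursions
    bulk <- numeric(nt)
    n_events <- rpois(1, config$bulk_rate)
    if (n_events > 0) {
      starts <- sample.int(nt, n_events, replace = TRUE)
      for (ev in seq_len(n_events)) {
        len <- sample(1:2, 1)
        idx <- starts[ev]:min(nt, starts[ev] + len - 1L)
        bulk[idx] <- 1
      }
    }

    # planted in-plane translations per slice: slow sinusoidal drift plus
    # sporadic single-volume jumps
    translations <- array(0, dim = c(ns, nt, 2))
    f_drift <- 0.008
    for (s in seq_len(ns)) {
      for (ax in 1:2) {
        amp <- config$motion_amp * (if (ax == 1) 1 else 0.7)
        translations[s, , ax] <- amp * sin(2 * pi * f_drift * vol_times + runif(1, 0, 2 * pi))
      }
      jumps <- which(runif(nt) < config$jump_prob)
      for (j in jumps) {
        translations[s, j, ] <- translations[s, j, ] +
          runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, replace = TRUE)
      }
    }

    tissue_of <- c("gm", "wm", "csf", "notspine")
    vol <- array(0, dim = c(nx, nx, ns, nt))
    horn_names <- c("lv", "rv", "ld", "rd")
    for (s in seq_len(ns)) {
      lab <- labels[, , s]
      horns <- horn_membership(lab)
      ts_s <- acq_times[s, ]
      card_s <- cardiac_waveform(ts_s, config$cardiac_freq, phase_c)
      card_s <- (card_s - mean(card_s)) / max(sd(card_s), 1e-12)
      resp_s <- resp_waveform(ts_s, config$resp_freq, phase_r)
      resp_s <- (resp_s - mean(resp_s)) / max(sd(resp_s), 1e-12)

      M <- matrix(0, nx * nx, nt)
      for (k in 1:4) {
        tis <- tissue_of[k]
        idx <- which(lab == k)
        if (!length(idx)) next
        # structured confounds. The dominant pulsatile modes (csf_slow,
        # cord_global) couple coherently (uniform gain): they are single
        # physical sources, which is what makes one eigenvector per mode
        # an adequate nuisance regressor. Secondary modes and the
        # quasi-periodic confounds couple with heterogeneous per-voxel
        # gains (mean 1, sd gain_cv), so a PCA can tell them apart.
        comps <- cbind(
          config$cardiac_amp[[tis]] * card_s,
          config$resp_amp[[tis]] * resp_s,
          config$csf_slow_amp[[tis]] * sig$csf_slow,
          config$cord_global_amp[[tis]] * sig$cord_global
        )
        gain_type <- c("iid", "iid", "uniform", "uniform")
        if (tis == "csf") {
          comps <- cbind(comps, config$csf_slow2_amp * sig$csf_slow2)
          # a second flow mode is spatially orthogonal to the bulk
          # pulsation: opposite-phase coupling across the annulus
          gain_type <- c(gain_type, "zeromean")
        }
        if (tis == "notspine" && length(config$neck_slow_amp)) {
          comps <- cbind(comps, sweep(sig$neck_slow, 2L,
                                      config$neck_slow_amp, "*"))
          gain_type <- c(gain_type, rep("iid", ncol(sig$neck_slow)))
        }
        active <- which(colSums(abs(comps)) > 0)
        if (length(active)) {
          G <- vapply(active, function(a) {
            switch(gain_type[a],
              uniform = rep(1, length(idx)),
              zeromean = config$gain_cv * rnorm(length(idx)),
              1 + config$gain_cv * rnorm(length(idx)))
          }, numeric(length(idx)))
          M[idx, ] <- config$baselines[[tis]] +
            matrix(G, length(idx)) %*% t(comps[, active, drop = FALSE])
        } else {
          M[idx, ] <- config$baselines[[tis]]
        }
      }
      for (h in seq_along(horn_names)) {
        idx <- which(horns[[horn_names[h]]])
        if (!length(idx)) next
        M[idx, ] <- M[idx, ] +
          rep(config$signal_amp * sig$horns[, h], each = length(idx))
      }
      if (any(bulk > 0)) {
        tissue_vox <- which(lab > 0L)
        M[tissue_vox, ] <- M[tissue_vox, ] *
          rep(1 + config$bulk_amp * bulk, each = length(tissue_vox))
      }
      M <- M + rnorm(length(M), sd = config$sigma_thermal)
      cpp_set_slice(vol, M, nx, nx, ns, nt, s)
    }
    attr(vol, "voxel_mm") <- config$voxel_mm
    attr(vol, "tr") <- tr

    truth <- structure(list(
      planted_rho = sig$planted_rho,
      horn_series = sig$horns,
      shared_ventral = sig$shared_ventral,
      shared_dorsal = sig$shared_dorsal,
      csf_slow = sig$csf_slow,
      csf_slow2 = sig$csf_slow2,
      cord_global = sig$cord_global,
      neck_slow = sig$neck_slow,
      bulk = bulk,
      translations = translations,
      config = config
    ), class = "phantom_truth")

    list(volume = vol, masks = masks, physio = physio, truth = truth)
  })
}

#' Apply the planted motion to a phantom volume
#'
#' Shifts every slice-volume by its ground-truth in-plane translation using
#' band-limited (Fourier/sinc) interpolation. All-zero translations return
#' the input unchanged, bit for bit.
#'
#' @param volume 4-D array from [generate_phantom()].
#' @param truth the matching `phantom_truth` object.
#' @return 4-D array of the same shape.
#' @export
render_motion <- function(volume, truth) {
  dm <- dim(volume)
  tran <- truth$translations
  if (is.null(tran)) stopf("ground truth lacks translation traces")
  if (dim(tran)[1] != dm[3] || dim(tran)[2] != dm[4]) {
    stopf("translation traces do not match the volume dimensions")
  }
  if (max(abs(tran)) > min(dm[1], dm[2]) / 4) {
    stopf("planted translation exceeds a quarter of the grid extent")
  }
  if (all(tran == 0)) return(volume)
  out <- cpp_render_motion(volume, dm[1], dm[2], dm[3], dm[4], tran)
  attr(out, "voxel_mm") <- attr(volume, "voxel_mm")
  attr(out, "tr") <- attr(volume, "tr")
  out
}

#' Physiological recording
#'
#' @param time sampling times (s), uniformly spaced.
#' @param cardiac,resp cardiac and respiratory traces (a.u.), same length as
#'   `time`.
#' @param acq_times matrix `[n_slices, n_volumes]` of slice acquisition
#'   times (s), strictly increasing along volumes.
#' @param rate sampling rate (Hz).
#' @return an object of class `physio_record`.
#' @export
physio_record <- function(time, cardiac, resp, acq_times = NULL, rate = 50) {
  if (length(cardiac) != length(time) || length(resp) != length(time)) {
    stopf("physio traces must have one sample per time point")
  }
  if (!is.null(acq_times)) {
    if (length(time) && max(acq_times) > max(time) + 1e-9) {
      stopf("physio traces do not cover the acquisition")
    }
    if (any(apply(acq_times, 1, function(r) any(diff(r) <= 0)))) {
      stopf("acquisition times must be strictly increasing")
    }
  }
  structure(list(time = time, cardiac = cardiac, resp = resp,
                 acq_times = acq_times, rate = rate),
            class = "physio_record")
}

#' Write a physiological recording to TSV
#'
#' Columns `time`, `cardiac`, `resp`; full precision, so a read-back via
#' [read_physio()] reproduces the traces exactly.
#'
#' @param record a `physio_record`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_physio <- function(record, path) {
  df <- data.frame(time = record$time, cardiac = record$cardiac,
                   resp = record$resp)
  # full double precision survives the round trip
  fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  if (nrow(df) == 0L) fmt <- matrix(character(0), 0, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", "cardiac", "resp"), collapse = "\t"), con)
  if (nrow(df)) writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a physiological recording from TSV
#'
#' @param path file written by [write_physio()].
#' @param acq_times optional acquisition-time matrix to attach.
#' @param rate sampling rate (Hz); inferred from the time column if omitted.
#' @return a `physio_record`.
#' @export
read_physio <- function(path, acq_times = NULL, rate = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE)
  if (is.null(rate)) {
    rate <- if (nrow(df) > 1) 1 / median(diff(df$time)) else 50
  }
  physio_record(df$time, df$cardiac, df$resp, acq_times = acq_times, rate = rate)
}
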