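# End-to-end orchestration: the 14-step slice-wise preprocessing chain,
# per-slice connectivity matrices, multi-subject group studies on the
# phantom, and null-calibration runs.

#' Preprocessing configuration
#'
#' Collects every tunable of the denoising chain. The `regressors` switch
#' reproduces the pipeline permutations used for sensitivity analyses:
#' skipping CSF/WM regression, CSF only, the standard CSF+WM chain, a
#' combined WM&GM eigenvector, or an eroded-WM eigenvector.
#'
#' @param notspine_cap,csf_cap cumulative-variance caps for not-spine and
#'   CSF principal components.
#' @param eig_gap successive-eigenvalue difference threshold (fraction of
#'   total variance).
#' @param gap_rule `"absolute"` (default) or `"relative"`; see
#'   [eig_selection_rule()].
#' @param max_components hard cap per PCA regressor block.
#' @param retroicor_order RETROICOR Fourier order.
#' @param band,atten_db,filter_order band-pass settings, see
#'   [filter_spec()].
#' @param regressors one of `"csf+wm"`, `"none"`, `"csf-only"`,
#'   `"csf+wm&gm"`, `"csf+wm-eroded"`.
#' @param motion run slice-wise motion correction.
#' @param affine run the optional simplified affine stage (off by default;
#'   phantom data are generated aligned).
#' @param max_shift integer search radius for translation estimation.
#' @param notspine_dilate dilation (voxels) of the spine region when
#'   building the not-spine mask.
#' @param central_halfwidth half-width (voxels) of the excluded central
#'   gray-matter band.
#' @param gm_erode,wm_erode disk radii (voxels) for sub-region erosion.
#' @param median_window motion-trace median-filter window.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(notspine_cap = 0.80, csf_cap = 0.50,
                            eig_gap = 0.02,
                            gap_rule = c("absolute", "relative"),
                            max_components = 10L, retroicor_order = 2L,
                            band = c(0.01, 0.08), atten_db = 30,
                            filter_order = 5L,
                            regressors = c("csf+wm", "none", "csf-only",
                                           "csf+wm&gm", "csf+wm-eroded"),
                            motion = TRUE, affine = FALSE, max_shift = 8L,
                            notspine_dilate = 3, central_halfwidth = 2,
                            gm_erode = 3, wm_erode = 11,
                            median_window = 5L) {
  structure(list(
    notspine_cap = notspine_cap, csf_cap = csf_cap, eig_gap = eig_gap,
    gap_rule = match.arg(gap_rule), max_components = as.integer(max_components),
    retroicor_order = as.integer(retroicor_order), band = band,
    atten_db = atten_db, filter_order = as.integer(filter_order),
    regressors = match.arg(regressors), motion = motion, affine = affine,
    max_shift = as.integer(max_shift), notspine_dilate = notspine_dilate,
    central_halfwidth = central_halfwidth, gm_erode = gm_erode,
    wm_erode = wm_erode, median_window = as.integer(median_window)
  ), class = "pipeline_config")
}

#' Run the full slice-wise preprocessing chain
#'
#' Applies, per slice: not-spine PCA regression (of all voxels), two-pass
#' weighted motion correction, RETROICOR, CSF PCA regression (of cord
#' voxels), white-matter eigenvector regression (of gray+white voxels),
#' zero-phase band-pass filtering (cord and CSF voxels), and quadrant
#' subdivision with morphological erosion of the eight sub-region masks.
#' Gray-matter TSNR is recorded before the CSF/WM regression stage and
#' after it (both before filtering).
#'
#' @param volume 4-D array `[nx, ny, n_slices, n_volumes]`.
#' @param masks a [tissue_masks()] object.
#' @param physio a [physio_record()] (required unless
#'   `retroicor_order = 0`).
#' @param config a [pipeline_config()].
#' @return a `preprocessed_run`: `series` (filtered 4-D array),
#'   `subregions` (list per slice), `motion` (list per slice),
#'   `regressor_info` (data frame: slice, k_notspine, k_csf,
#'   wm_var_fraction), `tsnr` (list with per-slice GM medians `pre` and
#'   `post` and pooled-voxel medians `pre_all`, `post_all`), `config`.
#' @export
preprocess_run <- function(volume, masks, physio = NULL,
                           config = pipeline_config()) {
  dm <- dim(volume)
  ns <- dm[3]
  nt <- dm[4]
  tr <- attr(volume, "tr") %||% 3.6
  spec <- filter_spec(config$band, tr, config$filter_order, config$atten_db)
  ns_rule <- eig_selection_rule(config$notspine_cap, config$eig_gap,
                                config$gap_rule, config$max_components)
  csf_rule <- eig_selection_rule(config$csf_cap, config$eig_gap,
                                 config$gap_rule, config$max_components)
  use_csf <- config$regressors != "none"
  use_wm <- config$regressors %in% c("csf+wm", "csf+wm&gm", "csf+wm-eroded")
  wm_variant <- switch(config$regressors,
                       "csf+wm&gm" = "wm+gm",
                       "csf+wm-eroded" = "wm-eroded",
                       "wm")

  out <- array(0, dim = dm)
  subregions <- vector("list", ns)
  motion <- vector("list", ns)
  info <- data.frame(slice = seq_len(ns), k_notspine = NA_integer_,
                     k_csf = NA_integer_, wm_var_fraction = NA_real_,
                     p_total = NA_integer_)
  tsnr_pre <- tsnr_post <- numeric(ns)
  vox_pre <- vox_post <- list()

  Fop_t <- t(filter_operator(spec, nt))
  for (s in seq_len(ns)) {
    M <- cpp_slice_matrix(volume, dm[1], dm[2], ns, nt, s) # voxels x time

    # steps 1-2: weighting kernel and not-spine mask (cached when the
    # label map repeats across slices, as it does for the phantom)
    same_labels <- s > 1L &&
      identical(masks$labels[, , s], masks$labels[, , s - 1L])
    if (!same_labels) {
      kernel <- make_weight_kernel(masks, s)
      notspine <- make_not_spine_mask(masks, s, config$notspine_dilate)
      gm_idx <- which(mask_slice(masks, s, "gm"))
      cord_idx <- which(mask_slice(masks, s, "cord"))
      spine_idx <- which(mask_slice(masks, s, "spine"))
      csf_idx <- which(mask_slice(masks, s, "csf"))
      wm_reg_idx <- switch(wm_variant,
        "wm" = which(mask_slice(masks, s, "wm")),
        "wm+gm" = cord_idx,
        "wm-eroded" = which(erode_subregion(mask_slice(masks, s, "wm"),
                                            1)$mask))
    }

    # step 6 regressors (evaluated at this slice's acquisition times)
    retro <- if (config$retroicor_order > 0) {
      if (is.null(physio)) stopf("physio record required for RETROICOR")
      retroicor_regressors(physio, s, config$retroicor_order)
    } else {
      matrix(0, nt, 0)
    }

    # steps 3-6, 11-13 run in the compiled per-slice core; steps 8-9
    # (affine registration to anatomy) are optional and skipped for
    # phantom data, which are generated in anatomical space
    res <- cpp_preprocess_slice(
      M, dm[1], dm[2], which(notspine) - 1L, csf_idx - 1L, wm_reg_idx - 1L,
      cord_idx - 1L, gm_idx - 1L, spine_idx - 1L, kernel$weights, retro,
      Fop_t, config$notspine_cap, config$csf_cap, config$eig_gap,
      config$gap_rule == "relative", config$max_components, config$motion,
      config$max_shift, 1L, config$median_window, use_csf, use_wm
    )
    info$k_notspine[s] <- res$k_notspine
    if (use_csf) info$k_csf[s] <- res$k_csf
    if (use_wm) info$wm_var_fraction[s] <- res$wm_var_fraction
    # degrees of freedom spent on nuisance regression (intercept counted
    # once; it is the same constant dimension in every stage)
    info$p_total[s] <- 1L + res$k_notspine + ncol(retro) +
      (if (use_csf) res$k_csf else 0L) + (if (use_wm) 1L else 0L)
    if (config$motion) {
      tr_raw <- res$trace_raw
      tr_filt <- res$trace_filtered
      colnames(tr_raw) <- colnames(tr_filt) <- c("dx", "dy")
      motion[[s]] <- list(trace_raw = tr_raw, trace_filtered = tr_filt,
                          target = res$target)
    }
    vox_pre[[s]] <- as.numeric(res$tsnr_pre)
    tsnr_pre[s] <- median(vox_pre[[s]], na.rm = TRUE)
    vox_post[[s]] <- as.numeric(res$tsnr_post)
    tsnr_post[s] <- median(vox_post[[s]], na.rm = TRUE)

    # step 14: quadrant subdivision and erosion (cached like the masks)
    if (same_labels) {
      subregions[[s]] <- subregions[[s - 1L]]
      subregions[[s]]$slice <- s
    } else {
      subregions[[s]] <- erode_subregions(
        subdivide_quadrants(masks, s, config$central_halfwidth),
        config$gm_erode, config$wm_erode
      )
    }
    cpp_set_slice(out, res$M, dm[1], dm[2], ns, nt, s)
  }
  attr(out, "tr") <- tr
  attr(out, "voxel_mm") <- attr(volume, "voxel_mm")
  structure(list(
    series = out, subregions = subregions, motion = motion,
    regressor_info = info, filter_dof = filter_dof(spec, nt),
    tsnr = list(pre = tsnr_pre, post = tsnr_post,
                pre_all = median(unlist(vox_pre), na.rm = TRUE),
                post_all = median(unlist(vox_post), na.rm = TRUE)),
    config = config
  ), class = "preprocessed_run")
}

#' Per-slice connectivity matrices of a preprocessed run
#'
#' @param run a `preprocessed_run`.
#' @return array `[8, 8, n_slices]` of z matrices.
#' @export
connectivity_matrices <- function(run) {
  dm <- dim(run$series)
  zs <- array(0, dim = c(8, 8, dm[3]),
              dimnames = list(subregion_names(), subregion_names(), NULL))
  md <- run$filter_dof %||% Inf
  for (s in seq_len(dm[3])) {
    M <- cpp_slice_matrix(run$series, dm[1], dm[2], dm[3], dm[4], s)
    p_s <- run$regressor_info$p_total[s]
    zs[, , s] <- .roi_connectivity_mat(M, run$subregions[[s]],
                                       if (is.na(p_s)) 0 else p_s, md)$z
  }
  zs
}

#' Simulate and analyse one phantom subject
#'
#' Generates a phantom, applies the planted motion, runs the preprocessing
#' chain and returns the per-slice and median connectivity matrices.
#'
#' @param config a [phantom_config()].
#' @param pipe a [pipeline_config()].
#' @return list with `slice_z` (`[8, 8, n_slices]`), `median_z` (8x8),
#'   `tsnr`, `regressor_info`, `motion_truth`, `motion_est`.
#' @export
run_subject <- function(config, pipe = pipeline_config()) {
  ph <- generate_phantom(config)
  vol <- render_motion(ph$volume, ph$truth)
  run <- preprocess_run(vol, ph$masks, ph$physio, pipe)
  slice_z <- connectivity_matrices(run)
  list(slice_z = slice_z, median_z = subject_median(slice_z),
       tsnr = run$tsnr, regressor_info = run$regressor_info,
       motion_truth = ph$truth$translations,
       motion_est = lapply(run$motion, function(m) m$trace_filtered))
}

#' Multi-subject phantom group study
#'
#' Simulates `n_subjects` independent phantom subjects (fresh seeds drawn
#' from `seed`), analyses each, stacks the per-subject median z matrices
#' and runs the group-level signed-rank inference.
#'
#' @param n_subjects number of subjects (default 22).
#' @param seed master seed for the study.
#' @param config base [phantom_config()]; per-subject seeds are derived.
#' @param pipe a [pipeline_config()].
#' @return list with `group` (`[8, 8, n_subjects]`), `result`
#'   (a `group_result`), `tsnr_gain_percent` (median-TSNR change across
#'   subjects), `slice_z` (`[8, 8, n_slices, n_subjects]`).
#' @export
run_group_study <- function(n_subjects = 22L, seed = 1L,
                            config = phantom_config(),
                            pipe = pipeline_config()) {
  subj_seeds <- with_preserved_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_subjects))
  group <- array(0, dim = c(8, 8, n_subjects),
                 dimnames = list(subregion_names(), subregion_names(), NULL))
  slice_z <- NULL
  pre <- post <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- subj_seeds[i]
    res <- run_subject(cfg, pipe)
    group[, , i] <- res$median_z
    if (is.null(slice_z)) {
      slice_z <- array(0, dim = c(8, 8, dim(res$slice_z)[3], n_subjects),
                       dimnames = list(subregion_names(), subregion_names(),
                                       NULL, NULL))
    }
    slice_z[, , , i] <- res$slice_z
    pre[i] <- res$tsnr$pre_all
    post[i] <- res$tsnr$post_all
  }
  result <- group_pipeline(group)
  list(group = group, result = result,
       tsnr_pre = median(pre), tsnr_post = median(post),
       tsnr_gain_percent = 100 * (median(post) - median(pre)) / median(pre),
       slice_z = slice_z)
}

#' Null-calibration study
#'
#' Simulates phantom subjects with every planted correlation set to zero
#' and tallies, per ROI pair, the fraction of slices whose z exceeds a
#' one-tailed threshold. Motion is disabled by default so the tally
#' isolates the statistical calibration of the correlation chain.
#'
#' @param n_slices_total minimum total number of slices to accumulate.
#' @param seed master seed.
#' @param config base [phantom_config()]; correlations are zeroed.
#' @param pipe a [pipeline_config()].
#' @param threshold one-tailed z threshold (default 1.65).
#' @param motion keep the planted motion and its correction (default
#'   FALSE).
#' @return list with `exceedance` (named per-pair fractions in percent),
#'   `n_slices`, `z` (matrix slices x pairs).
#' @export
run_null_study <- function(n_slices_total = 2000L, seed = 1L,
                           config = phantom_config(),
                           pipe = pipeline_config(), threshold = 1.65,
                           motion = FALSE) {
  config$rho_vv <- 0
  config$rho_dd <- 0
  config$rho_vd <- 0
  if (!motion) {
    config$motion_amp <- 0
    config$jump_prob <- 0
    pipe$motion <- FALSE
  }
  n_subj <- ceiling(n_slices_total / config$n_slices)
  subj_seeds <- with_preserved_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_subj))
  nm <- subregion_names()
  pair_idx <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  pair_names <- paste(nm[pair_idx[, 1]], nm[pair_idx[, 2]], sep = ":")
  zrows <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    cfg <- config
    cfg$seed <- subj_seeds[i]
    ph <- generate_phantom(cfg)
    vol <- if (motion) render_motion(ph$volume, ph$truth) else ph$volume
    run <- preprocess_run(vol, ph$masks, ph$physio, pipe)
    zs <- connectivity_matrices(run)
    zrows[[i]] <- t(apply(zs, 3, function(m) m[upper.tri(m)]))
  }
  z <- do.call(rbind, zrows)
  colnames(z) <- pair_names
  exceed <- 100 * colMeans(z > threshold)
  list(exceedance = exceed, n_slices = nrow(z), z = z)
}

#' Full-chain z calibration on independent AR(1) pairs
#'
#' Simulates pairs of independent AR(1) series, runs each through the
#' complete correlation-to-z chain (Pearson r, effective degrees of
#' freedom, Fisher transform) and summarises the empirical null.
#'
#' @param n_pairs number of pairs.
#' @param n series length.
#' @param phi AR(1) coefficient of both series.
#' @param seed RNG seed.
#' @return list with `mean`, `var` and the vector `z`.
#' @export
ar1_null_calibration <- function(n_pairs = 10000L, n = 150L, phi = 0.5,
                                 seed = 1L) {
  with_preserved_seed(seed, {
    z <- numeric(n_pairs)
    block <- 1000L
    done <- 0L
    while (done < n_pairs) {
      m <- min(block, n_pairs - done)
      A <- matrix(rnorm(n * m), n, m)
      B <- matrix(rnorm(n * m), n, m)
      A <- apply(A, 2, function(x) as.numeric(stats::filter(x, phi, "recursive")))
      B <- apply(B, 2, function(x) as.numeric(stats::filter(x, phi, "recursive")))
      for (k in seq_len(m)) {
        st <- correlation_stats(A[, k], B[, k])
        z[done + k] <- st$z
      }
      done <- done + m
    }
    list(mean = mean(z), var = stats::var(z), z = z)
  })
}
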