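phantom_slice <- function(seed = 7, ...) {
  ph <- generate_phantom(phantom_config(grid = 64L, n_slices = 1L,
                                        n_volumes = 40L, seed = seed,
                                        motion_amp = 0, jump_prob = 0, ...))
  list(series = array(ph$volume[, , 1, ], c(64, 64, 40)),
       kernel = make_weight_kernel(ph$masks, 1), ph = ph)
}

test_that("target selection minimises distance to the voxelwise median image", {
  fx <- phantom_slice()
  s <- fx$series
  # plant a volume equal to the median image: it must win
  med <- apply(matrix(s, 64 * 64, 40), 1, median)
  s2 <- s
  s2[, , 17] <- matrix(med, 64, 64)
  expect_equal(select_target_volume(s2), 17)

  # brute-force check on a small series
  small <- s[1:10, 1:10, 1:5]
  med5 <- apply(matrix(small, 100, 5), 1, median)
  err <- colSums((matrix(small, 100, 5) - med5)^2)
  expect_equal(select_target_volume(small), which.min(err))

  # exact tie goes to the lower index
  tied <- array(rnorm(25 * 4), c(5, 5, 4))
  tied[, , 3] <- tied[, , 1] # duplicated volumes tie exactly
  med_t <- apply(matrix(tied, 25, 4), 1, median)
  errs <- colSums((matrix(tied, 25, 4) - med_t)^2)
  if (which.min(errs) == 1) expect_lt(select_target_volume(tied), 3)
})

test_that("translation estimation recovers known shifts to sub-voxel accuracy", {
  fx <- phantom_slice()
  img <- fx$series[, , 1]
  w <- fx$kernel
  expect_lt(max(abs(estimate_translation(img, img, w))), 1e-3)
  for (sh in list(c(2, 1), c(-3, 2))) {
    mov <- spinecorr:::cpp_fourier_shift(img, sh[1], sh[2])
    expect_equal(unname(estimate_translation(mov, img, w)), sh,
                 tolerance = 0.05)
  }
  for (sh in list(c(0.5, -0.3), c(-1.25, 0.75), c(3.6, -3.9))) {
    mov <- spinecorr:::cpp_fourier_shift(img, sh[1], sh[2])
    expect_equal(unname(estimate_translation(mov, img, w)), sh,
                 tolerance = 0.1)
  }
  flat <- matrix(1, 64, 64)
  expect_error(estimate_translation(flat, img, w), "flat")
})

test_that("motion-trace median filtering suppresses spikes and matches the oracle", {
  expect_equal(filter_motion_trace(c(0, 0, 5, 0, 0)), rep(0, 5))
  expect_equal(filter_motion_trace(rep(2.5, 9)), rep(2.5, 9))
  expect_error(filter_motion_trace(1:5, window = 4), "odd")

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(6:30, 1))
    expect_equal(filter_motion_trace(x), median_filter_oracle(x, 5))
  }
  # two-column traces are filtered per component
  tr <- cbind(dx = c(1, 2, 3, 4, 5, 6), dy = c(0, 0, 9, 0, 0, 0))
  f <- filter_motion_trace(tr)
  expect_equal(f[, 1], median_filter_oracle(tr[, 1], 5))
  expect_equal(f[, 2], rep(0, 6))
})

test_that("median filtering is idempotent on smooth filtered traces", {
  # a filtered slow drift is locally monotone within the window, i.e. a
  # root of the running median
  t <- seq(0, 150)
  drift <- cbind(1.5 * sin(2 * pi * 0.008 * t * 3.6),
                 0.8 * cos(2 * pi * 0.01 * t * 3.6))
  once <- filter_motion_trace(drift)
  twice <- filter_motion_trace(once)
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("applying a trace undoes the motion it encodes", {
  fx <- phantom_slice()
  s <- fx$series
  expect_identical(apply_translation(s, matrix(0, 40, 2)), s)

  # shift every volume, correct with the true trace, re-estimate: residual small
  tr <- cbind(runif(40, -1.5, 1.5), runif(40, -1.5, 1.5))
  moved <- spinecorr:::cpp_shift_stack(s, tr[, 1], tr[, 2])
  fixed <- apply_translation(moved, tr)
  resid <- spinecorr:::cpp_estimate_stack(fixed, fixed[, , 1], fx$kernel$weights,
                                          4L, 3L)
  expect_lt(max(abs(resid)), 0.05)

  # Fourier upsampling of a constant image is constant
  const <- array(3.7, c(8, 8, 2))
  up <- apply_translation(const, matrix(0, 2, 2), upsample = 3L)
  expect_equal(dim(up), c(24, 24, 2))
  expect_equal(as.vector(up), rep(3.7, 24 * 24 * 2), tolerance = 1e-12)
})

test_that("two-pass correction recovers drift and ignores intensity-event spikes", {
  # drift up to 2 voxels plus one bulk intensity event (no real motion jump):
  # the median filter must reject the event-driven estimate spike
  cfg <- phantom_config(grid = 64L, n_slices = 1L, n_volumes = 60L, seed = 13L,
                        motion_amp = 0, jump_prob = 0, bulk_rate = 0)
  ph <- generate_phantom(cfg)
  s <- array(ph$volume[, , 1, ], c(64, 64, 60))
  t <- (0:59) * cfg$tr
  truth <- cbind(2 * sin(2 * pi * 0.006 * t), 1.2 * cos(2 * pi * 0.009 * t))
  moved <- spinecorr:::cpp_shift_stack(s, truth[, 1], truth[, 2])
  spike_vol <- 25
  moved[, , spike_vol] <- moved[, , spike_vol] * 1.15 # swallowing-like event
  kernel <- make_weight_kernel(ph$masks, 1)
  mc <- correct_motion_slice(moved, kernel)
  # estimates are relative to the target volume's own position
  rel_truth <- sweep(truth, 2, truth[mc$target, ])
  resid <- mc$trace_filtered - rel_truth
  expect_lt(sqrt(mean(resid^2)), 0.15)
  expect_lt(max(abs(resid[spike_vol, ])), 0.3)
})

test_that("the optional affine stage recovers identity and bounded distortions", {
  # anatomical and functional images share structure but have independent
  # noise, as in real acquisitions
  cfg <- phantom_config(grid = 64L, n_slices = 1L, n_volumes = 20L, seed = 7,
                        sigma_thermal = 0, motion_amp = 0, jump_prob = 0,
                        bulk_rate = 0)
  ph <- generate_phantom(cfg)
  struct <- ph$volume[, , 1, 1]
  set.seed(2)
  anat <- struct + rnorm(length(struct), sd = 5)
  moving0 <- struct + rnorm(length(struct), sd = 5)
  kern <- make_weight_kernel(ph$masks, 1)

  fit <- register_affine_slice(moving0, anat, kern)
  expect_lt(max(abs(fit$params[c("tx", "ty")])), 0.3)
  expect_lt(abs(fit$params[["sx"]]), 0.005)

  # a known 1% scale expansion along x is recovered within 0.3%
  # (the fitted sx maps moving -> anatomical, so it is the inverse scale)
  nx <- 64
  cx <- (nx + 1) / 2
  xs <- (seq_len(nx) - cx) * 1.01 + cx
  warped <- apply(struct, 2, function(col) approx(seq_len(nx), col, xs,
                                                  rule = 2)$y)
  moving <- warped + rnorm(length(warped), sd = 5)
  fit2 <- register_affine_slice(moving, anat, kern)
  expect_equal(fit2$params[["sx"]], 1 / 1.01 - 1, tolerance = 0.35)
  expect_lt(abs(fit2$params[["sx"]] - (1 / 1.01 - 1)), 0.003)
  expect_true(all(abs(fit2$params) <= c(5, 5, 0.01, 0.05, 0.05) + 1e-9))
})
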