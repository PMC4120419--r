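test_that("Pearson correlation handles the canonical cases and rejects degenerate input", {
  t <- seq_len(64)
  a <- rnorm(64)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  s <- sin(2 * pi * t / 16)
  c <- cos(2 * pi * t / 16)
  expect_lt(abs(pearson_r(s, c)), 1e-10) # orthogonal over whole periods
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_r(rnorm(3), rnorm(3)), "length")
})

test_that("effective degrees of freedom follow the autocorrelation corrections", {
  # exactly zero sample lag-1 autocorrelation: lag-1 form gives dof = N
  x <- rep(c(1, 0, -1, 0), 25) # every consecutive product is zero
  expect_equal(spinecorr:::lag1_autocor(x), 0)
  expect_equal(effective_dof(x, x, method = "bartlett-lag1"), 100)

  # periodic series with lag-1 autocorrelation ~ cos(2*pi/6) = 0.5:
  # lag-1 form gives dof ~ N * 0.75 / 1.25 = 90
  y <- cos(2 * pi * (0:149) / 6)
  r1 <- spinecorr:::lag1_autocor(y)
  expect_equal(r1, 0.5, tolerance = 0.02)
  expect_equal(effective_dof(y, y, method = "bartlett-lag1"),
               150 * (1 - r1^2) / (1 + r1^2), tolerance = 1e-12)
  expect_equal(effective_dof(y, y, method = "bartlett-lag1"), 90,
               tolerance = 1.5)

  # the two methods agree on AR(1)-like noise (where lag-1 is exact)
  set.seed(99)
  agree <- replicate(40, {
    a <- as.numeric(stats::filter(rnorm(150), 0.5, "recursive"))
    b <- as.numeric(stats::filter(rnorm(150), 0.5, "recursive"))
    effective_dof(a, b) / effective_dof(a, b, method = "bartlett-lag1")
  })
  expect_equal(mean(agree), 1, tolerance = 0.1)

  # near-unit autocorrelation collapses the effective sample size
  ramp <- as.numeric(1:150)
  expect_equal(effective_dof(ramp, ramp, method = "bartlett-lag1"), 4)
  expect_lt(effective_dof(ramp, ramp), 10)
  expect_error(effective_dof(1:5, 1:5), "at least 8")
})

test_that("the Fisher transform matches the arithmetic oracle and is monotone", {
  expect_equal(fisher_z(0, 57), 0)
  expect_equal(fisher_z(0.5, 103), 5.4931, tolerance = 1e-4)
  expect_equal(fisher_z(0.5, 103), atanh(0.5) * sqrt(100), tolerance = 1e-12)
  # odd in r
  for (r in c(0.1, 0.4, 0.77)) {
    expect_equal(fisher_z(-r, 50), -fisher_z(r, 50))
  }
  # strictly increasing in |r| and in dof
  rs <- seq(0, 0.99, by = 0.11)
  zs <- sapply(rs, fisher_z, dof = 40)
  expect_true(all(diff(zs) > 0))
  dofs <- c(10, 40, 90, 150)
  zd <- sapply(dofs, function(d) fisher_z(0.5, d))
  expect_true(all(diff(zd) > 0))
  # degenerate (identical) series stay finite through the clamp
  expect_true(is.finite(fisher_z(1, 150)))
  expect_error(fisher_z(1.5, 50), "exceed")
  expect_error(fisher_z(0.5, 3), "at least 4")
})

test_that("cluster labelling agrees with a recursive flood-fill oracle", {
  # exhaustive over all 2x2x2 maps
  for (code in 0:255) {
    m <- array(as.logical(intToBits(code)[1:8]), c(2, 2, 2))
    got <- label_clusters(m)
    expect_true(same_partition(got, floodfill_oracle(m)))
  }
  # random 4x4x3 maps, both connectivities
  set.seed(5)
  for (i in 1:120) {
    m <- array(runif(48) < 0.45, c(4, 4, 3))
    expect_true(same_partition(label_clusters(m, "face3d"),
                               floodfill_oracle(m, "face3d")))
    expect_true(same_partition(label_clusters(m, "inplane8"),
                               floodfill_oracle(m, "inplane8")))
  }
})

test_that("seed maps apply the threshold and cluster-extent rules", {
  set.seed(8)
  nx <- 14
  nt <- 150
  lab <- array(0L, c(nx, nx, 1))
  lab[2:13, 2:13, 1] <- 2L
  masks <- tissue_masks(lab)
  build <- function(blob_idx) {
    s <- as.numeric(scale(rnorm(nt)))
    M <- matrix(rnorm(nx * nx * nt, sd = 1), nx * nx, nt)
    seed_vox <- cbind(3, 3)
    M[(3 - 1) * nx + 3, ] <- s
    for (v in blob_idx) M[v, ] <- s + rnorm(nt, sd = 0.1)
    list(series = array(M, c(nx, nx, 1, nt)), s = s)
  }
  # an 8-voxel blob dies under the 9-voxel rule; a 9-voxel blob survives
  blob8 <- as.vector(outer(7:10, (7:8 - 1) * nx, `+`)) # 4x2 block
  blob9 <- c(blob8, 11 + (7 - 1) * nx) # plus one attached voxel
  m8 <- seed_correlation_map(build(blob8)$series, c(3, 3, 1), masks,
                             threshold = 3.29, min_cluster = 9)
  surv8 <- which(m8$surviving)
  expect_false(any(blob8 %in% surv8))
  m9 <- seed_correlation_map(build(blob9)$series, c(3, 3, 1), masks,
                             threshold = 3.29, min_cluster = 9)
  expect_true(all(blob9 %in% which(m9$surviving)))

  # an infinite threshold clears the map
  m_inf <- seed_correlation_map(build(blob9)$series, c(3, 3, 1), masks,
                                threshold = Inf, min_cluster = 0)
  expect_false(any(m_inf$surviving))
  expect_error(seed_correlation_map(build(blob9)$series, c(1, 1, 1), masks),
               "outside")
})

test_that("ROI connectivity matrices are symmetric and recover planted correlations", {
  ph <- generate_phantom(tiny_config())
  sub <- erode_subregions(subdivide_quadrants(ph$masks, 1))
  sl <- array(ph$volume[, , 1, ], c(32, 32, 60))
  sc <- roi_connectivity(sl, sub)
  expect_equal(sc$z, t(sc$z))
  expect_equal(diag(sc$z), rep(0, 8), ignore_attr = TRUE)

  # identical ROI means hit the clamp ceiling
  flat <- sl
  base <- as.numeric(scale(rnorm(60)))
  M <- matrix(flat, 32 * 32, 60)
  for (k in c("lv_gm", "rv_gm")) M[which(sub$masks[[k]]), ] <-
    rep(base, each = sum(sub$masks[[k]]))
  stats <- correlation_stats(base, base)
  sc2 <- roi_connectivity(array(M, c(32, 32, 60)), sub)
  expect_equal(sc2$z["lv_gm", "rv_gm"], stats$z, tolerance = 1e-10)
  expect_gt(sc2$z["lv_gm", "rv_gm"], 10) # clamped but very large

  # Monte-Carlo recovery of a planted rho_vv = 0.6 with little noise
  rs <- replicate(120, {
    cfg <- phantom_config(grid = 32L, n_slices = 1L, n_volumes = 150L,
                          rho_vv = 0.6, sigma_thermal = 2,
                          cardiac_amp = c(gm = 0, wm = 0, csf = 0, notspine = 0),
                          resp_amp = c(gm = 0, wm = 0, csf = 0, notspine = 0),
                          csf_slow_amp = c(gm = 0, wm = 0, csf = 0, notspine = 0),
                          csf_slow2_amp = 0,
                          cord_global_amp = c(gm = 0, wm = 0, csf = 0, notspine = 0),
                          neck_slow_amp = c(0, 0), bulk_rate = 0,
                          motion_amp = 0, jump_prob = 0,
                          seed = sample.int(1e6, 1))
    ph2 <- generate_phantom(cfg)
    sub2 <- erode_subregions(subdivide_quadrants(ph2$masks, 1))
    sl2 <- array(ph2$volume[, , 1, ], c(32, 32, 150))
    roi_connectivity(sl2, sub2)$r["lv_gm", "rv_gm"]
  })
  expect_gt(mean(rs), 0.55)
  expect_lt(mean(rs), 0.65)

  empty <- sub
  empty$masks$lv_gm[] <- FALSE
  expect_error(roi_connectivity(sl, empty), "lv_gm")
})

test_that("the full z chain is calibrated on independent AR(1) pairs", {
  cal <- ar1_null_calibration(n_pairs = 2000, n = 150, phi = 0.5, seed = 42)
  expect_gt(cal$var, 0.85)
  expect_lt(cal$var, 1.15)
  expect_lt(abs(cal$mean), 0.05)
})
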