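as_slice <- function(M, nx, ny) array(t(M), c(nx, ny, nrow(M)))

test_that("PCA of masked voxels has the documented eigenstructure", {
  nt <- 40
  # rank-1: every voxel a scaled copy of one series
  base <- sin(seq_len(nt))
  gains <- runif(10, 0.5, 2)
  M <- outer(gains, base) # voxels x time
  sl <- array(M, c(5, 2, nt))
  p <- pca_components(sl, matrix(TRUE, 5, 2))
  expect_equal(p$values[1], 1, tolerance = 1e-12)

  # two orthogonal equal-power components split the variance evenly
  c1 <- cos(2 * pi * (1:nt) / 8)
  c2 <- sin(2 * pi * (1:nt) / 8)
  M2 <- rbind(outer(rep(1, 4), c1), outer(rep(1, 4), c2))
  p2 <- pca_components(array(M2, c(4, 2, nt)), matrix(TRUE, 4, 2))
  expect_equal(p2$values[1:2], c(0.5, 0.5), tolerance = 1e-10)

  # completeness: projecting onto all time eigenvectors reproduces the data
  set.seed(1)
  Y <- matrix(rnorm(10 * nt), 10, nt)
  p3 <- pca_components(array(Y, c(5, 2, nt)), matrix(TRUE, 5, 2))
  Yc <- Y - rowMeans(Y)
  U <- p3$vectors
  expect_lt(max(abs(Yc - (Yc %*% U) %*% t(U))), 1e-10)

  expect_error(pca_components(array(0, c(2, 2, nt)), matrix(TRUE, 2, 2)),
               "zero total variance")
  expect_error(pca_components(array(1, c(2, 2, nt)),
                              matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)),
               "at least 2")
})

test_that("component count follows the cumulative-variance and gap rules", {
  rule80 <- eig_selection_rule(cap = 0.80, gap = 0.02)
  expect_equal(select_k(c(0.50, 0.30, 0.10, 0.06, 0.04), rule80), 2)
  expect_equal(select_k(c(0.40, 0.39, 0.11, 0.10), rule80), 1) # gap 0.01
  expect_equal(select_k(1.0, rule80), 1)
  expect_equal(select_k(c(0.30, 0.25, 0.2, 0.15, 0.1),
                        eig_selection_rule(0.8, 0.02, max_k = 3)), 3)
  rel <- eig_selection_rule(0.99, 0.2, gap_rule = "relative")
  expect_equal(select_k(c(0.4, 0.3, 0.29, 0.01), rel), 2) # (0.3-0.29)/0.3 < 0.2
  expect_error(select_k(numeric(0), rule80), "empty")
})

test_that("RETROICOR phases and regressors behave as specified", {
  ph <- generate_phantom(tiny_config(n_slices = 2L))
  phys <- ph$physio

  # cardiac phase is 0 at a detected peak and pi midway between peaks
  pk <- spinecorr:::find_peaks(phys$cardiac,
                               min_dist = floor(0.25 * phys$rate),
                               min_height = min(phys$cardiac) +
                                 0.5 * diff(range(phys$cardiac)))
  pt <- phys$time[pk]
  expect_gt(length(pt), 10)
  expect_equal(spinecorr:::cardiac_phase(pt[3], pt), 0, tolerance = 1e-9)
  expect_equal(spinecorr:::cardiac_phase((pt[3] + pt[4]) / 2, pt), pi,
               tolerance = 0.05)

  retro <- retroicor_regressors(phys, 1, order = 2)
  expect_equal(ncol(retro), 8)
  expect_true(all(grepl("^retroicor-", colnames(retro))))

  # a pure cardiac-phase Fourier series is removed almost entirely
  phi <- spinecorr:::cardiac_phase(phys$acq_times[1, ], pt)
  target <- 0.7 * cos(phi) + 0.2 * sin(2 * phi)
  sl <- array(rep(target, each = 4), c(2, 2, length(target)))
  clean <- regress_out(sl, retro)
  expect_lt(var(clean[1, 1, ]) / var(target), 0.01)

  short <- physio_record(time = c(0, 0.02), cardiac = c(0, 1), resp = c(0, 1),
                         acq_times = matrix(0.01, 1, 1), rate = 50)
  expect_error(retroicor_regressors(short, 1), "cardiac peaks")
})

test_that("the white-matter eigenvector tracks the dominant shared series", {
  nt <- 60
  ph <- generate_phantom(tiny_config())
  masks <- ph$masks
  base <- bandpass(cumsum(rnorm(nt)), filter_spec(tr = 3.6))
  nx <- dim(masks$labels)[1]
  M <- matrix(rnorm(nx * nx * nt, sd = 1e-3), nx * nx, nt)
  wm_idx <- which(mask_slice(masks, 1, "wm"))
  M[wm_idx, ] <- M[wm_idx, ] + outer(runif(length(wm_idx), 0.5, 2), base)
  sl <- array(M, c(nx, nx, nt))
  for (variant in c("wm", "wm+gm", "wm-eroded")) {
    w <- wm_eigenvector(sl, masks, 1, variant)
    expect_gte(w$var_fraction, 0)
    expect_lte(w$var_fraction, 1)
    expect_gt(abs(cor(w$vector, base)), 0.99)
  }
  # variants agree when white matter dominates the combined mask
  w1 <- wm_eigenvector(sl, masks, 1, "wm")
  w2 <- wm_eigenvector(sl, masks, 1, "wm+gm")
  expect_gt(abs(cor(w1$vector, w2$vector)), 0.9)
})

test_that("nuisance regression removes exactly the fitted span", {
  nt <- 50
  set.seed(3)
  x <- rnorm(nt)
  sl <- array(rep(x, each = 4), c(2, 2, nt))
  rs <- rs_add(regressor_set(nt), x, "self")
  clean <- regress_out(sl, rs)
  expect_lt(var(clean[1, 1, ]), 1e-20) # residual of self-regression is flat
  expect_equal(mean(clean[1, 1, ]), mean(x), tolerance = 1e-10) # mean re-added

  # an orthogonal regressor leaves the series untouched
  y <- rnorm(nt)
  y <- y - mean(y)
  ortho <- x - mean(x)
  ortho <- ortho - sum(ortho * y) / sum(y * y) * y
  sly <- array(rep(y, each = 4), c(2, 2, nt))
  cleany <- regress_out(sly, rs_add(regressor_set(nt), ortho, "orth"))
  expect_equal(var(cleany[1, 1, ]), var(y), tolerance = 1e-10)

  # residuals are orthogonal to every design column
  Z <- cbind(rnorm(nt), rnorm(nt), rnorm(nt))
  noisy <- array(rnorm(4 * nt), c(2, 2, nt))
  rs2 <- rs_add(regressor_set(nt), Z, c("a", "b", "c"))
  res <- regress_out(noisy, rs2)
  for (k in seq_len(ncol(Z))) {
    v <- res[1, 2, ] - mean(res[1, 2, ])
    expect_lt(abs(sum(v * Z[, k])), 1e-8 * sqrt(sum(v^2) * sum(Z[, k]^2)))
  }

  dup <- rs_add(rs_add(regressor_set(nt), x, "a"), x + 0, "b")
  expect_error(regress_out(noisy, dup), "collinear")
  expect_error(rs_add(rs_add(regressor_set(nt), x, "a"), y, "a"), "duplicate")
})

test_that("not-spine regression removes shared bulk events from the cord", {
  cfg <- phantom_config(grid = 48L, n_slices = 1L, n_volumes = 80L, seed = 9L,
                        bulk_rate = 6, bulk_amp = 0.12,
                        motion_amp = 0, jump_prob = 0)
  ph <- generate_phantom(cfg)
  expect_true(any(ph$truth$bulk > 0)) # this seed draws bulk events
  sl <- array(ph$volume[, , 1, ], c(48, 48, 80))
  notspine <- make_not_spine_mask(ph$masks, 1)
  p <- pca_components(sl, notspine)
  k <- select_k(p$values, eig_selection_rule(0.8, 0.02))
  rs <- rs_add(regressor_set(80), p$vectors[, seq_len(k), drop = FALSE],
               paste0("ns", seq_len(k)))
  clean <- regress_out(sl, rs)
  cord_idx <- which(mask_slice(ph$masks, 1, "cord"))
  bulk <- ph$truth$bulk - mean(ph$truth$bulk)
  energy <- function(arr) {
    M <- matrix(arr, 48 * 48, 80)[cord_idx, ]
    Mc <- M - rowMeans(M)
    sum((Mc %*% bulk)^2) / sum(bulk^2)
  }
  expect_lt(energy(clean), 0.1 * energy(sl))
})
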