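test_that("configuration invariants are enforced", {
  expect_error(phantom_config(n_volumes = 10), "at least 20")
  expect_error(phantom_config(tr = 0), "positive")
  expect_error(phantom_config(rho_vv = 1.2), "\\[0, 1\\]")
  expect_error(phantom_config(sigma_thermal = -1), "non-negative")
  expect_error(phantom_config(grid = 8), "at least 16")
})

test_that("identical seeds give bit-identical phantoms", {
  a <- generate_phantom(tiny_config(seed = 5L))
  b <- generate_phantom(tiny_config(seed = 5L))
  expect_identical(a$volume, b$volume)
  expect_identical(a$masks$labels, b$masks$labels)
  expect_identical(a$physio$cardiac, b$physio$cardiac)
  expect_identical(a$truth$translations, b$truth$translations)
  c <- generate_phantom(tiny_config(seed = 6L))
  expect_false(identical(a$volume, c$volume))
})

test_that("planted horn correlations are exact in the noiseless construction", {
  # full shared signal: left and right ventral series coincide
  cfg1 <- tiny_config(rho_vv = 1)
  s1 <- spinecorr:::plant_signals(cfg1)
  expect_equal(cor(s1$horns[, "lv"], s1$horns[, "rv"]), 1, tolerance = 1e-12)

  # planted rho = 0.6: the sample correlation is exact by construction
  rs6 <- replicate(200, {
    s <- spinecorr:::plant_signals(tiny_config(rho_vv = 0.6))
    cor(s$horns[, "lv"], s$horns[, "rv"])
  })
  expect_true(mean(rs6) > 0.55 && mean(rs6) < 0.65)
  expect_lt(max(abs(rs6 - 0.6)), 1e-10)

  # planted rho = 0: independent draws sit at chance level under the
  # Fisher null for band-limited series (effective dof = twice the number
  # of in-band frequency bins)
  cfg0 <- tiny_config(rho_vv = 0)
  df <- 1 / (cfg0$n_volumes * cfg0$tr)
  m_bins <- sum({
    f <- seq_len(floor(cfg0$n_volumes / 2) - 1L) * df
    f >= cfg0$signal_band[1] - 1e-12 & f <= cfg0$signal_band[2] + 1e-12
  })
  bound <- tanh(qnorm(0.975) / sqrt(2 * m_bins - 3))
  rs0 <- replicate(500, {
    s <- spinecorr:::plant_signals(cfg0)
    cor(s$horns[, "lv"], s$horns[, "rv"])
  })
  expect_gte(mean(abs(rs0) < bound), 0.92)
  expect_lt(abs(mean(rs0)), 0.05)
})

test_that("ground truth reproduces the planted correlations", {
  ph <- generate_phantom(tiny_config(rho_vv = 0.5, rho_dd = 0.35,
                                     rho_vd = 0.2))
  got <- cor(ph$truth$horn_series)
  # planted (nonzero) pairs are exact by construction
  expect_equal(got["lv", "rv"], 0.5, tolerance = 1e-12)
  expect_equal(got["ld", "rd"], 0.35, tolerance = 1e-12)
  expect_equal(cor(ph$truth$shared_ventral, ph$truth$shared_dorsal), 0.2,
               tolerance = 1e-12)
  # cross-pair entries carry the population value plus chance variation
  cross <- sqrt(0.5 * 0.35) * 0.2
  expect_equal(ph$truth$planted_rho["lv", "ld"], cross, tolerance = 1e-12)
  expect_lt(abs(got["lv", "ld"] - cross), 0.5)

  # unplanted pairs sit at chance level, not exactly zero
  ph0 <- generate_phantom(tiny_config(rho_vv = 0, rho_dd = 0, seed = 8L))
  g0 <- cor(ph0$truth$horn_series)
  expect_lt(abs(g0["lv", "rv"]), 0.4)
})

test_that("planted neural power is confined to the signal band", {
  cfg <- tiny_config()
  s <- spinecorr:::plant_signals(cfg)
  p <- periodogram(s$horns[, "lv"], cfg$tr)
  in_band <- p$freq >= cfg$signal_band[1] - 1e-9 &
    p$freq <= cfg$signal_band[2] + 1e-9
  expect_gt(sum(p$power[in_band]) / sum(p$power), 0.95)
})

test_that("CSF voxels are noisier than WM voxels when CSF confounds dominate", {
  ph <- generate_phantom(phantom_config(grid = 48L, n_slices = 1L,
                                        n_volumes = 80L, seed = 3L))
  M <- matrix(ph$volume[, , 1, ], 48 * 48, 80)
  v_csf <- median(apply(M[which(mask_slice(ph$masks, 1, "csf")), ], 1, var))
  v_wm <- median(apply(M[which(mask_slice(ph$masks, 1, "wm")), ], 1, var))
  expect_gt(v_csf, v_wm)
})

test_that("render_motion shifts content by the planted translations", {
  ph <- generate_phantom(tiny_config(motion_amp = 0, jump_prob = 0))
  expect_identical(render_motion(ph$volume, ph$truth), ph$volume)

  # integer displacement moves voxel content exactly
  tr <- ph$truth
  tr$translations[1, , ] <- 0
  tr$translations[1, 2, ] <- c(2, 1)
  moved <- render_motion(ph$volume, tr)
  expect_equal(moved[10 + 2, 12 + 1, 1, 2], ph$volume[10, 12, 1, 2],
               tolerance = 1e-9)
  expect_equal(moved[, , 1, 1], ph$volume[, , 1, 1]) # untouched volume

  # half-voxel round trip on a smooth image returns the original within
  # interpolation error (the shift interpolant is band-limited; images
  # with appreciable Nyquist energy lose it to the real-output convention)
  xg <- outer(1:32, rep(1, 32))
  img <- exp(-((xg - 16)^2 + (t(xg) - 18)^2) / 12)
  back <- spinecorr:::cpp_fourier_shift(
    spinecorr:::cpp_fourier_shift(img, 0.5, 0), -0.5, 0)
  expect_lt(max(abs(back - img)), 1e-6 * diff(range(img)))

  tr$translations[1, 2, ] <- c(20, 0) # more than a quarter of the grid
  expect_error(render_motion(ph$volume, tr), "quarter")
})

test_that("physio files round-trip exactly and have rate x duration rows", {
  ph <- generate_phantom(tiny_config())
  path <- tempfile(fileext = ".tsv")
  write_physio(ph$physio, path)
  back <- read_physio(path)
  expect_identical(back$time, ph$physio$time)
  expect_identical(back$cardiac, ph$physio$cardiac)
  expect_identical(back$resp, ph$physio$resp)

  # 50 Hz over 540 s
  rec <- physio_record(time = seq(0, by = 1 / 50, length.out = 50 * 540),
                       cardiac = rnorm(27000), resp = rnorm(27000))
  write_physio(rec, path)
  expect_equal(nrow(read.delim(path)), 27000)

  empty <- physio_record(numeric(0), numeric(0), numeric(0))
  write_physio(empty, path)
  expect_identical(readLines(path), "time\tcardiac\tresp")

  expect_error(physio_record(1:3, 1:2, 1:3), "one sample per")
})
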