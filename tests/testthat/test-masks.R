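# helper: tissue_masks with a centred circular geometry drawn by hand
circle_masks <- function(n = 41, r_gm = 3, r_wm = 8, r_csf = 12) {
  c0 <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (x - c0)^2 + (y - c0)^2
  lab <- matrix(0L, n, n)
  lab[d2 <= r_csf^2] <- 3L
  lab[d2 <= r_wm^2] <- 2L
  lab[d2 <= r_gm^2] <- 1L
  tissue_masks(array(lab, dim = c(n, n, 1)))
}

test_that("weight kernel peaks at the cord centroid with FWHM at the CSF extent", {
  masks <- circle_masks()
  k <- make_weight_kernel(masks, 1)
  ctr <- k$center
  expect_equal(unname(k$weights[ctr[1], ctr[2]]), 1, tolerance = 1e-12)

  # at the CSF boundary along each axis the kernel is at half maximum
  csf <- mask_slice(masks, 1, "csf")
  xr <- range(which(apply(csf, 1, any)))
  expect_equal(k$weights[xr[1], ctr[2]], 0.5, tolerance = 0.02)
  expect_equal(k$weights[xr[2], ctr[2]], 0.5, tolerance = 0.02)

  # circular CSF: isotropic kernel, sigma = fwhm / 2.3548
  expect_equal(unname(k$sigma[1]), unname(k$sigma[2]))
  expect_equal(unname(k$sigma[1]), unname(k$fwhm[1]) / (2 * sqrt(2 * log(2))))

  empty_csf <- circle_masks()
  empty_csf$labels[empty_csf$labels == 3L] <- 0L
  expect_error(make_weight_kernel(empty_csf, 1), "CSF")
})

test_that("not-spine mask excludes the dilated spine region", {
  ph <- generate_phantom(tiny_config(grid = 64L, n_volumes = 20L))
  ns <- make_not_spine_mask(ph$masks, 1)
  expect_false(any(ns & mask_slice(ph$masks, 1, "spine")))
  # the phantom's neck tissue lies inside the not-spine mask
  neck <- mask_slice(ph$masks, 1, "notspine")
  expect_true(all(ns[neck]))

  # degenerate: cord filling the whole slice leaves nothing outside
  all_cord <- tissue_masks(array(2L, dim = c(8, 8, 1)))
  expect_false(any(make_not_spine_mask(all_cord, 1)))
})

test_that("quadrant subdivision respects symmetry and the central-band rule", {
  ph <- generate_phantom(tiny_config(grid = 64L))
  sub <- subdivide_quadrants(ph$masks, 1)
  sizes <- sapply(sub$masks, sum)
  expect_equal(sizes[["lv_gm"]], sizes[["rv_gm"]])
  expect_equal(sizes[["ld_gm"]], sizes[["rd_gm"]])
  expect_equal(sizes[["lv_wm"]], sizes[["rv_wm"]])

  gm <- mask_slice(ph$masks, 1, "gm")
  wm <- mask_slice(ph$masks, 1, "wm")
  # WM quadrants partition WM
  wm_union <- Reduce(`|`, sub$masks[c("lv_wm", "rv_wm", "ld_wm", "rd_wm")])
  expect_identical(wm_union, wm)
  expect_equal(sum(sapply(sub$masks[5:8], sum)), sum(wm))
  # GM quadrants are pairwise disjoint and within GM
  gm_sum <- Reduce(`+`, lapply(sub$masks[1:4], function(m) m * 1L))
  expect_true(all(gm_sum <= 1))
  expect_true(all(gm[Reduce(`|`, sub$masks[1:4])]))

  # with no central band the GM quadrants partition GM exactly
  sub0 <- subdivide_quadrants(ph$masks, 1, central_halfwidth = 0)
  expect_equal(sum(sapply(sub0$masks[1:4], sum)), sum(gm))

  # equivariance under left-right mirroring of an asymmetric input
  asym <- ph$masks
  gm_idx <- which(asym$labels[, , 1] == 1L, arr.ind = TRUE)
  drop <- gm_idx[gm_idx[, 1] > 40, , drop = FALSE] # notch one side
  asym$labels[cbind(drop, 1L)] <- 2L
  sub_a <- subdivide_quadrants(asym, 1)
  mirr <- asym
  mirr$labels <- mirr$labels[dim(mirr$labels)[1]:1, , , drop = FALSE]
  sub_m <- subdivide_quadrants(mirr, 1)
  expect_identical(sub_m$masks$lv_gm[64:1, ], sub_a$masks$rv_gm)
  expect_identical(sub_m$masks$rd_gm[64:1, ], sub_a$masks$ld_gm)
})

test_that("checkerboard quadrants are recovered exactly", {
  # four separated blobs, one per quadrant, on a synthetic label map
  n <- 20
  lab <- matrix(0L, n, n)
  lab[4:8, 4:8] <- 1L     # right-ventral (low x, low y)
  lab[13:17, 4:8] <- 1L   # left-ventral
  lab[4:8, 13:17] <- 1L   # right-dorsal
  lab[13:17, 13:17] <- 1L # left-dorsal
  lab[9:12, 9:12] <- 2L   # central WM keeps the centroid in the middle
  masks <- tissue_masks(array(lab, dim = c(n, n, 1)))
  sub <- subdivide_quadrants(masks, 1, central_halfwidth = 0)
  expect_identical(which(sub$masks$rv_gm), which(lab == 1L &
    row(lab) <= 8 & col(lab) <= 8))
  expect_identical(which(sub$masks$lv_gm), which(lab == 1L &
    row(lab) >= 13 & col(lab) <= 8))
  expect_identical(which(sub$masks$ld_gm), which(lab == 1L &
    row(lab) >= 13 & col(lab) >= 13))
})

test_that("disk erosion matches the brute-force oracle", {
  # worked examples
  solid <- matrix(FALSE, 9, 9)
  d2 <- (row(solid) - 5)^2 + (col(solid) - 5)^2
  solid[d2 <= 3^2] <- TRUE # discrete disk of radius 3
  e <- erode_subregion(solid, 3)
  expect_equal(e$radius, 3)
  expect_identical(which(e$mask), which(d2 == 0))

  sq <- matrix(FALSE, 7, 7)
  sq[3:5, 3:5] <- TRUE
  e2 <- erode_subregion(sq, 3) # too large: falls back
  expect_equal(e2$radius, 1)
  expect_identical(which(e2$mask), which(row(sq) == 4 & col(sq) == 4))

  e0 <- erode_subregion(sq, 0)
  expect_identical(e0$mask, sq)
  expect_error(erode_subregion(matrix(FALSE, 3, 3), 1), "empty")

  # exhaustive over all non-empty 3x3 masks, radii 1 and 2
  for (code in 1:511) {
    m3 <- matrix(as.logical(intToBits(code)[1:9]), 3, 3)
    for (r in 1:2) {
      oracle <- erode_oracle(m3, r)
      got <- erode_subregion(m3, r)
      if (any(oracle)) {
        expect_equal(got$radius, r)
        expect_identical(got$mask, oracle)
      } else {
        expect_lt(got$radius, r) # fallback engaged
        expect_true(any(got$mask))
      }
    }
  }

  # random larger masks
  set.seed(42)
  for (i in 1:60) {
    m12 <- matrix(runif(144) < 0.6, 12, 12)
    if (!any(m12)) next
    r <- sample(1:3, 1)
    oracle <- erode_oracle(m12, r)
    got <- erode_subregion(m12, r)
    if (any(oracle)) expect_identical(got$mask, oracle)
  }
})

test_that("erosion is anti-extensive and monotone in the radius", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(runif(100) < 0.7, 10, 10)
    if (!any(m)) next
    prev <- m
    for (r in 1:3) {
      e <- erode_subregion(m, r)
      expect_true(all(m[e$mask]))          # subset of the input
      if (e$radius == r) {
        expect_true(all(prev[e$mask]))     # nested under smaller radius
        prev <- e$mask
      }
      expect_true(any(e$mask))             # fallback never empties
    }
  }
})
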