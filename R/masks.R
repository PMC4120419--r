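# Mask handling: cord-centred Gaussian weighting kernels, the not-spine
# mask, quadrant subdivision of gray/white matter into left/right
# ventral/dorsal sub-regions, and morphological erosion by a discrete disk
# with automatic radius fallback.
#
# Coordinate convention: 1-based voxel indices; axis 1 runs right -> left,
# axis 2 runs ventral -> dorsal.

FWHM_SIGMA <- 2 * sqrt(2 * log(2)) # FWHM = 2.3548 sigma for a Gaussian

#' Cord-centred Gaussian weighting kernel
#'
#' Builds the per-slice anisotropic 2-D Gaussian weight map used by the
#' motion and registration stages: peak 1 at the cord (GM union WM)
#' centroid, with the full-width-at-half-maximum along each in-plane axis
#' set at the CSF boundaries (the bounding extent of the CSF mask along
#' that axis).
#'
#' @param masks a [tissue_masks()] object.
#' @param slice slice index.
#' @return a list of class `weight_kernel`: `weights` (matrix in \[0, 1\]),
#'   `center` (centroid, voxels), `fwhm` (per-axis, voxels).
#' @export
make_weight_kernel <- function(masks, slice) {
  csf <- mask_slice(masks, slice, "csf")
  if (!any(csf)) stopf("empty CSF mask on slice %d", slice)
  cord <- mask_slice(masks, slice, "cord")
  idx <- which(cord, arr.ind = TRUE)
  if (!nrow(idx)) stopf("empty cord mask on slice %d", slice)
  ctr <- colMeans(idx)
  csf_idx <- which(csf, arr.ind = TRUE)
  # FWHM = distance between the outermost CSF voxel centres per axis
  fwhm <- c(diff(range(csf_idx[, 1])), diff(range(csf_idx[, 2])))
  sig <- fwhm / FWHM_SIGMA
  nx <- nrow(csf)
  ny <- ncol(csf)
  wx <- exp(-(seq_len(nx) - ctr[1])^2 / (2 * sig[1]^2))
  wy <- exp(-(seq_len(ny) - ctr[2])^2 / (2 * sig[2]^2))
  structure(list(weights = outer(wx, wy), center = ctr, fwhm = fwhm,
                 sigma = sig), class = "weight_kernel")
}

#' Not-spine mask
#'
#' Complement, within the imaged slice, of the dilated spine region (cord
#' plus CSF): everything safely outside the spinal canal, used to harvest
#' nuisance regressors that affect cord and neck tissue alike.
#'
#' @param masks a [tissue_masks()] object.
#' @param slice slice index.
#' @param dilate dilation radius (voxels) applied to the spine region
#'   before inverting, to keep partial-volume voxels out.
#' @return logical matrix.
#' @export
make_not_spine_mask <- function(masks, slice, dilate = 3) {
  spine <- mask_slice(masks, slice, "spine")
  if (!any(spine)) return(!spine & TRUE)
  if (dilate > 0) spine <- dilate_disk(spine, dilate)
  !spine
}

#' Sub-region masks container
#'
#' Eight per-slice binary masks: gray matter left-ventral (LV), right-
#' ventral (RV), left-dorsal (LD) and right-dorsal (RD) quadrants, and the
#' same four quadrants of white matter, with the erosion radius actually
#' applied to each.
#'
#' @param masks named list of eight logical matrices (names
#'   `lv_gm ... rd_wm`).
#' @param radius named numeric vector of erosion radii used (NA before
#'   erosion).
#' @param slice slice index.
#' @return an object of class `subregion_masks`.
#' @export
subregion_masks <- function(masks, radius, slice) {
  nm <- subregion_names()
  if (!identical(sort(names(masks)), sort(nm))) {
    stopf("sub-region masks must be named %s", paste(nm, collapse = ", "))
  }
  structure(list(masks = masks[nm], radius = radius[nm], slice = slice),
            class = "subregion_masks")
}

#' Canonical sub-region order
#'
#' Gray-matter quadrants first, then white matter: LV, RV, LD, RD within
#' each tissue. This is the row/column order of every connectivity matrix.
#' @return character vector of length 8.
#' @export
subregion_names <- function() {
  c("lv_gm", "rv_gm", "ld_gm", "rd_gm", "lv_wm", "rv_wm", "ld_wm", "rd_wm")
}

#' Subdivide gray and white matter into quadrant sub-regions
#'
#' Quadrants are defined by the left-right and ventral-dorsal axes through
#' the cord (GM union WM) centroid. Gray-matter voxels within
#' `central_halfwidth` voxels of the midline (the left-right dividing axis)
#' are excluded, so the central gray matter connecting the two sides
#' belongs to no quadrant; white-matter quadrants partition white matter.
#'
#' @param masks a [tissue_masks()] object.
#' @param slice slice index.
#' @param central_halfwidth half-width (voxels) of the excluded central
#'   gray-matter band.
#' @return a `subregion_masks` object (pre-erosion, `radius` all NA).
#' @export
subdivide_quadrants <- function(masks, slice, central_halfwidth = 2) {
  gm <- mask_slice(masks, slice, "gm")
  wm <- mask_slice(masks, slice, "wm")
  if (!any(gm) || !any(wm)) stopf("GM and WM masks must be non-empty (slice %d)", slice)
  cord_idx <- which(gm | wm, arr.ind = TRUE)
  cx <- mean(cord_idx[, 1])
  cy <- mean(cord_idx[, 2])
  nx <- nrow(gm)
  ny <- ncol(gm)
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  left <- x > cx
  right <- !left
  ventral <- y < cy
  dorsal <- !ventral
  central <- abs(x - cx) <= central_halfwidth
  gm_q <- gm & !central
  if (any(gm) && !any(gm_q)) {
    stopf("slice %d: all gray matter falls in the excluded central band", slice)
  }
  out <- list(
    lv_gm = gm_q & left & ventral, rv_gm = gm_q & right & ventral,
    ld_gm = gm_q & left & dorsal, rd_gm = gm_q & right & dorsal,
    lv_wm = wm & left & ventral, rv_wm = wm & right & ventral,
    ld_wm = wm & left & dorsal, rd_wm = wm & right & dorsal
  )
  subregion_masks(out, stats::setNames(rep(NA_real_, 8), names(out)), slice)
}

# binary dilation by a discrete disk via shifted unions (border-safe)
dilate_disk <- function(mask, radius) {
  off <- disk_offsets(radius)
  nx <- nrow(mask)
  ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(off))) {
    i <- off$i[k]
    j <- off$j[k]
    xs <- max(1, 1 + i):min(nx, nx + i)
    ys <- max(1, 1 + j):min(ny, ny + j)
    out[xs, ys] <- out[xs, ys] | mask[xs - i, ys - j]
  }
  out
}

# discrete Euclidean disk: offsets (i, j) with i^2 + j^2 <= r^2
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(i = -r:r, j = -r:r)
  g[g$i^2 + g$j^2 <= radius^2, , drop = FALSE]
}

#' Erode a binary mask by a discrete disk, with radius fallback
#'
#' Binary erosion with the discrete Euclidean disk
#' `{(i, j): i^2 + j^2 <= r^2}`; pixels beyond the image border count as
#' background. If the eroded mask is empty the radius is decremented by 1
#' and the erosion retried, down to radius 0 (the identity), so a non-empty
#' input always yields a non-empty result.
#'
#' Implementation: a voxel survives erosion at radius r iff its squared
#' Euclidean distance to the nearest background voxel exceeds r^2, so one
#' exact distance transform answers every radius at once.
#'
#' @param mask logical matrix.
#' @param radius requested disk radius (voxels), non-negative.
#' @return list with `mask` (eroded logical matrix) and `radius` (the
#'   radius actually used).
#' @export
erode_subregion <- function(mask, radius) {
  if (!any(mask)) stopf("cannot erode an empty mask")
  if (radius < 0) stopf("radius must be non-negative")
  radius <- floor(radius)
  if (radius == 0) return(list(mask = mask, radius = 0))
  d2 <- edt_sq(mask)
  r <- radius
  while (r > 0 && !any(d2 > r^2)) r <- r - 1L
  if (r == 0) return(list(mask = mask, radius = 0))
  list(mask = mask & d2 > r^2, radius = r)
}

#' Erode all eight sub-region masks
#'
#' Applies [erode_subregion()] with the gray-matter radius to the four GM
#' quadrants and the white-matter radius to the four WM quadrants,
#' recording the radius actually used for each (the fallback may reduce
#' it).
#'
#' @param sub a `subregion_masks` object from [subdivide_quadrants()].
#' @param gm_radius disk radius (voxels) for gray-matter sub-regions.
#' @param wm_radius disk radius (voxels) for white-matter sub-regions.
#' @return an eroded `subregion_masks` object.
#' @export
erode_subregions <- function(sub, gm_radius = 3, wm_radius = 11) {
  nm <- subregion_names()
  out <- sub$masks
  used <- sub$radius
  for (k in nm) {
    r <- if (grepl("_gm$", k)) gm_radius else wm_radius
    e <- erode_subregion(sub$masks[[k]], r)
    out[[k]] <- e$mask
    used[[k]] <- e$radius
  }
  subregion_masks(out, used, sub$slice)
}
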