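# File interfaces: NIfTI-1 volumes and label maps, TSV exports for motion
# traces, regressor sets, connectivity matrices and group matrices, and a
# JSON ground-truth dump.

#' Write a 4-D volume (or 3-D map) as NIfTI-1
#'
#' @param volume numeric array; attribute `voxel_mm` (or the argument)
#'   supplies the voxel dimensions, `tr` the repetition time.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel dimensions in mm.
#' @param tr repetition time (s), stored in the time pixdim.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path,
                               voxel_mm = attr(volume, "voxel_mm"),
                               tr = attr(volume, "tr")) {
  voxel_mm <- voxel_mm %||% c(1, 1, 1)
  pix <- c(voxel_mm, if (length(dim(volume)) == 4L) tr %||% 1)
  arr <- array(as.numeric(volume), dim = dim(volume))
  attr(arr, "pixdim") <- pix
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return numeric array with `voxel_mm` and (for 4-D) `tr` attributes.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pd <- RNifti::pixdim(img)
  attr(arr, "voxel_mm") <- pd[seq_len(min(3L, length(pd)))]
  if (length(dim(arr)) == 4L && length(pd) >= 4L) attr(arr, "tr") <- pd[4]
  arr
}

#' Write tissue masks as an integer label NIfTI
#'
#' Codes: 0 background, 1 gray matter, 2 white matter, 3 CSF, 4 not-spine.
#' @param masks a [tissue_masks()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_masks_nifti <- function(masks, path) {
  lab <- masks$labels
  attr(lab, "pixdim") <- masks$voxel_mm
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), path)
  invisible(path)
}

#' Read tissue masks from a label NIfTI
#'
#' @param path NIfTI label map (codes 0-4).
#' @return a [tissue_masks()] object.
#' @export
read_masks_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 2L) dm <- c(dm, 1L) # single-slice maps drop the 3rd dim
  lab <- array(as.integer(img), dim = dm)
  tissue_masks(lab, voxel_mm = RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))])
}

#' Write eroded sub-region masks as an 8-label NIfTI
#'
#' Labels follow [subregion_names()] order (1 = lv_gm ... 8 = rd_wm).
#' @param subs list of `subregion_masks` (one per slice).
#' @param path output path.
#' @param voxel_mm voxel dimensions.
#' @return the path, invisibly.
#' @export
write_subregions_nifti <- function(subs, path, voxel_mm = c(0.31, 0.31, 4)) {
  nm <- subregion_names()
  dm <- dim(subs[[1]]$masks[[1]])
  lab <- array(0L, dim = c(dm, length(subs)))
  for (s in seq_along(subs)) {
    plane <- matrix(0L, dm[1], dm[2])
    for (k in seq_along(nm)) plane[subs[[s]]$masks[[nm[k]]]] <- k
    lab[, , s] <- plane
  }
  attr(lab, "pixdim") <- voxel_mm
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), path)
  invisible(path)
}

#' Export motion traces as TSV
#'
#' Columns: slice, volume, dx_raw, dy_raw, dx_filt, dy_filt.
#' @param motion the `motion` element of a `preprocessed_run`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_motion_tsv <- function(motion, path) {
  rows <- lapply(seq_along(motion), function(s) {
    m <- motion[[s]]
    if (is.null(m)) return(NULL)
    data.frame(slice = s, volume = seq_len(nrow(m$trace_raw)),
               dx_raw = m$trace_raw[, 1], dy_raw = m$trace_raw[, 2],
               dx_filt = m$trace_filtered[, 1], dy_filt = m$trace_filtered[, 2])
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a per-slice connectivity stack as long-format TSV
#'
#' Columns: slice, roi_a, roi_b, z (upper triangle only).
#' @param zs array `[8, 8, n_slices]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_connectivity_tsv <- function(zs, path) {
  nm <- dimnames(zs)[[1]] %||% subregion_names()
  rows <- list()
  for (s in seq_len(dim(zs)[3])) {
    for (i in 1:7) {
      for (j in (i + 1):8) {
        rows[[length(rows) + 1L]] <- data.frame(
          slice = s, roi_a = nm[i], roi_b = nm[j], z = zs[i, j, s])
      }
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write / read a group matrix (8 x 8 x n subjects) as long-format TSV
#'
#' The plain-text exchange format for per-subject median z matrices:
#' columns subject, roi_a, roi_b, z, one row per ordered pair (the reader
#' symmetrises and zeroes the diagonal). An 8 x 8 x n matrix exported from
#' other tooling in this layout can be fed straight to [group_pipeline()].
#'
#' @param group array `[8, 8, n_subjects]`.
#' @param path file path.
#' @return `write_group_matrix`: the path, invisibly;
#'   `read_group_matrix`: the array.
#' @export
write_group_matrix <- function(group, path) {
  nm <- dimnames(group)[[1]] %||% subregion_names()
  rows <- list()
  for (s in seq_len(dim(group)[3])) {
    for (i in 1:7) {
      for (j in (i + 1):8) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, roi_a = nm[i], roi_b = nm[j], z = group[i, j, s])
      }
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_group_matrix
#' @export
read_group_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE)
  nm <- subregion_names()
  subs <- sort(unique(df$subject))
  group <- array(0, dim = c(8, 8, length(subs)), dimnames = list(nm, nm, NULL))
  for (r in seq_len(nrow(df))) {
    i <- match(df$roi_a[r], nm)
    j <- match(df$roi_b[r], nm)
    s <- match(df$subject[r], subs)
    group[i, j, s] <- group[j, i, s] <- df$z[r]
  }
  group
}

#' Write phantom ground truth as JSON
#'
#' Stores the planted correlation matrix, component time courses,
#' translation traces and the generating configuration.
#'
#' @param truth a `phantom_truth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    planted_rho = truth$planted_rho,
    horn_series = truth$horn_series,
    shared_ventral = truth$shared_ventral,
    shared_dorsal = truth$shared_dorsal,
    csf_slow = truth$csf_slow,
    cord_global = truth$cord_global,
    bulk = truth$bulk,
    translations = truth$translations,
    config = unclass(truth$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
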