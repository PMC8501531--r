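## Volume and dataset I/O: NIfTI (.nii.gz) with voxel-spacing metadata via
## RNifti, and a directory layout pairing each case's label, encoded-ROI
## and dose volumes with an index table.

#' Write a volume to NIfTI
#'
#' @param vol a [VoxelVolume-class] (labels, codes or dose).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "VoxelVolume"))
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param what one of `"dose"`, `"labels"`, `"encoded"`; selects the
#'   returned class.
#' @return A [DoseVolume-class], [LabelVolume-class] or
#'   [EncodedVolume-class] with spacing from the file header.
#' @export
readVolume <- function(path, what = c("dose", "labels", "encoded")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  switch(what,
         dose = DoseVolume(arr, sp),
         labels = LabelVolume(array(as.integer(round(arr)), dim(arr)), sp),
         encoded = EncodedVolume(arr, sp))
}

#' Write a phantom dataset to a directory
#'
#' Stores, per case, the label, encoded-ROI and dose (cGy) volumes as
#' `.nii.gz` plus an `index.csv` with case ids and spacing.
#'
#' @param dataset list of cases from [generateDataset()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(dataset, function(cs) {
    writeVolume(cs$labels, file.path(dir, paste0(cs$id, "_labels.nii.gz")))
    writeVolume(cs$encoded, file.path(dir, paste0(cs$id, "_roi.nii.gz")))
    writeVolume(cs$dose, file.path(dir, paste0(cs$id, "_dose.nii.gz")))
    data.frame(id = cs$id,
               spacingZ = cs$labels@spacing[1],
               spacingY = cs$labels@spacing[2],
               spacingX = cs$labels@spacing[3])
  }))
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phantom dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param doseNorm normalization constant in cGy used to rebuild the
#'   `doseNorm` arrays (default 6000).
#' @return list of cases as produced by [generateDataset()].
#' @export
readDataset <- function(dir, doseNorm = 6000) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    id <- idx$id[i]
    labels <- readVolume(file.path(dir, paste0(id, "_labels.nii.gz")),
                         "labels")
    encoded <- readVolume(file.path(dir, paste0(id, "_roi.nii.gz")),
                          "encoded")
    dose <- readVolume(file.path(dir, paste0(id, "_dose.nii.gz")), "dose")
    list(id = id, labels = labels, encoded = encoded, dose = dose,
         doseNorm = dose@voxels / doseNorm)
  })
}

#' Resample a volume to a new grid
#'
#' Mirrors the preprocessing convention of clinical pipelines: the axial
#' axis is center-cropped (or zero-padded) to the requested slice count and
#' each slice is resampled in-plane -- bilinearly for continuous volumes,
#' nearest-neighbour for labels. Spacing metadata is rescaled accordingly.
#'
#' @param vol a [VoxelVolume-class].
#' @param slices target number of axial slices.
#' @param inplane target in-plane extents, length 2.
#' @return A volume of the same class on the new grid.
#' @export
resampleVolume <- function(vol, slices = 64L, inplane = c(256L, 256L)) {
  stopifnot(is(vol, "VoxelVolume"))
  arr <- vol@voxels
  d <- dim(arr)
  nearest <- is(vol, "LabelVolume")

  # axial center crop / zero pad
  nz <- d[1]
  if (slices <= nz) {
    start <- (nz - slices) %/% 2L + 1L
    arr <- arr[start:(start + slices - 1L), , , drop = FALSE]
  } else {
    out <- array(0, c(slices, d[2], d[3]))
    start <- (slices - nz) %/% 2L + 1L
    out[start:(start + nz - 1L), , ] <- arr
    arr <- out
  }

  ny <- d[2]; nx <- d[3]
  ty <- (seq_len(inplane[1]) - 0.5) * ny / inplane[1] + 0.5
  tx <- (seq_len(inplane[2]) - 0.5) * nx / inplane[2] + 0.5
  if (nearest) {
    iy <- pmin(pmax(round(ty), 1L), ny)
    ix <- pmin(pmax(round(tx), 1L), nx)
    res <- arr[, iy, ix, drop = FALSE]
  } else {
    y0 <- pmin(pmax(floor(ty), 1L), ny - 1L); fy <- pmin(pmax(ty - y0, 0), 1)
    x0 <- pmin(pmax(floor(tx), 1L), nx - 1L); fx <- pmin(pmax(tx - x0, 0), 1)
    a00 <- arr[, y0, x0, drop = FALSE]; a01 <- arr[, y0, x0 + 1L, drop = FALSE]
    a10 <- arr[, y0 + 1L, x0, drop = FALSE]
    a11 <- arr[, y0 + 1L, x0 + 1L, drop = FALSE]
    FY <- array(rep(rep(fy, each = slices), times = inplane[2]),
                c(slices, inplane[1], inplane[2]))
    FX <- array(rep(fx, each = slices * inplane[1]),
                c(slices, inplane[1], inplane[2]))
    res <- (1 - FY) * ((1 - FX) * a00 + FX * a01) +
           FY * ((1 - FX) * a10 + FX * a11)
  }
  newSp <- c(vol@spacing[1], vol@spacing[2] * ny / inplane[1],
             vol@spacing[3] * nx / inplane[2])
  if (nearest) LabelVolume(array(as.integer(res), dim(res)), newSp)
  else if (is(vol, "EncodedVolume")) EncodedVolume(res, newSp)
  else DoseVolume(res, newSp)
}
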