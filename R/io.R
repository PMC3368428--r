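#' Write / read an optical attenuation stack as multi-page TIFF
#'
#' One 32-bit float multi-page TIFF per wavelength band
#' (`<prefix>_<band>nm.tif`), frames as pages, plus a JSON sidecar with the
#' band centres, frame rate and pixel size.
#'
#' @param stack an `ois_stack`.
#' @param prefix output path prefix.
#' @return `read_stack_tiff` returns the restored `ois_stack`.
#' @export
write_stack_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "ois_stack"))
  A <- stack$attenuation
  # TIFF samples are stored in [0, 1]; keep an affine intensity transform
  # in the sidecar so attenuation values round-trip
  lo <- min(A); hi <- max(A)
  span <- if (hi > lo) hi - lo else 1
  for (b in seq_along(stack$wavelengths_nm)) {
    pages <- lapply(seq_len(dim(A)[2]),
                    function(t) (A[b, t, , ] - lo) / span)
    tiff::writeTIFF(pages, sprintf("%s_%gnm.tif", prefix,
                                   stack$wavelengths_nm[b]),
                    bits.per.sample = 32, reduce = FALSE)
  }
  jsonlite::write_json(list(wavelengths_nm = stack$wavelengths_nm,
                            halfwidth_nm = stack$halfwidth_nm,
                            rate_hz = stack$rate_hz,
                            pixel_um = stack$pixel_um,
                            intensity_offset = lo,
                            intensity_span = span),
                       paste0(prefix, "_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  bands <- meta$wavelengths_nm
  arrs <- lapply(bands, function(w) {
    pages <- tiff::readTIFF(sprintf("%s_%gnm.tif", prefix, w), all = TRUE,
                            as.is = FALSE)
    simplify2array(pages)  # y, x, t
  })
  nt <- dim(arrs[[1]])[3]; ny <- dim(arrs[[1]])[1]; nx <- dim(arrs[[1]])[2]
  A <- array(0, dim = c(length(bands), nt, ny, nx))
  for (b in seq_along(bands))
    A[b, , , ] <- aperm(arrs[[b]], c(3, 1, 2))
  off <- meta$intensity_offset %||% 0
  span <- meta$intensity_span %||% 1
  A <- A * span + off
  structure(list(attenuation = A, wavelengths_nm = bands,
                 halfwidth_nm = meta$halfwidth_nm, rate_hz = meta$rate_hz,
                 pixel_um = meta$pixel_um), class = "ois_stack")
}

#' Write an fMRI series or a 2D map as NIfTI-1
#'
#' Series are written as `x  x y x 1 x T` volumes with pixel dimensions
#' derived from the FOV; maps as single volumes.
#'
#' @param fmri an `ois_fmri`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_fmri_nifti <- function(fmri, path) {
  stopifnot(inherits(fmri, "ois_fmri"))
  d <- dim(fmri$data)
  vox_mm <- fmri$fov_mm / d[2]
  arr <- array(aperm(fmri$data, c(3, 2, 1)), dim = c(d[3], d[2], 1, d[1]))
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- c(vox_mm, vox_mm, 2, fmri$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_fmri_nifti
#' @param map numeric matrix.
#' @param pixel_mm pixel size in mm.
#' @export
write_map_nifti <- function(map, path, pixel_mm = 1) {
  img <- RNifti::asNifti(array(t(map), dim = c(ncol(map), nrow(map), 1)))
  RNifti::pixdim(img) <- c(pixel_mm, pixel_mm, 2)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_fmri_nifti
#' @export
read_fmri_nifti <- function(path, te_s = 0.012) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  data <- aperm(array(img, dim = c(d[1], d[2], d[4])), c(3, 2, 1))
  structure(list(data = data, tr_s = pd[4] %||% 1, te_s = te_s,
                 fov_mm = d[1] * pd[1], matrix_px = d[1],
                 base_signal = NA_real_), class = "ois_fmri")
}

#' Write a region time-series table as CSV
#'
#' Columns `time_s`, `d_hbo2_uM`, `d_hbr_uM`, `d_hbt_uM`.
#'
#' @param field an `ois_field`.
#' @param mask logical region mask.
#' @param path output CSV path.
#' @export
write_region_csv <- function(field, mask, path) {
  df <- data.frame(
    time_s = field$time_s,
    d_hbo2_uM = apply_mask_mean(field$d_hbo2, mask),
    d_hbr_uM = apply_mask_mean(field$d_hbr, mask),
    d_hbt_uM = apply_mask_mean(field$d_hbt, mask))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a paradigm as YAML
#' @param paradigm an [make_paradigm()] object.
#' @param path file path.
#' @export
write_paradigm_yaml <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  yaml::write_yaml(unclass(paradigm), path)
  invisible(path)
}

#' @rdname write_paradigm_yaml
#' @export
read_paradigm_yaml <- function(path) {
  do.call(make_paradigm, yaml::read_yaml(path))
}
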