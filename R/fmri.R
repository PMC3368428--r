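#' Generate a synthetic EPI-like BOLD series
#'
#' The synthetic measurement arm: pushes a ground-truth haemodynamic field
#' through the extravascular MR attenuation forward model at the mid-range
#' vessel radius, places the optical window physically into a 64 x 64
#' imaging plane (FOV 30 mm), decimates to the repetition time and scales
#' onto a constant baseline with additive Gaussian noise.  The optical
#' window (a few mm across at 80 um pixels) maps onto a small patch of the
#' coarser fMRI grid; each fMRI voxel averages the BOLD fractions of the
#' field pixels whose centres fall inside it, and voxels outside the window
#' stay at baseline.
#'
#' @param field an [generate_haemodynamics()] field covering the paradigm.
#' @param baseline a [baseline_concentrations()] state.
#' @param mr an [mr_config()].
#' @param blut a [build_bold_lut()] table.
#' @param noise_sd per-frame Gaussian noise, as a fraction of the baseline
#'   signal.
#' @param seed integer seed.
#' @param paradigm optional [make_paradigm()]; when given, the output
#'   length is checked to equal `baseline_s + n_trials * isi_s` frames at
#'   TR.
#' @param matrix_px acquisition matrix (default 64).
#' @param fov_mm field of view (default 30 mm).
#' @param base_signal arbitrary-unit baseline signal level.
#' @return An `ois_fmri`: array `data` of dim `[T, matrix, matrix]`,
#'   `tr_s`, `te_s`, `fov_mm`, plus the window placement used.
#' @export
generate_fmri <- function(field, baseline, mr, blut, noise_sd = 0.005,
                          seed = 1, paradigm = NULL, matrix_px = 64,
                          fov_mm = 30, base_signal = 100) {
  stopifnot(inherits(field, "ois_field"))
  tr_s <- if (is.null(paradigm)) 1 else paradigm$fmri_tr_s
  rate <- field$rate_hz
  nt_field <- dim(field$d_hbt)[1]
  duration_s <- nt_field / rate
  n_frames <- floor(duration_s / tr_s + 1e-9)
  if (!is.null(paradigm)) {
    want <- round((paradigm$baseline_s + paradigm$n_trials * paradigm$isi_s) /
                    tr_s)
    if (n_frames < want)
      stop("field does not cover the paradigm duration")
    n_frames <- want
  }
  # decimate the field to TR by frame subsampling, then forward model
  idx <- round((seq_len(n_frames) - 1) * tr_s * rate) + 1L
  dec <- structure(list(
    d_hbo2 = field$d_hbo2[idx, , , drop = FALSE],
    d_hbr = field$d_hbr[idx, , , drop = FALSE],
    d_hbt = field$d_hbt[idx, , , drop = FALSE],
    time_s = (idx - 1) / rate, rate_hz = 1 / tr_s,
    pixel_um = field$pixel_um, grid_px = field$grid_px),
    class = "ois_field")
  pred <- predict_bold(dec, baseline, blut, mr, radii_um = 10)
  bold <- pred$central                       # [T, ny, nx] fractional

  # physical placement: field pixel centres -> fMRI voxel indices
  vox_um <- fov_mm * 1000 / matrix_px
  ny <- dim(bold)[2]; nx <- dim(bold)[3]
  off_y <- (matrix_px * vox_um - ny * field$pixel_um) / 2
  off_x <- (matrix_px * vox_um - nx * field$pixel_um) / 2
  if (off_y < 0 || off_x < 0) stop("optical window larger than the FOV")
  fy <- floor((off_y + (seq_len(ny) - 0.5) * field$pixel_um) / vox_um) + 1L
  fx <- floor((off_x + (seq_len(nx) - 0.5) * field$pixel_um) / vox_um) + 1L
  vox_of_px <- outer(fy, fx, function(a, b) (b - 1L) * matrix_px + a)
  counts <- tabulate(vox_of_px, nbins = matrix_px * matrix_px)

  bold_m <- matrix(bold, n_frames, ny * nx)
  acc <- matrix(0, n_frames, matrix_px * matrix_px)
  grp <- as.vector(vox_of_px)
  # accumulate columns into their fMRI voxel
  acc[, sort(unique(grp))] <- sapply(sort(unique(grp)), function(gv)
    rowSums(bold_m[, grp == gv, drop = FALSE]))
  nz <- counts > 0
  acc[, nz] <- sweep(acc[, nz, drop = FALSE], 2, counts[nz], `/`)

  set.seed(as.integer(seed))
  data <- base_signal * (1 + acc) +
    base_signal * noise_sd * matrix(rnorm(length(acc)), nrow(acc))
  data <- array(data, dim = c(n_frames, matrix_px, matrix_px))
  structure(list(data = data, tr_s = tr_s, te_s = mr$te_s, fov_mm = fov_mm,
                 matrix_px = matrix_px,
                 window = list(fy = range(fy), fx = range(fx)),
                 base_signal = base_signal,
                 qc = pred$qc), class = "ois_fmri")
}

#' @export
print.ois_fmri <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fMRI series: %d frames, %d x %d, TR %gs, FOV %g mm\n",
              d[1], d[2], d[3], x$tr_s, x$fov_mm))
  invisible(x)
}

#' Fractional BOLD signal change
#'
#' Normalises an fMRI series by the mean of its initial baseline period.
#'
#' @param fmri an `ois_fmri`.
#' @param baseline_s initial baseline duration used for the normalisation.
#' @return Array `[T, y, x]` of fractional changes.
#' @export
fmri_fractional <- function(fmri, baseline_s = 60) {
  stopifnot(inherits(fmri, "ois_fmri"))
  nb <- max(1L, round(baseline_s / fmri$tr_s))
  mu <- apply(fmri$data[seq_len(nb), , , drop = FALSE], c(2, 3), mean)
  sweep(fmri$data, c(2, 3), mu, `/`) - 1
}
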