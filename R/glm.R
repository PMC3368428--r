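#' Build a GLM design matrix
#'
#' Three-column design: a trial-locked response regressor (boxcar over the
#' stimulation frames, optionally convolved with a response kernel), a ramp
#' normalised to `[0, 1]`, and a DC offset of ones.
#'
#' @param paradigm an [make_paradigm()] object.
#' @param frame_rate_hz sampling rate of the series to be fitted.
#' @param kernel optional numeric response kernel; when supplied the boxcar
#'   is convolved with it and renormalised to unit peak.
#' @param duration_s series duration; default the full paradigm.
#' @param onset_shift_s shift applied to all onsets (used when fitting
#'   trial-folded series whose window starts at the stimulus onset).
#' @return A `frames x 3` matrix with columns `response`, `ramp`, `dc` and
#'   attribute `frame_rate_hz`.
#' @export
build_design <- function(paradigm, frame_rate_hz, kernel = NULL,
                         duration_s = paradigm_duration_s(paradigm),
                         onset_shift_s = 0) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  n <- round(duration_s * frame_rate_hz)
  if (n < 3) stop("paradigm not representable at this frame rate")
  t <- (seq_len(n) - 1) / frame_rate_hz
  resp <- numeric(n)
  for (on in onset_times(paradigm) + onset_shift_s)
    resp[t >= on & t < on + paradigm$stim_duration_s] <- 1
  if (!is.null(kernel)) {
    k <- kernel / sum(kernel)
    resp <- convolve(resp, rev(k), type = "open")[seq_len(n)]
    if (max(resp) > 0) resp <- resp / max(resp)
  }
  ramp <- if (n > 1) (t - t[1]) / (t[n] - t[1]) else 0
  X <- cbind(response = resp, ramp = ramp, dc = 1)
  attr(X, "frame_rate_hz") <- frame_rate_hz
  X
}

#' Voxelwise GLM fit with z-scores
#'
#' Ordinary least squares per voxel; the z-score of the response regressor
#' is its estimate divided by its standard error (residual variance times
#' the design covariance).  Voxels with zero residual variance receive a
#' capped sentinel z of +/- 1e6 and a QC flag.
#'
#' @param series numeric vector, `time x voxels` matrix, or `[time, y, x]`
#'   array.
#' @param design a [build_design()] matrix (or any full-rank matrix whose
#'   first column is the regressor of interest).
#' @return An `ois_glm`: `beta` (regressors x voxels, reshaped to maps for
#'   array input), `z` map for the response regressor, `sigma2` residual
#'   variance, `zero_residual` QC flags.
#' @export
fit_glm <- function(series, design) {
  arr <- NULL
  if (is.array(series) && length(dim(series)) == 3L) {
    arr <- dim(series)
    series <- matrix(series, arr[1], arr[2] * arr[3])
  } else if (is.null(dim(series))) {
    series <- matrix(series, ncol = 1)
  }
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (nrow(series) != n) stop("series and design frame counts differ")
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qrX, series)
  fitted <- X %*% beta
  res <- series - fitted
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se2 <- sigma2 * xtx_inv[1, 1]
  zero_res <- sigma2 < 1e-24
  z <- numeric(ncol(series))
  ok <- !zero_res
  z[ok] <- beta[1, ok] / sqrt(se2[ok])
  z[!ok] <- sign(beta[1, !ok]) * 1e6
  z[!ok & abs(beta[1, ]) < 1e-10] <- 0
  out <- list(beta = beta, z = z, sigma2 = sigma2,
              zero_residual = zero_res, df = df,
              colnames = colnames(X))
  if (!is.null(arr)) {
    out$z <- matrix(z, arr[2], arr[3])
    out$sigma2 <- matrix(sigma2, arr[2], arr[3])
    out$zero_residual <- matrix(zero_res, arr[2], arr[3])
    out$beta_maps <- lapply(seq_len(p), function(i)
      matrix(beta[i, ], arr[2], arr[3]))
    names(out$beta_maps) <- colnames(X)
  }
  structure(out, class = "ois_glm")
}

# connected-component labelling of a logical matrix (4- or 8-connectivity)
label_components <- function(mask, connectivity = 4) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 4) {
    nbr <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else if (connectivity == 8) {
    nbr <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
    nbr <- nbr[!(nbr[, 1] == 0 & nbr[, 2] == 0), ]
  } else stop("connectivity must be 4 or 8")
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      vy <- (v - 1L) %% ny + 1L
      vx <- (v - 1L) %/% ny + 1L
      for (k in seq_len(nrow(nbr))) {
        vy2 <- vy + nbr[k, 1]; vx2 <- vx + nbr[k, 2]
        if (vy2 >= 1 && vy2 <= ny && vx2 >= 1 && vx2 <= nx) {
          w <- (vx2 - 1L) * ny + vy2
          if (mask[w] && lab[w] == 0L) {
            lab[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  lab
}

#' Cluster-threshold a z-map
#'
#' Retains connected components of supra-threshold voxels whose size
#' reaches `min_cluster`.  The defaults implement the mapping rule used for
#' the activation maps: z > 4 for positive BOLD, z < -2 for negative BOLD,
#' and clusters of more than five adjacent voxels (i.e. size >= 6;
#' `min_cluster` is configurable so size >= 5 readings are possible).
#'
#' @param zmap numeric z-score matrix.
#' @param z_pos positive threshold (> 0).
#' @param z_neg negative threshold (< 0).
#' @param min_cluster minimum retained component size (voxels).
#' @param connectivity 4 (default) or 8.
#' @return List of logical matrices `positive` and `negative` (always
#'   disjoint).
#' @export
threshold_clusters <- function(zmap, z_pos = 4, z_neg = -2, min_cluster = 6,
                               connectivity = 4) {
  if (!(z_pos > 0 && z_neg < 0)) stop("need z_pos > 0 > z_neg")
  if (min_cluster < 1) stop("min_cluster must be >= 1")
  keep_big <- function(mask) {
    lab <- label_components(mask, connectivity)
    if (!any(mask)) return(mask)
    sizes <- tabulate(lab[lab > 0])
    mask & matrix(sizes[pmax(lab, 1L)] >= min_cluster & lab > 0L,
                  nrow(mask), ncol(mask))
  }
  list(positive = keep_big(zmap > z_pos),
       negative = keep_big(zmap < z_neg))
}

#' Mean time series over a region mask
#'
#' @param series `[time, y, x]` array.
#' @param mask non-empty logical matrix.
#' @param paradigm,rate_hz,fold,prestim_s when `fold = TRUE`, the region
#'   mean is additionally averaged across trial windows (see
#'   [fold_trials()]).
#' @return Numeric time series.
#' @export
region_timeseries <- function(series, mask, fold = FALSE, paradigm = NULL,
                              rate_hz = NULL, prestim_s = 0) {
  if (!any(mask)) stop("empty region mask")
  ts <- apply_mask_mean(series, mask)
  if (fold) {
    if (is.null(paradigm) || is.null(rate_hz))
      stop("folding needs paradigm and rate_hz")
    ts <- fold_trials(ts, paradigm, rate_hz, prestim_s = prestim_s)
  }
  ts
}

#' Refine a design matrix from a measured region time series
#'
#' Second pass of the two-pass mapping procedure: the response column is
#' replaced by the detrended (best-fit line removed), unit-peak-normalised
#' region mean extracted with the preliminary boxcar design; the ramp and
#' DC columns are unchanged.
#'
#' @param design a [build_design()] matrix.
#' @param region_series numeric series of the same length as the design.
#' @return The refined design matrix.
#' @export
refine_design <- function(design, region_series) {
  X <- as.matrix(design)
  if (length(region_series) != nrow(X))
    stop("region series length does not match the design")
  t <- seq_along(region_series)
  detr <- stats::residuals(lm(region_series ~ t))
  m <- max(abs(detr))
  if (m < 1e-12) stop("zero-variance region series")
  X[, 1] <- detr / m
  colnames(X)[1] <- "response"
  X
}
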