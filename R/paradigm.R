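#' Stimulation paradigm
#'
#' Builds the stimulation paradigm used throughout the pipeline: an initial
#' baseline followed by a train of identical stimulation events.  Defaults
#' reproduce the whisker-pad protocol the synthetic data emulate: 60 s
#' baseline, thirty 16 s stimulation events at an inter-stimulus interval of
#' 70 s, optical imaging at 8 Hz per wavelength with a 10 s pre-stimulus
#' window per trial, and fMRI at TR = 1 s.
#'
#' @param ... named overrides of the default fields.  Allowed names:
#'   `baseline_s`, `n_trials`, `stim_duration_s`, `isi_s`, `ois_prestim_s`,
#'   `ois_trial_window_s`, `ois_rate_hz`, `fmri_tr_s`.  All must be positive
#'   scalars.
#'
#' @return An object of class `ois_paradigm`: a named list of the eight
#'   fields above.
#' @examples
#' p <- make_paradigm()
#' onset_times(p)[1:3]   # 60 130 200
#' @export
make_paradigm <- function(...) {
  defaults <- list(
    baseline_s = 60, n_trials = 30, stim_duration_s = 16, isi_s = 70,
    ois_prestim_s = 10, ois_trial_window_s = 70, ois_rate_hz = 8,
    fmri_tr_s = 1)
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("paradigm overrides must be named", call. = FALSE)
    bad <- setdiff(nm, names(defaults))
    if (length(bad))
      stop("unknown paradigm field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (f in nm) {
      v <- overrides[[f]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("paradigm field '", f, "' must be a positive scalar",
             call. = FALSE)
      defaults[[f]] <- v
    }
  }
  p <- defaults
  p$n_trials <- as.integer(round(p$n_trials))
  if (p$n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (p$ois_trial_window_s < p$stim_duration_s + p$ois_prestim_s)
    stop("ois_trial_window_s must cover prestim + stimulation", call. = FALSE)
  if (p$isi_s < p$stim_duration_s)
    stop("isi_s shorter than the stimulation itself", call. = FALSE)
  structure(p, class = "ois_paradigm")
}

#' Stimulus onset times
#'
#' @param paradigm an [make_paradigm()] object.
#' @return Numeric vector of `n_trials` onset times in seconds,
#'   `baseline_s + k * isi_s` for `k = 0, ..., n_trials - 1`.
#' @export
onset_times <- function(paradigm) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  paradigm$baseline_s + paradigm$isi_s * (seq_len(paradigm$n_trials) - 1)
}

#' Total paradigm duration in seconds
#'
#' Baseline plus `n_trials` full inter-stimulus intervals.
#' @param paradigm an [make_paradigm()] object.
#' @return Duration in seconds.
#' @export
paradigm_duration_s <- function(paradigm) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  paradigm$baseline_s + paradigm$n_trials * paradigm$isi_s
}

#' @export
print.ois_paradigm <- function(x, ...) {
  cat(sprintf(
    "Stimulation paradigm: %gs baseline, %d x %gs stimulation, ISI %gs\n",
    x$baseline_s, x$n_trials, x$stim_duration_s, x$isi_s))
  cat(sprintf("  OIS %g Hz (window %gs, prestim %gs); fMRI TR %gs\n",
              x$ois_rate_hz, x$ois_trial_window_s, x$ois_prestim_s,
              x$fmri_tr_s))
  invisible(x)
}

#' Average an array across trial windows
#'
#' Folds a time series (vector or `[time, y, x]` array) sampled at
#' `rate_hz` into a single trial window by averaging windows locked to the
#' stimulus onsets.  Trials whose window would run past the end of the data
#' are dropped.
#'
#' @param x numeric vector or 3D array with time as the first dimension.
#' @param paradigm an [make_paradigm()] object.
#' @param rate_hz sampling rate of `x` in frames per second.
#' @param prestim_s seconds before each onset to include (default 0).
#' @param window_s window length in seconds (default the ISI).
#' @return Object of the same kind as `x` with the time dimension reduced to
#'   `round(window_s * rate_hz)` frames; attribute `n_trials_used` records
#'   how many windows entered the average.
#' @export
fold_trials <- function(x, paradigm, rate_hz, prestim_s = 0,
                        window_s = paradigm$isi_s) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  vec <- is.null(dim(x))
  if (vec) x <- array(x, dim = c(length(x), 1, 1))
  if (length(dim(x)) != 3L) stop("x must be a vector or [time, y, x] array")
  nt <- dim(x)[1]
  wlen <- round(window_s * rate_hz)
  starts <- round((onset_times(paradigm) - prestim_s) * rate_hz) + 1L
  starts <- starts[starts >= 1L & (starts + wlen - 1L) <= nt]
  if (!length(starts)) stop("no complete trial window fits the data")
  acc <- array(0, dim = c(wlen, dim(x)[2], dim(x)[3]))
  for (s in starts) acc <- acc + x[s:(s + wlen - 1L), , , drop = FALSE]
  acc <- acc / length(starts)
  out <- if (vec) as.vector(acc) else acc
  attr(out, "n_trials_used") <- length(starts)
  out
}
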