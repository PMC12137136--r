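## Epoch containers and windowed-signal utilities.

#' Construct an epoch array
#'
#' Container for a trials x channels x time tensor of epoched signal
#' (e.g. normalized high-gamma power), with its sampling rate, time axis
#' relative to stimulus onset, trial table and channel metadata.
#'
#' @param data numeric array `[n_trials, n_channels, n_times]`, no NaN.
#' @param sfreq sampling rate in Hz.
#' @param times time axis in seconds relative to stimulus onset; must be
#'   uniformly spaced at `1/sfreq`.
#' @param trials a [trial_table()] with `n_trials` rows.
#' @param channels a [channel_info()] with `n_channels` rows.
#' @return object of class `epoch_array`.
#' @export
epoch_array <- function(data, sfreq, times, trials, channels) {
  stopifnot(length(dim(data)) == 3L)
  if (anyNA(data)) stop("epoch data must not contain NA/NaN")
  stopifnot(nrow(trials) == dim(data)[1],
            nrow(channels) == dim(data)[2],
            length(times) == dim(data)[3])
  if (length(times) > 1) {
    dt <- diff(times)
    if (max(abs(dt - 1 / sfreq)) > 1e-6 / sfreq)
      stop("times must be uniformly spaced at 1/sfreq")
  }
  structure(list(data = data, sfreq = sfreq, times = times,
                 trials = trials, channels = channels),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("epoch_array: %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts a channels x time continuous signal into per-trial epochs spanning
#' `[tmin, tmax]` seconds around each stimulus onset (default -1.0 to
#' +2.5 s). Sample `k` of epoch `e` equals the continuous signal at
#' `onset_e + times[k]`, with onsets snapped to the sampling grid.
#'
#' @param signal numeric matrix `[n_channels, n_samples]`; sample 1 is time
#'   0 of the recording.
#' @param sfreq sampling rate in Hz.
#' @param events a [trial_table()].
#' @param tmin,tmax epoch window in seconds relative to onset.
#' @param channels optional [channel_info()]; defaults to generic names.
#' @return an [epoch_array()].
#' @export
epoch <- function(signal, sfreq, events, tmin = -1.0, tmax = 2.5,
                  channels = NULL) {
  stopifnot(is.matrix(signal), tmin < tmax)
  n_ch <- nrow(signal); n_samp <- ncol(signal)
  if (is.null(channels))
    channels <- channel_info(sprintf("ch%03d", seq_len(n_ch)))
  offs <- round(tmin * sfreq):round(tmax * sfreq)
  times <- offs / sfreq
  onset_idx <- round(events$onset_s * sfreq) + 1L  # sample 1 <-> t = 0
  lo <- onset_idx + offs[1]
  hi <- onset_idx + offs[length(offs)]
  bad <- which(lo < 1L | hi > n_samp)
  if (length(bad))
    stop("event(s) too close to recording edge; trial_id: ",
         paste(events$trial_id[bad], collapse = ", "))
  n_tr <- nrow(events)
  dat <- array(0, dim = c(n_tr, n_ch, length(offs)))
  for (e in seq_len(n_tr)) {
    dat[e, , ] <- signal[, (onset_idx[e] + offs[1]):(onset_idx[e] + offs[length(offs)]), drop = FALSE]
  }
  epoch_array(dat, sfreq, times, events, channels)
}

#' Reduce epochs over a time window to one scalar per trial and channel
#'
#' Reducers: `auc` (trapezoidal time-integral over the window), `mean`
#' (time average), `peak_to_peak` (max minus min, for evoked potentials).
#'
#' @param epochs an [epoch_array()].
#' @param window numeric `c(t0, t1)` in seconds, inside the epoch time axis.
#' @param reducer one of `"auc"`, `"mean"`, `"peak_to_peak"`.
#' @return object of class `window_scalar`: list with `values`
#'   (`n_trials x n_channels` matrix), `window` and `reducer`.
#' @export
window_reduce <- function(epochs, window, reducer = c("auc", "mean", "peak_to_peak")) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(epochs, "epoch_array"), length(window) == 2L,
            window[1] < window[2])
  tol <- 1e-9
  if (window[1] < min(epochs$times) - tol || window[2] > max(epochs$times) + tol)
    stop("window outside the epoch time axis")
  sel <- which(epochs$times >= window[1] - tol & epochs$times <= window[2] + tol)
  if (length(sel) < 2L) stop("window contains fewer than 2 samples")
  x <- epochs$data[, , sel, drop = FALSE]
  tt <- epochs$times[sel]
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]
  vals <- switch(reducer,
    auc = {
      # trapezoid over uniform grid: dt * (sum - (first + last)/2)
      dt <- 1 / epochs$sfreq
      s <- matrix(apply(x, c(1, 2), sum), n_tr, n_ch)
      first <- matrix(x[, , 1], n_tr, n_ch)
      last <- matrix(x[, , length(sel)], n_tr, n_ch)
      dt * (s - 0.5 * (first + last))
    },
    mean = apply(x, c(1, 2), mean),
    peak_to_peak = apply(x, c(1, 2), function(v) max(v) - min(v)))
  vals <- matrix(vals, n_tr, n_ch)
  colnames(vals) <- epochs$channels$name
  structure(list(values = vals, window = window, reducer = reducer),
            class = "window_scalar")
}

#' Average epochs into non-overlapping time bins
#'
#' Each output sample is the mean of one `bin_s`-second bin of input
#' samples, aligned to the start of the epoch; a trailing partial bin is
#' dropped. Output times are bin left edges and the new sampling rate is
#' `1/bin_s`. `bin_s` must be an integer multiple of the input sample
#' period.
#'
#' @param epochs an [epoch_array()].
#' @param bin_s bin width in seconds (default 0.02).
#' @return a decimated [epoch_array()].
#' @export
bin_decimate <- function(epochs, bin_s = 0.02) {
  stopifnot(inherits(epochs, "epoch_array"))
  ratio <- bin_s * epochs$sfreq
  if (ratio < 1 - 1e-6) stop("bin_s must be >= one sample period")
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("bin_s must be an integer multiple of 1/sfreq")
  r <- as.integer(round(ratio))
  if (r == 1L) return(epochs)
  n_t <- dim(epochs$data)[3]
  n_bins <- n_t %/% r
  if (n_bins < 1L) stop("epoch shorter than one bin")
  keep <- seq_len(n_bins * r)
  x <- epochs$data[, , keep, drop = FALSE]
  dm <- dim(x)
  dim(x) <- c(dm[1] * dm[2], r, n_bins)
  out <- apply(x, c(1, 3), mean)
  dim(out) <- c(dm[1], dm[2], n_bins)
  times <- epochs$times[seq(1, n_bins * r, by = r)]
  epoch_array(out, 1 / bin_s, times, epochs$trials, epochs$channels)
}

#' Save / load an epoch array container
#'
#' Loss-less single-file round-trip of the full epoch container (data,
#' times, sampling rate, trial table, channel table).
#'
#' @param epochs an [epoch_array()].
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` the
#'   restored [epoch_array()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epoch_array"))
  x
}

#' Subset an epoch array by trials and/or channels
#'
#' @param epochs an [epoch_array()].
#' @param trials logical or integer index over trials.
#' @param channels logical or integer index over channels.
#' @return an [epoch_array()].
#' @export
epoch_subset <- function(epochs, trials = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  ti <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else trials
  ci <- if (is.null(channels)) seq_len(dim(epochs$data)[2]) else channels
  tt <- epochs$trials[ti, , drop = FALSE]
  class(tt) <- c("trial_table", "data.frame")
  ch <- epochs$channels[ci, , drop = FALSE]
  class(ch) <- c("channel_info", "data.frame")
  epoch_array(epochs$data[ti, ci, , drop = FALSE], epochs$sfreq,
              epochs$times, tt, ch)
}
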