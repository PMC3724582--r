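# Band-pass filtering and non-overlapping windowing.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift — amplitude features are
#' unaffected by group delay. Pass-band is maximally flat; the effective
#' magnitude response is the squared Butterworth response.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling frequency in Hz.
#' @param low,high Band edges in Hz; require `0 < low < high < fs/2`.
#' @param order Butterworth order of the underlying one-pass design.
#' @return Filtered vector, same length as `x`.
#' @export
#' @examples
#' y <- bandpass_filter(sin(2 * pi * 100 * seq(0, 1, by = 1e-3)), 1000, 30, 450)
bandpass_filter <- function(x, fs, low = 30, high = 450, order = 4) {
  if (!(low > 0 && low < high)) stop("invalid band: need 0 < low < high")
  if (high >= fs / 2) stop("upper band edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Apply the band-pass filter to every channel of every recording
#'
#' Filtering runs per trial, so the five active trials of a gesture are
#' filtered before being concatenated (no splicing discontinuities enter the
#' filter).
#'
#' @param dataset An `emg_dataset`.
#' @param low,high Band edges in Hz.
#' @return The dataset with filtered samples.
#' @export
preprocess_dataset <- function(dataset, low = 30, high = 450) {
  out <- lapply(dataset, function(r) {
    r$samples <- apply(r$samples, 2, bandpass_filter,
                       fs = r$sampling_rate, low = low, high = high)
    r
  })
  attributes(out) <- attributes(dataset)
  out
}

#' Segment a signal into non-overlapping windows
#'
#' Splits a sample vector into consecutive disjoint windows of
#' `round(window_ms * fs / 1000)` samples; an incomplete tail is discarded.
#' At the defaults (256 ms, 1000 Hz) a 10-s signal yields 39 windows.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling frequency in Hz.
#' @param window_ms Window length in milliseconds.
#' @return Matrix with one window per row (`0` rows if `x` is shorter than
#'   one window, with a warning).
#' @export
#' @examples
#' nrow(segment_signal(numeric(10000), 1000, 256))  # 39
segment_signal <- function(x, fs, window_ms = 256) {
  stopifnot(window_ms > 0, fs > 0)
  n_win <- round(window_ms * fs / 1000)
  if (n_win < 2) stop("window too short: fewer than 2 samples")
  k <- floor(length(x) / n_win)
  if (k == 0) {
    warning("signal shorter than one window; returning 0 segments")
    return(matrix(numeric(0), nrow = 0, ncol = n_win))
  }
  matrix(x[seq_len(k * n_win)], nrow = k, ncol = n_win, byrow = TRUE)
}

# Concatenate the active signal of one gesture across trials, per channel.
# Returns an n_total x n_channels matrix in trial order.
concat_gesture_signal <- function(dataset, gesture_id) {
  recs <- Filter(function(r) r$gesture_id == gesture_id, dataset)
  if (length(recs) == 0) stop("no recordings for gesture ", gesture_id)
  recs <- recs[order(vapply(recs, function(r) r$trial, 1L))]
  do.call(rbind, lapply(recs, function(r) r$samples))
}
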