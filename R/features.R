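# Time-domain feature extraction.
#
# Ten per-window amplitude statistics over the N samples x_1..x_N of a
# window. All are evaluated exactly as classically printed for sEMG work:
# MAV  = (1/N) sum |x_i|             mean absolute value
# IEMG = sum |x_i|                   integrated EMG
# RMS  = sqrt((1/N) sum x_i^2)       root mean square
# SSI  = sum x_i^2                   simple square integral
# VAR  = (1/N) sum (x_i - xbar)^2    population variance
# MV   = xbar                        mean value
# WL   = sum |x_{i+1} - x_i|         waveform length
# MPV  = max |x_i|                   maximum peak value
# SSC  = #{ interior i : x_i > x_{i-1}, x_i > x_{i+1}, x_i - x_{i+1} >= eps }
# MAVS = MAV_{k+1} - MAV_k           across adjacent windows (see mavs_series)

#' Feature-extraction configuration
#'
#' @param ssc_epsilon Threshold \eqn{\epsilon} (EMG units) for the SSC
#'   slope-sign-change count; default 0.02.
#' @param mavs_pad Policy for the final MAVS element so the series keeps the
#'   per-gesture window count: `"zero"` appends 0, `"replicate"` repeats the
#'   last difference.
#' @param ssc_both_extrema If `TRUE`, SSC also counts thresholded local
#'   minima (the conventional two-sided rule); default counts peaks only.
#' @return List of class `emg_feature_config`.
#' @export
feature_config <- function(ssc_epsilon = 0.02,
                           mavs_pad = c("zero", "replicate"),
                           ssc_both_extrema = FALSE) {
  stopifnot(ssc_epsilon >= 0)
  structure(list(ssc_epsilon = ssc_epsilon,
                 mavs_pad = match.arg(mavs_pad),
                 ssc_both_extrema = isTRUE(ssc_both_extrema)),
            class = "emg_feature_config")
}

#' Evaluate one time-domain feature on a window
#'
#' Computes one of the nine per-window statistics (MAVS operates across
#' windows; see [mavs_series()]). Feature names are case-insensitive.
#'
#' @param x Numeric sample vector (one window), length >= 2.
#' @param method One of `"MAV"`, `"RMS"`, `"VAR"`, `"WL"`, `"IEMG"`,
#'   `"SSC"`, `"MV"`, `"SSI"`, `"MPV"`.
#' @param config A [feature_config()].
#' @return Scalar feature value.
#' @export
#' @examples
#' feature_value(c(1, -2, 3, -4), "MAV")   # 2.5
#' feature_value(c(1, -2, 3, -4), "WL")    # 15
feature_value <- function(x, method, config = feature_config()) {
  method <- match_feature(method)
  if (method == "MAVS") {
    stop("MAVS is defined across adjacent windows; use mavs_series()")
  }
  n <- length(x)
  if (n < 2) stop("a window needs at least 2 samples")
  switch(method,
         MAV  = mean(abs(x)),
         RMS  = sqrt(mean(x^2)),
         VAR  = mean((x - mean(x))^2),
         WL   = sum(abs(diff(x))),
         IEMG = sum(abs(x)),
         SSC  = ssc_count(x, config$ssc_epsilon, config$ssc_both_extrema),
         MV   = mean(x),
         SSI  = sum(x^2),
         MPV  = max(abs(x)))
}

ssc_count <- function(x, eps, both_extrema = FALSE) {
  n <- length(x)
  if (n < 3) return(0)
  i <- 2:(n - 1)
  peaks <- x[i] > x[i - 1] & x[i] > x[i + 1] & (x[i] - x[i + 1]) >= eps
  cnt <- sum(peaks)
  if (both_extrema) {
    troughs <- x[i] < x[i - 1] & x[i] < x[i + 1] & (x[i + 1] - x[i]) >= eps
    cnt <- cnt + sum(troughs)
  }
  cnt
}

#' Mean-absolute-value slope series
#'
#' Differences of MAV between adjacent windows: element k is
#' `MAV[k+1] - MAV[k]`. The final element is padded (policy
#' `config$mavs_pad`) so the output has the same length as the input,
#' preserving the per-gesture window count.
#'
#' @param mav_values Ordered MAV values per window, length >= 2.
#' @param config A [feature_config()].
#' @return Numeric vector, same length as `mav_values`.
#' @export
#' @examples
#' mavs_series(c(2.0, 2.5, 2.2))  # 0.5 -0.3 0.0
mavs_series <- function(mav_values, config = feature_config()) {
  k <- length(mav_values)
  if (k < 2) stop("mavs_series needs at least 2 MAV values")
  d <- diff(mav_values)
  pad <- if (config$mavs_pad == "zero") 0 else d[k - 1]
  c(d, pad)
}

#' Build a per-subject feature set
#'
#' For each gesture the active trials are concatenated per channel,
#' segmented into non-overlapping windows, and one feature value per window
#' and channel is computed. At the defaults (10 gestures x 10 s x 3
#' channels, 256-ms windows) this yields a 390 x 3 matrix.
#'
#' @param dataset An `emg_dataset` (normally already band-pass filtered;
#'   see [preprocess_dataset()]).
#' @param method Feature name (case-insensitive), including `"MAVS"`.
#' @param config A [feature_config()].
#' @param window_ms Window length in ms.
#' @return An `emg_feature_set`: list with `matrix` (rows = windows,
#'   columns = `<feature>_ch<j>`), `row_labels` (gesture per row),
#'   `segment_index` (1-based within gesture), `feature`, `subject`.
#' @export
build_feature_set <- function(dataset, method, config = feature_config(),
                              window_ms = 256) {
  method <- match_feature(method)
  if (length(dataset) == 0) stop("empty dataset")
  gestures <- unique(vapply(dataset, function(r) r$gesture_id, ""))
  fs <- dataset[[1]]$sampling_rate
  blocks <- list(); labels <- character(0); seg_idx <- integer(0)
  for (g in gestures) {
    sig <- concat_gesture_signal(dataset, g)
    segs <- lapply(seq_len(ncol(sig)), function(ch) {
      segment_signal(sig[, ch], fs, window_ms)
    })
    k <- nrow(segs[[1]])
    if (k == 0) stop("gesture ", g, " has no complete window")
    vals <- sapply(segs, function(m) {
      if (method == "MAVS") {
        mav <- apply(m, 1, feature_value, method = "MAV", config = config)
        mavs_series(mav, config)
      } else {
        apply(m, 1, feature_value, method = method, config = config)
      }
    })
    vals <- matrix(vals, nrow = k)
    blocks[[g]] <- vals
    labels <- c(labels, rep(g, k))
    seg_idx <- c(seg_idx, seq_len(k))
  }
  mat <- do.call(rbind, blocks)
  colnames(mat) <- paste0(tolower(method), "_ch", seq_len(ncol(mat)))
  rownames(mat) <- NULL
  structure(list(matrix = mat, row_labels = labels,
                 segment_index = seg_idx, feature = method,
                 subject = attr(dataset, "subject") %||% "S1"),
            class = "emg_feature_set")
}

#' Build all single-feature sets
#'
#' @inheritParams build_feature_set
#' @param methods Feature names; defaults to all ten.
#' @return Named list of `emg_feature_set`, one per feature.
#' @export
build_all_feature_sets <- function(dataset, methods = emg_features(),
                                   config = feature_config(),
                                   window_ms = 256) {
  methods <- vapply(methods, match_feature, "")
  sets <- lapply(methods, build_feature_set, dataset = dataset,
                 config = config, window_ms = window_ms)
  names(sets) <- methods
  sets
}

#' Concatenate ranked single-feature sets into a combination
#'
#' Horizontally concatenates the first `k` feature sets in ranked order,
#' channel-major within feature, so a k-feature combination over three
#' channels has 3k columns (e.g. `k = 2` with order MPV, MAV gives columns
#' `mpv_ch1, mpv_ch2, mpv_ch3, mav_ch1, mav_ch2, mav_ch3`).
#'
#' @param single_sets Named list of `emg_feature_set` (names = features).
#' @param order Ranked feature names, best first.
#' @param k Number of leading features to take, `2 <= k <= length(order)`.
#' @return An `emg_feature_set` whose `feature` is e.g. `"C2:MPV+MAV"`.
#' @export
combine_feature_sets <- function(single_sets, order, k) {
  order <- vapply(order, match_feature, "")
  if (k < 2 || k > length(order)) stop("k must be in 2..length(order)")
  chosen <- order[seq_len(k)]
  missing <- setdiff(chosen, names(single_sets))
  if (length(missing)) stop("missing feature sets: ",
                            paste(missing, collapse = ", "))
  ref <- single_sets[[chosen[1]]]
  mats <- lapply(chosen, function(f) {
    s <- single_sets[[f]]
    if (!identical(s$row_labels, ref$row_labels)) {
      stop("row labels of ", f, " do not match")
    }
    s$matrix
  })
  structure(list(matrix = do.call(cbind, mats), row_labels = ref$row_labels,
                 segment_index = ref$segment_index,
                 feature = paste0("C", k, ":", paste(chosen, collapse = "+")),
                 subject = ref$subject),
            class = "emg_feature_set")
}

#' @export
print.emg_feature_set <- function(x, ...) {
  cat(sprintf("<emg_feature_set> %s, subject %s: %d rows x %d columns, %d classes\n",
              x$feature, x$subject, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$row_labels))))
  invisible(x)
}

#' @export
as.data.frame.emg_feature_set <- function(x, ...) {
  data.frame(subject = x$subject, gesture = x$row_labels,
             segment = x$segment_index, x$matrix, check.names = FALSE)
}
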