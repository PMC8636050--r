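#' Filter specification
#'
#' Mains-interference notch plus band-limiting bandpass applied to every
#' channel before segmentation. The notch is a second-order IIR (biquad) at
#' `notch_hz` with quality factor `notch_q`; the bandpass is a Butterworth
#' filter of total order `order`. Both are run forward-backward (zero phase)
#' with reflection padding so window timing is not skewed by filter delay.
#'
#' @param notch_hz mains frequency to remove (default 50 Hz).
#' @param bandpass_hz passband edges in Hz (default `c(10, 450)`).
#' @param order total Butterworth bandpass order (even, default 4).
#' @param notch_q notch quality factor (default 30).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, bandpass_hz = c(10, 450),
                        order = 4, notch_q = 30) {
  if (length(bandpass_hz) != 2 || bandpass_hz[1] <= 0 ||
      bandpass_hz[2] <= bandpass_hz[1]) {
    stop("bandpass_hz must be c(low, high) with 0 < low < high")
  }
  if (order %% 2 != 0 || order < 2) stop("bandpass order must be even and >= 2")
  structure(list(notch_hz = notch_hz, bandpass_hz = bandpass_hz,
                 order = order, notch_q = notch_q),
            class = "filter_spec")
}

# RBJ audio-EQ-cookbook biquad band-stop; returns list(b, a).
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering with reflection padding to suppress edge transients.
filtfilt_padded <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, max(3 * (length(a) + length(b)), 1000))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Apply notch and bandpass filters to a recording
#'
#' Filtering is channel-wise and zero-phase, performed once per trial before
#' any segmentation. The recording's meta is stamped so a window set can
#' assert the filters were applied exactly once.
#'
#' @param rec an [emg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered recording.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$rate_hz / 2
  if (spec$bandpass_hz[2] >= nyq) {
    stop("bandpass upper edge ", spec$bandpass_hz[2],
         " Hz must be below Nyquist (", nyq, " Hz)")
  }
  if (spec$notch_hz <= 0 || spec$notch_hz >= nyq) {
    stop("notch frequency must lie in (0, Nyquist)")
  }
  if (isTRUE(rec$filtered)) {
    warning("recording ", rec$trial_id, " already filtered; filtering again")
  }
  notch <- design_notch(spec$notch_hz, rec$rate_hz, spec$notch_q)
  bp <- signal::butter(spec$order / 2, spec$bandpass_hz / nyq, type = "pass")
  x <- rec$samples
  for (c in seq_len(nrow(x))) {
    y <- filtfilt_padded(notch$b, notch$a, x[c, ])
    x[c, ] <- filtfilt_padded(bp$b, bp$a, y)
  }
  out <- rec
  out$samples <- x
  out$filtered <- TRUE
  out$filter_settings <- unclass(spec)
  out
}

#' Crop a recording to its movement-preparation period
#'
#' Prediction uses only the static preparation posture preceding the
#' movement; the interval must be present in `rec$annotations$preparation`
#' as a half-open sample interval.
#'
#' @param rec an [emg_recording()].
#' @return The cropped recording (label and metadata preserved).
#' @export
extract_preparation <- function(rec) {
  iv <- rec$annotations$preparation
  if (is.null(iv)) {
    stop("recording ", rec$trial_id, " has no 'preparation' annotation; ",
         "add one as annotations = list(preparation = c(start, end))")
  }
  if (iv[2] <= iv[1]) stop("empty preparation interval")
  if (iv[2] > n_samples(rec) + 1) stop("preparation interval ends beyond the recording")
  out <- rec
  out$samples <- rec$samples[, iv[1]:(iv[2] - 1), drop = FALSE]
  out$annotations$preparation <- c(1L, ncol(out$samples) + 1L)
  out
}

#' Segment a recording into sliding analysis windows
#'
#' Windows of `window_len` samples advance by `step` samples; a trailing
#' remainder shorter than one window is discarded, giving
#' `floor((T - window_len) / step) + 1` windows in temporal order. At the
#' study's 1500 Hz rate the default 300-sample window spans 200 ms.
#'
#' @param rec an [emg_recording()] (typically filtered and cropped).
#' @param window_len window length in samples (default 300).
#' @param step hop between window starts in samples (default 100).
#' @return A [window_set()] for this trial.
#' @export
segment_windows <- function(rec, window_len = 300, step = 100) {
  Tn <- n_samples(rec)
  if (Tn < window_len) {
    stop("recording has ", Tn, " samples; need at least window_len = ", window_len)
  }
  if (step < 1) stop("step must be >= 1")
  n_w <- (Tn - window_len) %/% step + 1
  C <- n_channels(rec)
  w <- array(0, c(n_w, C, window_len))
  for (i in seq_len(n_w)) {
    s <- (i - 1) * step + 1
    w[i, , ] <- rec$samples[, s:(s + window_len - 1)]
  }
  window_set(w, labels = rep(label_code(rec$label), n_w),
             subject_ids = rep(rec$subject_id, n_w),
             trial_ids = rep(paste(rec$subject_id, rec$trial_id, sep = "/"), n_w),
             window_order = seq_len(n_w),
             meta = list(window_len = window_len, step = step,
                         rate_hz = rec$rate_hz,
                         filtered = isTRUE(rec$filtered),
                         filter_settings = rec$filter_settings))
}

#' Milliseconds to samples at a given rate
#'
#' @param ms duration in milliseconds.
#' @param rate_hz sampling rate.
#' @return Number of samples (integer).
#' @export
ms_to_samples <- function(ms, rate_hz = 1500) as.integer(round(ms * rate_hz / 1000))

#' Inverse-frequency class weights
#'
#' Weight of class `c` is `count(majority) / count(c)`, so the most frequent
#' class has weight exactly 1 and all others at least 1. Used by the weighted
#' cross-entropy loss and the classical baselines.
#'
#' @param labels integer class codes (every class 0..max must be present).
#' @param n_classes number of classes (default: inferred).
#' @return Named numeric vector of weights, one per class code.
#' @export
compute_class_weights <- function(labels, n_classes = NULL) {
  if (length(labels) == 0) stop("labels is empty")
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0)) {
    stop("class(es) absent from labels: ",
         paste(which(counts == 0) - 1L, collapse = ", "))
  }
  w <- max(counts) / counts
  names(w) <- as.character(seq_len(n_classes) - 1L)
  w
}

#' Filter, crop, and window a set of recordings
#'
#' Convenience wrapper running [apply_filters()], [extract_preparation()],
#' and [segment_windows()] over every recording and binding the results.
#'
#' @param recordings list of recordings, or the grouped list returned by
#'   [load_dataset()] / [generate_cohort()].
#' @param spec a [filter_spec()], or `NULL` to skip filtering.
#' @param window_len,step see [segment_windows()].
#' @return A single [window_set()].
#' @export
preprocess_recordings <- function(recordings, spec = filter_spec(),
                                  window_len = 300, step = 100) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (length(recordings) && !inherits(recordings[[1]], "emg_recording")) {
    recordings <- unlist(recordings, recursive = FALSE)   # grouped by subject
  }
  ws <- lapply(recordings, function(rec) {
    if (!is.null(spec)) rec <- apply_filters(rec, spec)
    if (!is.null(rec$annotations$preparation)) rec <- extract_preparation(rec)
    segment_windows(rec, window_len = window_len, step = step)
  })
  bind_windows(ws)
}
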