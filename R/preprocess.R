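#' EEG recordings and signal conditioning
#'
#' Raw recordings are conditioned in three steps before feature extraction:
#' downsampling to 200 Hz with an anti-aliasing decimation filter, zero-phase
#' Butterworth band-pass filtering to 0.5-50 Hz (keeping the delta through
#' gamma bands), and segmentation into non-overlapping 4-second windows
#' (800 samples at 200 Hz, giving a 0.25 Hz spectral resolution).
#'
#' @name preprocess
NULL

#' Construct an EEG recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channel_names channel labels in montage order (defaults to the
#'   rownames of `samples`).
#' @param subject_id,session_id,video_id provenance identifiers.
#' @param label emotion class label (integer or factor level).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_names = rownames(samples),
                          subject_id = NA, session_id = NA, video_id = NA,
                          label = NA) {
  samples <- as.matrix(samples)
  if (rate <= 0) stop("sampling rate must be positive")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop("channel_names length must match the number of rows of samples")
  rownames(samples) <- channel_names
  structure(list(samples = samples, rate = rate, channel_names = channel_names,
                 subject_id = subject_id, session_id = session_id,
                 video_id = video_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$samples), " channels x ", ncol(x$samples),
      " samples @ ", x$rate, " Hz (subject ", x$subject_id, ", label ",
      x$label, ")\n", sep = "")
  invisible(x)
}

#' Downsample a recording with anti-aliasing
#'
#' Integer rate ratios are decimated (low-pass anti-alias filter, then
#' subsampling); non-integer ratios go through rational polyphase resampling.
#' The output length is `floor(n * target_rate / rate)` and the output
#' Nyquist frequency is `target_rate / 2`.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate target sampling rate in Hz, default 200.
#' @return The resampled [eeg_recording()].
#' @export
resample_to_target <- function(rec, target_rate = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate)
    stop("upsampling refused: target rate ", target_rate,
         " Hz exceeds the recording rate ", rec$rate, " Hz")
  if (target_rate == rec$rate) return(rec)
  n_in <- ncol(rec$samples)
  n_out <- floor(n_in * target_rate / rec$rate)
  ratio <- rec$rate / target_rate
  out <- if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    # anti-alias low-pass at 80% of the target Nyquist, zero-phase with
    # reflection padding, then keep every q-th sample
    lp <- signal::butter(8, 0.8 / q, type = "low")
    t(apply(rec$samples, 1, function(x)
      .zero_phase(lp, x)[seq(1, by = q, length.out = n_out)]))
  } else {
    frac <- .as_rational(target_rate / rec$rate)
    t(apply(rec$samples, 1, function(x) {
      y <- signal::resample(x, frac[1], frac[2])
      length(y) <- n_out            # pad/trim to the floor-length contract
      y[is.na(y)] <- 0
      y
    }))
  }
  rownames(out) <- rec$channel_names
  rec$samples <- out
  rec$rate <- target_rate
  rec
}

# forward-backward filtering with reflection padding to suppress edge
# transients (the plain reverse-filter trick starts from zero state)
.zero_phase <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, 1000L)
  xp <- c(2 * x[1] - x[1 + rev(seq_len(pad))], x, 2 * x[n] - x[n - seq_len(pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + n)]
}

.as_rational <- function(x, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("rate ratio ", x, " has no small rational form")
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass (default 0.5-50 Hz) applied
#' forward-backward so the effective response is 8th order with zero phase
#' shift, preserving segment alignment.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz.
#' @param order filter order of the one-way design, default 4.
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(rec, low = 0.5, high = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (high >= nyq)
    stop("upper band edge ", high, " Hz must be below the Nyquist frequency ",
         nyq, " Hz")
  if (low <= 0 || low >= high) stop("require 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$samples, 1, function(x) .zero_phase(bf, x)))
  rownames(out) <- rec$channel_names
  rec$samples <- out
  rec
}

#' Cut a 200 Hz recording into non-overlapping 4-second windows
#'
#' Produces `floor(n_samples / (window * rate))` blocks of exactly
#' `window * rate` samples (800 at the default 4 s and 200 Hz); any trailing
#' remainder is discarded. A recording shorter than one window yields an
#' empty segmentation with a warning.
#'
#' @param rec an [eeg_recording()] already at 200 Hz.
#' @param window window length in seconds, default 4.
#' @return An object of class `segmented_recording`: list with `segments`
#'   (list of channels x 800 matrices, in temporal order), `rate`, and the
#'   inherited provenance fields.
#' @export
segment <- function(rec, window = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != 200)
    stop("segmentation expects a 200 Hz recording; call resample_to_target() first")
  len <- as.integer(window * rec$rate)
  n_seg <- floor(ncol(rec$samples) / len)
  if (n_seg == 0)
    warning("recording shorter than one ", window, " s window; no segments")
  segs <- lapply(seq_len(n_seg), function(i)
    rec$samples[, ((i - 1) * len + 1):(i * len), drop = FALSE])
  structure(list(segments = segs, rate = rec$rate,
                 channel_names = rec$channel_names,
                 subject_id = rec$subject_id, session_id = rec$session_id,
                 video_id = rec$video_id, label = rec$label),
            class = "segmented_recording")
}

#' Full conditioning pipeline for one recording
#'
#' Downsample to `target_rate`, band-pass filter, and segment, in that order.
#'
#' @inheritParams resample_to_target
#' @inheritParams bandpass
#' @inheritParams segment
#' @return A `segmented_recording`.
#' @export
preprocess_recording <- function(rec, target_rate = 200, low = 0.5, high = 50,
                                 window = 4) {
  segment(bandpass(resample_to_target(rec, target_rate), low, high), window)
}
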