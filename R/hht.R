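#' Hilbert-Huang spectral features
#'
#' Each 4-second window is summarized per channel by its marginal Hilbert
#' spectrum: the signal is decomposed into intrinsic mode functions (IMFs) by
#' empirical mode decomposition (EMD), the analytic signal of each IMF gives
#' instantaneous frequency and squared amplitude, and the squared amplitudes
#' are accumulated into fifty 1 Hz bins spanning 0-50 Hz (bin j covers
#' [j, j+1) Hz, center j + 0.5). The per-window result is a channels x 50
#' nonnegative power matrix; windows are stacked and zero-padded into
#' per-video and per-subject tensors.
#'
#' @name hht_features
NULL

# local extrema indices of a vector (strict sign changes of the derivative;
# plateaus collapse to their midpoint)
.local_extrema <- function(x) {
  dx <- diff(x)
  nz <- which(dx != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  # compress plateaus: signs of consecutive non-zero slopes
  s <- sign(dx[nz])
  chg <- which(diff(s) != 0)
  idx <- vapply(chg, function(j) {
    # extremum lies between end of slope nz[j] and start of slope nz[j+1]
    as.integer(round((nz[j] + 1 + nz[j + 1]) / 2))
  }, integer(1))
  list(max = idx[s[chg] > 0], min = idx[s[chg] < 0])
}

# cubic-spline envelope through extrema, with boundary extrema mirrored past
# the signal ends to suppress end swings
.envelope <- function(x, idx) {
  n <- length(x)
  t <- idx
  v <- x[idx]
  if (length(idx) >= 2) {
    t <- c(2 - rev(idx[seq_len(min(2, length(idx)))]),
           t,
           2 * n - rev(rev(idx)[seq_len(min(2, length(idx)))]))
    v <- c(rev(v[seq_len(min(2, length(v)))]),
           v,
           rev(rev(v)[seq_len(min(2, length(v)))]))
    keep <- !duplicated(t)
    t <- t[keep]; v <- v[keep]
  }
  stats::spline(t, v, xout = seq_len(n), method = "natural")$y
}

#' Empirical mode decomposition
#'
#' Standard EMD with cubic-spline envelopes and a Cauchy-type sifting stop
#' (relative change below `sift_tol`, at most `max_sift` sifts per IMF).
#' Decomposition stops when the residual is monotone (fewer than two maxima
#' or two minima) or `max_imf` IMFs have been extracted.
#'
#' @param x numeric vector.
#' @param max_imf maximum number of IMFs, default 10.
#' @param max_sift maximum sifting iterations per IMF, default 12.
#' @param sift_tol Cauchy stopping tolerance, default 0.05.
#' @return List with `imfs` (matrix, one IMF per row; zero rows if `x` has no
#'   oscillation) and `residual`.
#' @export
emd <- function(x, max_imf = 10, max_sift = 12, sift_tol = 0.05) {
  if (!all(is.finite(x))) stop("emd: input contains non-finite values")
  n <- length(x)
  res <- x
  imfs <- list()
  for (k in seq_len(max_imf)) {
    ex <- .local_extrema(res)
    if (length(ex$max) < 2 || length(ex$min) < 2) break
    h <- res
    for (s in seq_len(max_sift)) {
      ex_h <- .local_extrema(h)
      if (length(ex_h$max) < 2 || length(ex_h$min) < 2) break
      m <- (.envelope(h, ex_h$max) + .envelope(h, ex_h$min)) / 2
      h_new <- h - m
      dh <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (dh < sift_tol) break
    }
    imfs[[k]] <- h
    res <- res - h
  }
  imf_mat <- if (length(imfs)) do.call(rbind, imfs) else
    matrix(numeric(0), 0, n)
  list(imfs = imf_mat, residual = res)
}

#' Analytic signal via the FFT
#'
#' @param x numeric vector.
#' @return Complex vector `x + i * H(x)` with `H` the Hilbert transform.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Marginal Hilbert power spectrum of one window
#'
#' For each channel of a 200 Hz segment: EMD into IMFs, analytic signal per
#' IMF, instantaneous frequency by forward-differencing the unwrapped phase
#' (clipped to [0, 100] Hz for robustness to phase noise), and squared
#' amplitude accumulated into the 1 Hz bins of [0, 50); samples whose
#' instantaneous frequency falls outside [0, 50) are discarded. A channel
#' with no oscillation (EMD yields no IMF) produces a zero row with a
#' warning.
#'
#' @param segment numeric matrix, channels x samples (800 samples at 200 Hz
#'   for the standard 4-second window).
#' @param rate sampling rate in Hz, default 200.
#' @param n_bins number of 1 Hz bins, default 50.
#' @param ... passed to [emd()].
#' @return `spectral_window`: channels x `n_bins` nonnegative matrix with
#'   attribute `bin_centers` (0.5, 1.5, ..., 49.5 Hz).
#' @export
hht_psd <- function(segment, rate = 200, n_bins = 50, ...) {
  segment <- as.matrix(segment)
  if (!all(is.finite(segment))) stop("hht_psd: non-finite input")
  out <- matrix(0, nrow(segment), n_bins,
                dimnames = list(rownames(segment), NULL))
  flat <- character(0)
  for (ch in seq_len(nrow(segment))) {
    dec <- emd(segment[ch, ], ...)
    if (nrow(dec$imfs) == 0) {
      if (any(segment[ch, ] != segment[ch, 1])) flat <- c(flat, as.character(ch))
      next
    }
    acc <- numeric(n_bins)
    for (k in seq_len(nrow(dec$imfs))) {
      z <- analytic_signal(dec$imfs[k, ])
      phase <- .unwrap_phase(Arg(z))
      f <- diff(phase) * rate / (2 * pi)
      # snap to a 1e-6 Hz grid so boundary frequencies bin deterministically
      f <- round(pmin(pmax(f, 0), 100), 6)
      a2 <- Mod(z)[-length(z)]^2
      keep <- f >= 0 & f < n_bins
      if (any(keep)) {
        b <- floor(f[keep]) + 1L
        acc <- acc + as.numeric(
          tabulate_weighted(b, a2[keep], n_bins))
      }
    }
    out[ch, ] <- acc
  }
  if (length(flat))
    warning("EMD produced no IMF for channel(s) ", paste(flat, collapse = ", "),
            "; zero power row(s) emitted")
  structure(out, bin_centers = seq_len(n_bins) - 0.5, class = "spectral_window")
}

.unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# weighted bin counts (rowsum on a dense index)
tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Spectral features for a segmented recording
#'
#' Applies [hht_psd()] to every 4-second window.
#'
#' @param seg a `segmented_recording` from [segment()].
#' @param ... passed to [hht_psd()].
#' @return List of `spectral_window` matrices, in temporal order.
#' @export
spectral_windows <- function(seg, ...) {
  stopifnot(inherits(seg, "segmented_recording"))
  lapply(seg$segments, hht_psd, rate = seg$rate, ...)
}

#' Stack a video's windows into a zero-padded tensor
#'
#' @param windows list of channels x freq matrices in temporal order.
#' @param w_pad padded window count (>= number of windows).
#' @param label emotion label carried with the tensor.
#' @return `video_tensor`: list with `data` (array w_pad x channels x freqs),
#'   `n_real_windows`, `label`.
#' @export
assemble_video_tensor <- function(windows, w_pad, label = NA) {
  n <- length(windows)
  if (n < 1) stop("need at least one window")
  if (n > w_pad)
    stop("video has ", n, " windows but w_pad = ", w_pad,
         "; increase the padding length to at least ", n)
  dims <- dim(as.matrix(windows[[1]]))
  arr <- array(0, c(w_pad, dims[1], dims[2]))
  for (i in seq_len(n)) arr[i, , ] <- as.matrix(windows[[i]])
  structure(list(data = arr, n_real_windows = n, label = label),
            class = "video_tensor")
}

#' Stack a subject's video tensors
#'
#' @param videos list of `video_tensor` objects sharing one `w_pad`.
#' @param subject_id identifier carried with the tensor.
#' @return `subject_tensor`: list with `data` (videos x w x channels x
#'   freqs), `labels`, `n_real_windows`, `subject_id`.
#' @export
assemble_subject_tensor <- function(videos, subject_id = NA) {
  if (length(videos) == 0) stop("empty video list")
  w_pads <- vapply(videos, function(v) dim(v$data)[1], numeric(1))
  if (length(unique(w_pads)) > 1)
    stop("mixed padding lengths: ", paste(unique(w_pads), collapse = ", "))
  d <- dim(videos[[1]]$data)
  arr <- array(0, c(length(videos), d))
  for (i in seq_along(videos)) arr[i, , , ] <- videos[[i]]$data
  structure(list(data = arr,
                 labels = vapply(videos, function(v) v$label, numeric(1)),
                 n_real_windows = vapply(videos, function(v) v$n_real_windows,
                                         numeric(1)),
                 subject_id = subject_id),
            class = "subject_tensor")
}

#' Padding length implied by a set of per-recording window counts
#'
#' The padding convention stacks every video to the maximum observed window
#' count, so no recording is truncated.
#'
#' @param counts integer vector of per-recording 4-second window counts.
#' @return `max(counts)`.
#' @export
infer_pad_length <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  max(counts)
}
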