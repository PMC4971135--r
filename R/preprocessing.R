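# Pre-emphasis, framing, windowing, band analysis and cry-unit splitting.

#' Pre-emphasize a signal
#'
#' First-order high-pass FIR filter `P(z) = 1 - coeff * z^-1`, applied before
#' feature extraction to compensate the spectral tilt of the glottal source.
#' The first sample passes through unfiltered (`y[1] = x[1]`).
#'
#' @param signal a mono [audio_signal()].
#' @param coeff filter coefficient in `[0, 1)`; default 0.97.
#' @return pre-emphasized [audio_signal()] of the same length.
#' @export
pre_emphasize <- function(signal, coeff = 0.97) {
  if (coeff < 0 || coeff >= 1) stop("coeff must be in [0, 1)")
  x <- signal$samples
  if (is.matrix(x)) stop("pre_emphasize expects a mono signal")
  y <- x - coeff * c(0, x[-length(x)])
  y[1L] <- x[1L]
  audio_signal(y, signal$sample_rate)
}

#' Cut a mono signal into overlapping frames
#'
#' Frame length is `round(frame_ms * fs / 1000)` samples; the hop is
#' `round(L * (1 - overlap_frac))`. Trailing samples that do not fill a frame
#' are dropped; a signal shorter than one frame yields zero frames.
#'
#' @param signal mono [audio_signal()].
#' @param frame_ms frame duration in milliseconds (10 or 30 in typical use).
#' @param overlap_frac fractional overlap between consecutive frames, in
#'   `[0, 1)`; default 0.30.
#' @return A `frame_sequence`: list with `frames` (N x L matrix), `L`, `hop`,
#'   `frame_ms`, `overlap_frac`, `sample_rate`.
#' @export
frame_signal <- function(signal, frame_ms, overlap_frac = 0.30) {
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  x <- signal$samples
  if (is.matrix(x)) stop("frame_signal expects a mono signal")
  fs <- signal$sample_rate
  L <- round(frame_ms * fs / 1000)
  hop <- max(1L, round(L * (1 - overlap_frac)))
  n <- length(x)
  N <- if (n < L) 0L else (n - L) %/% hop + 1L
  frames <- if (N == 0L) matrix(numeric(0), nrow = 0L, ncol = L) else {
    idx <- outer(seq_len(L), (seq_len(N) - 1L) * hop, `+`)
    matrix(x[idx], nrow = N, ncol = L, byrow = TRUE)
  }
  structure(list(frames = frames, L = as.integer(L), hop = as.integer(hop),
                 frame_ms = frame_ms, overlap_frac = overlap_frac,
                 sample_rate = fs),
            class = "frame_sequence")
}

#' Hamming window of length L
#' @param L window length in samples.
#' @return numeric vector `0.54 - 0.46 * cos(2*pi*n/(L-1))`, n = 0..L-1.
#' @export
hamming_window <- function(L) {
  if (L == 1L) return(1)
  n <- 0:(L - 1L)
  0.54 - 0.46 * cos(2 * pi * n / (L - 1L))
}

#' Apply a Hamming window to every frame
#' @param frames a `frame_sequence` from [frame_signal()].
#' @return the `frame_sequence` with windowed frames.
#' @export
apply_hamming <- function(frames) {
  if (nrow(frames$frames) > 0L)
    frames$frames <- sweep(frames$frames, 2L, hamming_window(frames$L), `*`)
  frames
}

#' Cumulative power fraction across frequency
#'
#' Welch-averaged periodogram (Hamming-windowed segments of `seg_len` samples
#' with 50% overlap, zero-padded to `n_fft`), cumulatively summed over
#' frequency and normalized to end at 1. Used to locate the upper cutoff of
#' the band that carries most of the cry energy.
#'
#' @param signal mono, non-silent [audio_signal()].
#' @param n_fft FFT size (default 4096).
#' @param seg_len Welch segment length (default 1024).
#' @return A `band_analysis`: list with `freqs` (Hz) and
#'   `cumulative_fraction` (nondecreasing, ends at 1).
#' @export
cumulative_power_fraction <- function(signal, n_fft = 4096, seg_len = 1024) {
  x <- signal$samples
  if (is.matrix(x)) stop("expects a mono signal")
  fs <- signal$sample_rate
  if (length(x) < seg_len) seg_len <- length(x)
  hop <- max(1L, seg_len %/% 2L)
  w <- hamming_window(seg_len)
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  n_bins <- n_fft %/% 2L + 1L
  pxx <- numeric(n_bins)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    spec <- stats::fft(c(seg, numeric(n_fft - seg_len)))
    pxx <- pxx + Mod(spec[seq_len(n_bins)])^2
  }
  total <- sum(pxx)
  if (total <= 0) stop("zero-power signal")
  cf <- cumsum(pxx) / total
  structure(list(freqs = (seq_len(n_bins) - 1L) * fs / n_fft,
                 cumulative_fraction = cf),
            class = "band_analysis")
}

#' Frequency at which a target fraction of power is reached
#' @param analysis a `band_analysis` from [cumulative_power_fraction()].
#' @param fraction target cumulative power fraction in (0, 1].
#' @return cutoff frequency in Hz (smallest grid frequency reaching the
#'   fraction).
#' @export
band_cutoff <- function(analysis, fraction) {
  i <- which(analysis$cumulative_fraction >= fraction - 1e-12)[1L]
  analysis$freqs[i]
}

#' Split labeled segments into ~3-second cry units
#'
#' Each segment is tiled into consecutive non-overlapping chunks of `unit_s`
#' seconds; a trailing remainder shorter than `unit_s` is kept and flagged
#' `partial` (set `keep_partial = FALSE` to drop remainders). Unit indices
#' increment across the whole segment list.
#'
#' @param segments list of mono [audio_signal()] objects (one cry type).
#' @param unit_s unit duration target in seconds (default 3).
#' @param cry_type `"EXP"` or `"INSV"`, recorded on each unit.
#' @param source_file identifier recorded on each unit.
#' @param keep_partial keep trailing partial units? Default `TRUE`.
#' @return list of `cry_unit` objects: `audio`, `cry_type`, `source_file`,
#'   `unit_index`, `partial`.
#' @export
split_cry_units <- function(segments, unit_s = 3.0, cry_type = "EXP",
                            source_file = NA_character_, keep_partial = TRUE) {
  if (unit_s <= 0) stop("unit_s must be positive")
  units <- list()
  idx <- 0L
  for (seg in segments) {
    fs <- seg$sample_rate
    n <- length(seg$samples)
    per <- round(unit_s * fs)
    start <- 1L
    while (start <= n) {
      stop_i <- min(start + per - 1L, n)
      partial <- (stop_i - start + 1L) < per
      if (!partial || keep_partial) {
        units[[length(units) + 1L]] <- structure(
          list(audio = audio_signal(seg$samples[start:stop_i], fs),
               cry_type = cry_type, source_file = source_file,
               unit_index = idx, partial = partial),
          class = "cry_unit")
        idx <- idx + 1L
      }
      start <- stop_i + 1L
    }
  }
  units
}
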