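# MFCC front end: mel filterbank, cepstra, frame energy, delta/acceleration.

LOG_FLOOR <- 1e-10

#' Feature extraction configuration
#'
#' Defaults give the standard 39-dimensional front end: 12 mel cepstra from a
#' 24-filter bank over 0--4 kHz plus log frame energy, with first and second
#' time derivatives appended.
#'
#' @param n_filters number of triangular mel filters K (default 24).
#' @param n_cepstra number of cepstral coefficients M kept (default 12).
#' @param f_low,f_high filterbank band edges in Hz (defaults 0 and 4000; most
#'   cry energy lies below 4 kHz).
#' @param delta_window regression half-window for derivatives (default 2).
#' @param frame_ms frame duration in ms (default 10; 30 also common).
#' @param overlap_frac frame overlap fraction (default 0.30).
#' @param include_energy append log frame energy? Default `TRUE`.
#' @param preemphasis pre-emphasis coefficient (default 0.97).
#' @return a `feature_config` list.
#' @export
feature_config <- function(n_filters = 24L, n_cepstra = 12L, f_low = 0,
                           f_high = 4000, delta_window = 2L, frame_ms = 10,
                           overlap_frac = 0.30, include_energy = TRUE,
                           preemphasis = 0.97) {
  stopifnot(n_cepstra >= 1, n_cepstra < n_filters,
            f_low >= 0, f_high > f_low, delta_window >= 1)
  structure(list(n_filters = as.integer(n_filters),
                 n_cepstra = as.integer(n_cepstra),
                 f_low = f_low, f_high = f_high,
                 delta_window = as.integer(delta_window),
                 frame_ms = frame_ms, overlap_frac = overlap_frac,
                 include_energy = isTRUE(include_energy),
                 preemphasis = preemphasis),
            class = "feature_config")
}

#' @rdname mel_filterbank
#' @param f frequency in Hz.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname mel_filterbank
#' @param m mel value.
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' K triangular filters with unit peaks, centers equally spaced on the mel
#' scale between `f_low` and `f_high`, evaluated on the FFT bin grid.
#'
#' @param config a [feature_config()].
#' @param n_fft FFT size.
#' @param sample_rate sampling rate in Hz.
#' @return K x (n_fft/2 + 1) weight matrix; attribute `centers_hz` holds the
#'   filter center frequencies.
#' @export
mel_filterbank <- function(config, n_fft, sample_rate) {
  if (config$f_high > sample_rate / 2)
    stop("f_high exceeds the Nyquist frequency")
  K <- config$n_filters
  edges_mel <- seq(hz_to_mel(config$f_low), hz_to_mel(config$f_high),
                   length.out = K + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  fb <- matrix(0, nrow = K, ncol = n_bins)
  for (k in seq_len(K)) {
    lo <- edges_hz[k]; mid <- edges_hz[k + 1L]; hi <- edges_hz[k + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  structure(fb, centers_hz = edges_hz[2:(K + 1L)])
}

#' Mel cepstra from log filterbank energies
#'
#' The DCT `C_i = sum_k S_k * cos(i * (k - 1/2) * pi / K)`, i = 1..M, applied
#' literally with no orthonormal scaling (any constant is absorbed by the
#' downstream mixture models).
#'
#' @param S vector of K log filterbank energies, or an N x K matrix (one row
#'   per frame).
#' @param M number of cepstral coefficients to keep.
#' @return length-M vector, or N x M matrix for matrix input.
#' @export
mfcc_from_logfb <- function(S, M) {
  vec_in <- !is.matrix(S)
  if (vec_in) S <- matrix(S, nrow = 1L)
  K <- ncol(S)
  if (M > K) stop("M must not exceed the number of filters K")
  dct <- outer(seq_len(K) - 0.5, seq_len(M), function(k, i) cos(i * k * pi / K))
  C <- S %*% dct
  if (vec_in) drop(C) else C
}

#' Log frame energy
#'
#' `log(max(sum(frame^2), 1e-10))`; the floor keeps silent frames finite.
#'
#' @param frame numeric vector of samples, or an N x L matrix of frames.
#' @return scalar, or length-N vector for matrix input.
#' @export
frame_log_energy <- function(frame) {
  if (is.matrix(frame)) log(pmax(rowSums(frame^2), LOG_FLOOR))
  else log(max(sum(frame^2), LOG_FLOOR))
}

#' Delta (time-derivative) coefficients
#'
#' `D_n = sum_theta theta * (C_{n+theta} - C_{n-theta}) / (2 * sum_theta
#' theta^2)` per column, with the first and last rows replicated past the
#' boundaries. Applying it to its own output yields acceleration
#' coefficients.
#'
#' @param C T x d matrix of static parameters (a vector is treated as one
#'   column).
#' @param theta regression half-window (default 2).
#' @return matrix of the same shape as `C`.
#' @export
delta <- function(C, theta = 2L) {
  if (!is.matrix(C)) C <- matrix(C, ncol = 1L)
  T_ <- nrow(C)
  pad <- rbind(C[rep(1L, theta), , drop = FALSE], C,
               C[rep(T_, theta), , drop = FALSE])
  num <- matrix(0, nrow = T_, ncol = ncol(C))
  for (th in seq_len(theta)) {
    i <- seq_len(T_) + theta
    num <- num + th * (pad[i + th, , drop = FALSE] - pad[i - th, , drop = FALSE])
  }
  num / (2 * sum(seq_len(theta)^2))
}

#' Construct a feature sequence
#'
#' @param X T x D numeric matrix of feature vectors.
#' @param cry_type `"EXP"`, `"INSV"` or `NA`.
#' @param source_file,unit_index provenance identifiers.
#' @export
feature_sequence <- function(X, cry_type = NA_character_,
                             source_file = NA_character_, unit_index = NA_integer_) {
  if (!is.matrix(X)) X <- matrix(X, nrow = if (length(X)) 1L else 0L)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  structure(list(X = X, cry_type = cry_type, source_file = source_file,
                 unit_index = unit_index),
            class = "feature_sequence")
}

feature_names <- function(M, include_energy, with_deltas = TRUE) {
  base <- c(paste0("c", seq_len(M)), if (include_energy) "e")
  if (!with_deltas) return(base)
  d <- M + include_energy
  c(base, paste0("d", seq_len(d)), paste0("a", seq_len(d)))
}

#' Extract MFCC + delta + acceleration features from an audio segment
#'
#' Pipeline: pre-emphasis, framing, Hamming window, magnitude-squared FFT
#' (size = next power of two >= frame length), triangular mel filterbank,
#' floored log, DCT to M cepstra, log frame energy, then delta and
#' delta-delta columns. With defaults this yields 39 columns per frame
#' (12 MFCC + energy, and their first and second derivatives).
#'
#' @param segment mono [audio_signal()].
#' @param config a [feature_config()].
#' @param cry_type,source_file,unit_index provenance recorded on the result.
#' @return a [feature_sequence()]; `T = 0` rows if the segment is shorter
#'   than one frame.
#' @export
extract_features <- function(segment, config = feature_config(),
                             cry_type = NA_character_,
                             source_file = NA_character_,
                             unit_index = NA_integer_) {
  fs <- segment$sample_rate
  y <- pre_emphasize(segment, config$preemphasis)
  fr <- frame_signal(y, config$frame_ms, config$overlap_frac)
  M <- config$n_cepstra
  D <- (M + config$include_energy) * 3L
  if (nrow(fr$frames) == 0L) {
    X <- matrix(numeric(0), nrow = 0L, ncol = D,
                dimnames = list(NULL, feature_names(M, config$include_energy)))
    return(feature_sequence(X, cry_type, source_file, unit_index))
  }
  fr <- apply_hamming(fr)
  n_fft <- 2^ceiling(log2(fr$L))
  n_bins <- n_fft %/% 2L + 1L
  padded <- cbind(fr$frames, matrix(0, nrow(fr$frames), n_fft - fr$L))
  spec <- Mod(stats::mvfft(t(padded)))^2        # n_fft x N
  pow <- t(spec[seq_len(n_bins), , drop = FALSE])  # N x n_bins
  fb <- mel_filterbank(config, n_fft, fs)
  S <- log(pmax(pow %*% t(fb), LOG_FLOOR))
  C <- mfcc_from_logfb(S, M)
  static <- if (config$include_energy) cbind(C, frame_log_energy(fr$frames)) else C
  d1 <- delta(static, config$delta_window)
  d2 <- delta(d1, config$delta_window)
  X <- cbind(static, d1, d2)
  colnames(X) <- feature_names(M, config$include_energy)
  feature_sequence(X, cry_type, source_file, unit_index)
}

#' Write/read a feature sequence as CSV
#'
#' One row per frame; a sidecar JSON (same path with extension `.json`)
#' stores the provenance and configuration.
#'
#' @param fseq a [feature_sequence()].
#' @param path CSV output path.
#' @param config optional [feature_config()] stored in the sidecar.
#' @export
write_features <- function(fseq, path, config = NULL) {
  utils::write.csv(as.data.frame(fseq$X), path, row.names = FALSE)
  meta <- list(cry_type = fseq$cry_type, source_file = fseq$source_file,
               unit_index = fseq$unit_index, config = config)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  X <- as.matrix(utils::read.csv(path))
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  feature_sequence(X,
                   cry_type = meta$cry_type %||% NA_character_,
                   source_file = meta$source_file %||% NA_character_,
                   unit_index = meta$unit_index %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
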