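# Audio, segment-label and manifest I/O for cry corpora.

#' Segment label vocabulary
#'
#' The 13 segment classes that may appear in a label file: voiced expiration
#' (EXP) and inspiration (INSV) are the units used for modelling; the rest
#' mark unvoiced, noisy or non-cry material that is skipped.
#'
#' @export
CRY_LABELS <- c("EXP", "EXPN", "INS", "INSV", "EXP2", "INS2", "PSEUDOCRY",
                "Speech", "Background", "NoisyCry", "NoisyPseudoCry",
                "Noise", "BIP")

#' Health-condition categories
#'
#' @export
HEALTH_CLASSES <- c("Healthy", "Heart", "Neurological", "Respiratory",
                    "Blood", "Other")

#' Construct an audio signal
#'
#' @param samples numeric vector (mono) or matrix with one column per channel,
#'   amplitudes nominally in [-1, 1].
#' @param sample_rate sampling rate in Hz (positive integer).
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `n_channels`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (is.matrix(samples)) {
    n_channels <- ncol(samples)
    if (n_channels == 1L) samples <- drop(samples)
  } else {
    samples <- as.numeric(samples)
    n_channels <- 1L
  }
  n <- if (is.matrix(samples)) nrow(samples) else length(samples)
  if (n == 0L) stop("audio signal must contain at least one sample")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive number")
  structure(list(samples = samples, sample_rate = as.integer(sample_rate),
                 n_channels = as.integer(n_channels)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  cat(sprintf("<audio_signal: %d samples, %d Hz, %d channel(s), %.3f s>\n",
              n, x$sample_rate, x$n_channels, n / x$sample_rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal an `audio_signal`.
#' @export
audio_duration <- function(signal) {
  n <- if (is.matrix(signal$samples)) nrow(signal$samples) else length(signal$samples)
  n / signal$sample_rate
}

# -- WAV ---------------------------------------------------------------------

read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

int24_to_int <- function(raw_bytes) {
  # little-endian signed 24-bit triples -> integer
  m <- matrix(as.integer(raw_bytes), nrow = 3L)
  v <- m[1L, ] + m[2L, ] * 256L + m[3L, ] * 65536L
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Read a PCM WAV file
#'
#' Supports 16/24/32-bit integer PCM and 32-bit float payloads at any
#' sampling rate. Integer samples are scaled to floats by the usual
#' 2^(bits-1) convention, so 16-bit silence reads back as exactly 0.
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE payload: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr)) break
    if (hdr$id == "fmt ") {
      body <- readBin(con, "raw", hdr$size)
      u16 <- function(i) sum(as.integer(body[i:(i + 1L)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(body[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
      fmt <- list(audio_format = u16(1L), n_channels = u16(3L),
                  sample_rate = u32(5L), bits = u16(15L))
    } else if (hdr$id == "data") {
      data_raw <- readBin(con, "raw", hdr$size)
    } else {
      readBin(con, "raw", hdr$size + hdr$size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported (compressed?) WAV format code ", fmt$audio_format)

  bits <- fmt$bits
  x <- if (fmt$audio_format == 3L && bits == 32L) {
    readBin(data_raw, "numeric", length(data_raw) / 4L, size = 4L,
            endian = "little")
  } else if (bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, size = 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (bits == 24L) {
    int24_to_int(data_raw) / 8388608
  } else if (bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4L, size = 4L,
            endian = "little") / 2147483648
  } else stop("unsupported PCM bit depth: ", bits)

  nc <- fmt$n_channels
  if (nc > 1L) x <- matrix(x, ncol = nc, byrow = TRUE)  # interleaved frames
  audio_signal(x, fmt$sample_rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  x <- signal$samples
  if (is.matrix(x)) x <- as.vector(t(x))  # interleave channels
  q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  n_bytes <- length(q) * 2L
  nc <- signal$n_channels
  fs <- signal$sample_rate
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(nc, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * nc * 2L), con, size = 4L, endian = "little")
  writeBin(as.integer(nc * 2L), con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}

#' Mix a multi-channel signal down to mono
#'
#' Each output sample is the arithmetic mean across channels; a mono input is
#' returned unchanged, so the operation is idempotent.
#'
#' @param signal an [audio_signal()].
#' @return a mono [audio_signal()].
#' @export
to_mono <- function(signal) {
  if (signal$n_channels == 1L) return(signal)
  audio_signal(rowMeans(signal$samples), signal$sample_rate)
}

# -- segment labels ----------------------------------------------------------

validate_segment_labels <- function(df) {
  bad <- setdiff(unique(df$label), CRY_LABELS)
  if (length(bad) > 0L)
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  if (any(df$start_s < 0) || any(df$end_s <= df$start_s))
    stop("segment labels must satisfy 0 <= start_s < end_s")
  df <- df[order(df$start_s), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9))
    stop("overlapping segment labels are not allowed")
  rownames(df) <- NULL
  df
}

#' Read an Audacity-style segment label file
#'
#' Tab-separated lines of `start_s<TAB>end_s<TAB>label`. Labels are validated
#' against [CRY_LABELS], checked for overlap, and returned sorted by start
#' time.
#'
#' @param path label file path.
#' @return data frame with columns `start_s`, `end_s`, `label`.
#' @export
read_segment_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed label line (need 3 tab-separated fields)")
  df <- data.frame(start_s = as.numeric(vapply(parts, `[[`, "", 1L)),
                   end_s = as.numeric(vapply(parts, `[[`, "", 2L)),
                   label = trimws(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  validate_segment_labels(df)
}

#' Write a segment label file
#' @param labels data frame with `start_s`, `end_s`, `label`.
#' @param path output path.
#' @export
write_segment_labels <- function(labels, path) {
  lines <- sprintf("%.6f\t%.6f\t%s", labels$start_s, labels$end_s, labels$label)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a cry recording
#'
#' @param audio an [audio_signal()].
#' @param labels segment-label data frame (see [read_segment_labels()]).
#' @param health_class one of [HEALTH_CLASSES].
#' @param infant_id non-empty identifier of the infant.
#' @export
cry_recording <- function(audio, labels, health_class, infant_id) {
  if (!health_class %in% HEALTH_CLASSES)
    stop("unknown health class: ", health_class)
  if (!nzchar(infant_id)) stop("infant_id must be non-empty")
  labels <- validate_segment_labels(labels)
  dur <- audio_duration(audio)
  if (nrow(labels) > 0L && any(labels$end_s > dur + 1e-9))
    stop("segment label extends past end of recording")
  structure(list(audio = audio, labels = labels,
                 health_class = health_class, infant_id = infant_id),
            class = "cry_recording")
}

#' Extract the audio of all segments with a given label
#'
#' Slices use half-open sample intervals `[round(start * fs), round(end * fs))`
#' so adjacent segments never share a boundary sample.
#'
#' @param recording a [cry_recording()].
#' @param target segment label to extract, typically `"EXP"` or `"INSV"`.
#' @return list of mono [audio_signal()] objects (empty if no match).
#' @export
extract_segments <- function(recording, target) {
  audio <- to_mono(recording$audio)
  fs <- audio$sample_rate
  hits <- recording$labels[recording$labels$label == target, , drop = FALSE]
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    a <- round(hits$start_s[i] * fs) + 1L
    b <- round(hits$end_s[i] * fs)
    out[[i]] <- audio_signal(audio$samples[a:b], fs)
  }
  out
}

# -- corpus manifest ---------------------------------------------------------

#' Read and validate a corpus manifest
#'
#' CSV with header `wav,labels,health_class,infant_id,split`. The split tag is
#' one of `ubm`, `adapt`, `test`; every infant must appear in exactly one
#' split so no infant contributes to both model building and testing.
#'
#' @param path manifest CSV path.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest manifest data frame to validate.
#' @export
validate_manifest <- function(manifest) {
  need <- c("wav", "labels", "health_class", "infant_id", "split")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0L) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!all(manifest$split %in% c("ubm", "adapt", "test")))
    stop("split tags must be one of ubm/adapt/test")
  if (!all(manifest$health_class %in% HEALTH_CLASSES))
    stop("unknown health class in manifest")
  tab <- unique(manifest[, c("infant_id", "split")])
  dup <- tab$infant_id[duplicated(tab$infant_id)]
  if (length(dup) > 0L)
    stop("infant(s) present in more than one split: ",
         paste(unique(dup), collapse = ", "))
  manifest
}

#' Write a corpus manifest CSV
#' @param manifest manifest data frame.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(validate_manifest(manifest), path, row.names = FALSE)
  invisible(path)
}
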