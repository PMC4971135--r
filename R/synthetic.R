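# Synthetic cry corpora: feature-space (GMM-sampled) and audio-space
# (glottal-pulse/formant synthesis) generators with a single class-separation
# knob, so every stage of the toolchain is testable without clinical data.

#' Sample frames from a GMM
#'
#' T independent draws: a component by the mixture weights, then the diagonal
#' Gaussian.
#'
#' @param gmm a [gmm_params()] model.
#' @param T_ number of frames.
#' @param seed RNG seed.
#' @return T x D matrix.
#' @export
sample_gmm <- function(gmm, T_, seed = NULL) {
  if (T_ < 1L) stop("T must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  K <- n_components(gmm); D <- ncol(gmm$means)
  comp <- sample.int(K, T_, replace = TRUE, prob = gmm$weights)
  Z <- matrix(stats::rnorm(T_ * D), T_, D)
  gmm$means[comp, , drop = FALSE] + Z * sqrt(gmm$variances[comp, , drop = FALSE])
}

#' Derive separated class models from a base model
#'
#' Each class model is the base model with a seeded random unit direction per
#' component, scaled by `delta * sqrt(variance)`, added to the means. With
#' `delta = 0` every class model equals the base model; growing `delta`
#' increases class separation monotonically.
#'
#' @param ubm base [gmm_params()] model.
#' @param delta mean-shift magnitude in per-dimension standard deviations.
#' @param n_classes number of class models to derive.
#' @param seed RNG seed.
#' @return list of [gmm_params()] models.
#' @export
make_class_models <- function(ubm, delta, n_classes, seed = 1L) {
  if (delta < 0) stop("delta must be nonnegative")
  set.seed(seed)
  K <- n_components(ubm); D <- ncol(ubm$means)
  lapply(seq_len(n_classes), function(ci) {
    m <- ubm
    for (k in seq_len(K)) {
      u <- stats::rnorm(D)
      u <- u / sqrt(sum(u^2))
      m$means[k, ] <- m$means[k, ] + delta * sqrt(ubm$variances[k, ]) * u
    }
    m$tag <- paste0("synthetic_class_", ci)
    m
  })
}

#' Parameters for synthetic cry audio
#'
#' Newborn cries are voiced sounds with a high fundamental (around 450 Hz for
#' a healthy full-term infant) shaped by vocal-tract resonances; inspiratory
#' sounds are shorter, quieter and breathier. These parameters drive a
#' source-filter synthesizer adequate for exercising the DSP front end — they
#' make no claim of clinical realism.
#'
#' @param f0_hz fundamental frequency in Hz (default 450).
#' @param formants_hz vector of formant frequencies (defaults 1100, 3300).
#' @param jitter fractional period perturbation (default 0.01).
#' @param shimmer fractional amplitude perturbation (default 0.05).
#' @param noise_snr_db additive white-noise SNR in dB (default 15; `Inf`
#'   for clean).
#' @param breathiness fraction of aspiration noise mixed into the source
#'   (default 0.05 for expiration; inspiration units use a higher value).
#' @return a `synthetic_audio_params` list.
#' @export
synthetic_audio_params <- function(f0_hz = 450, formants_hz = c(1100, 3300),
                                   jitter = 0.01, shimmer = 0.05,
                                   noise_snr_db = 15, breathiness = 0.05) {
  structure(list(f0_hz = f0_hz, formants_hz = formants_hz, jitter = jitter,
                 shimmer = shimmer, noise_snr_db = noise_snr_db,
                 breathiness = breathiness),
            class = "synthetic_audio_params")
}

resonator <- function(x, f, bw, fs) {
  # two-pole resonator at frequency f, bandwidth bw
  r <- exp(-pi * bw / fs)
  a1 <- -2 * r * cos(2 * pi * f / fs)
  a2 <- r^2
  stats::filter(x, filter = c(-a1, -a2), method = "recursive")
}

#' Synthesize a cry-like waveform
#'
#' Glottal pulse train at the fundamental with jitter (period perturbation)
#' and shimmer (amplitude perturbation), mixed with aspiration noise, passed
#' through two-pole formant resonators and an amplitude envelope, with
#' additive white noise at the stated SNR.
#'
#' @param params a [synthetic_audio_params()].
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @return an [audio_signal()] with peak amplitude 0.8.
#' @export
synth_cry_audio <- function(params, duration_s, fs = 44100, seed = NULL) {
  if (duration_s <= 0) stop("duration must be positive")
  if (params$f0_hz >= fs / 4) stop("f0 too high for the sampling rate")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  src <- numeric(n)
  pos <- 1
  while (pos <= n) {
    src[ceiling(pos)] <- 1 * (1 + params$shimmer * stats::rnorm(1))
    period <- fs / params$f0_hz * (1 + params$jitter * stats::rnorm(1))
    pos <- pos + max(period, 2)
  }
  if (params$breathiness > 0)
    src <- (1 - params$breathiness) * src +
      params$breathiness * stats::rnorm(n, sd = stats::sd(src))
  y <- src
  for (i in seq_along(params$formants_hz))
    y <- as.numeric(resonator(y, params$formants_hz[i], 80 + 40 * i, fs))
  t <- seq_len(n) / n
  y <- y * sqrt(pmin(t, 1 - t, 0.1) / 0.1)      # attack/decay envelope
  if (is.finite(params$noise_snr_db)) {
    sig_p <- mean(y^2)
    noise_sd <- sqrt(sig_p / 10^(params$noise_snr_db / 10))
    y <- y + stats::rnorm(n, sd = noise_sd)
  }
  audio_signal(0.8 * y / max(abs(y)), fs)
}

#' Specification of a synthetic cry corpus
#'
#' Defaults emulate the structure of a two-class (healthy vs. respiratory)
#' corpus at desk scale: infant-disjoint UBM/adaptation/test splits, a few
#' recordings per infant, expiratory segments several times longer than
#' inspiratory ones, and some recordings lacking inspiration entirely.
#' Feature frames correspond to 10-ms frames with 30% overlap (142 frames per
#' second), so a full 3-s cry unit holds 427 frames.
#'
#' @param class_names class labels, first entry the healthy class (default
#'   `c("Healthy", "Respiratory")`).
#' @param n_infants named vector: infants per class in each split (default
#'   ubm 12, adapt 12, test 20).
#' @param recordings_per_infant recordings per infant (default 2).
#' @param exp_range total expiration seconds per recording, min/max of a
#'   uniform draw (default 2--12 s).
#' @param insv_range total inspiration seconds per recording (default
#'   0.5--5 s).
#' @param p_insv probability a recording contains any inspiration (default
#'   0.85).
#' @param separation class separation `delta` in per-dimension standard
#'   deviations (default 1.5).
#' @param noise_level standard deviation of additive feature-space noise
#'   emulating NICU recording noise, relative to the per-dimension model
#'   standard deviation (default 0.25).
#' @param infant_sd standard deviation of a per-infant random mean offset,
#'   relative to the per-dimension model standard deviation (default 0.75).
#'   Infant-disjoint splits mean a detector is always evaluated on unseen
#'   infants, so between-infant variability is what makes the test split a
#'   generalization test rather than a re-identification test.
#' @param feature_dim feature dimension (default 39).
#' @param base_K components of the generating base mixture (default 4).
#' @param frames_per_s feature frames per second (default 142).
#' @param unit_s cry unit duration in seconds (default 3).
#' @param seed corpus seed; fixed seed gives a bit-reproducible corpus.
#' @return a `synthetic_corpus_spec` list.
#' @export
synthetic_corpus_spec <- function(class_names = c("Healthy", "Respiratory"),
                                  n_infants = c(ubm = 12L, adapt = 12L,
                                                test = 20L),
                                  recordings_per_infant = 2L,
                                  exp_range = c(2, 12),
                                  insv_range = c(0.5, 5), p_insv = 0.85,
                                  separation = 1.5, noise_level = 0.25,
                                  infant_sd = 0.75,
                                  feature_dim = 39L, base_K = 4L,
                                  frames_per_s = 142, unit_s = 3.0,
                                  seed = 1L) {
  stopifnot(length(class_names) >= 2L, separation >= 0, infant_sd >= 0,
            all(exp_range > 0), all(insv_range > 0),
            all(class_names %in% HEALTH_CLASSES))
  structure(list(class_names = class_names, n_infants = n_infants,
                 recordings_per_infant = as.integer(recordings_per_infant),
                 exp_range = exp_range, insv_range = insv_range,
                 p_insv = p_insv, separation = separation,
                 noise_level = noise_level, infant_sd = infant_sd,
                 feature_dim = as.integer(feature_dim),
                 base_K = as.integer(base_K), frames_per_s = frames_per_s,
                 unit_s = unit_s, seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

random_base_gmm <- function(K, D) {
  w <- stats::rgamma(K, 5); w <- w / sum(w)
  gmm_params(w, matrix(stats::rnorm(K * D, sd = 1.5), K, D),
             matrix(stats::runif(K * D, 0.5, 1.5), K, D),
             tag = "synthetic_base")
}

split_duration_into_units <- function(total_s, unit_s) {
  full <- floor(total_s / unit_s)
  rem <- total_s - full * unit_s
  durs <- rep(unit_s, full)
  if (rem > 0.05) durs <- c(durs, rem)
  durs
}

#' Generate a synthetic cry corpus
#'
#' In `feature` mode each cry unit is a matrix of frames sampled from the
#' recording's class model (the base model shifted by the separation knob,
#' see [make_class_models()]) with additive Gaussian feature noise; the
#' corpus is returned in memory and optionally written to `out_dir` (one
#' feature CSV per recording plus a manifest). In `audio` mode each recording
#' is a WAV file with an Audacity-style label file, where the class shifts
#' the fundamental and first formant; `out_dir` is required.
#'
#' @param spec a [synthetic_corpus_spec()].
#' @param mode `"feature"` or `"audio"`.
#' @param out_dir output directory (optional in feature mode).
#' @return a `cry_corpus` list with `manifest`, `units` (feature mode: named
#'   by file_id, each a list of `features` ([feature_sequence()] objects) and
#'   `partial` flags), `class_models`, `base_model` and `spec`.
#' @export
make_corpus <- function(spec, mode = c("feature", "audio"), out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "audio" && is.null(out_dir))
    stop("audio mode requires out_dir")
  set.seed(spec$seed)
  classes <- spec$class_names
  base <- random_base_gmm(spec$base_K, spec$feature_dim)
  class_models <- make_class_models(base, spec$separation, length(classes),
                                    seed = spec$seed + 1L)
  names(class_models) <- classes

  manifest <- NULL
  units <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  sd_dim <- sqrt(colSums(base$weights * base$variances))
  infant_sd <- spec$infant_sd %||% 0
  rec_counter <- 0L
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (split in names(spec$n_infants)) {
      for (ii in seq_len(spec$n_infants[[split]])) {
        infant_id <- sprintf("%s_%s_i%02d", cls, split, ii)
        infant_offset <- if (infant_sd > 0)
          infant_sd * sd_dim * stats::rnorm(spec$feature_dim)
        else numeric(spec$feature_dim)
        for (ri in seq_len(spec$recordings_per_infant)) {
          rec_counter <- rec_counter + 1L
          file_id <- sprintf("rec%04d", rec_counter)
          exp_s <- stats::runif(1, spec$exp_range[1], spec$exp_range[2])
          insv_s <- if (stats::runif(1) < spec$p_insv)
            stats::runif(1, spec$insv_range[1], spec$insv_range[2]) else 0
          rec_units <- list(); partial <- logical(0)
          for (ct in c("EXP", "INSV")) {
            tot <- if (ct == "EXP") exp_s else insv_s
            if (tot <= 0) next
            durs <- split_duration_into_units(tot, spec$unit_s)
            for (ui in seq_along(durs)) {
              T_ <- max(1L, round(durs[ui] * spec$frames_per_s))
              X <- sample_gmm(class_models[[cls]], T_)
              X <- X + rep(infant_offset, each = nrow(X))
              if (spec$noise_level > 0)
                X <- X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) *
                  rep(spec$noise_level * sd_dim, each = nrow(X))
              rec_units[[length(rec_units) + 1L]] <-
                feature_sequence(X, cry_type = ct, source_file = file_id,
                                 unit_index = length(rec_units))
              partial <- c(partial, durs[ui] < spec$unit_s - 1e-9)
            }
          }
          units[[file_id]] <- list(features = rec_units, partial = partial)
          manifest <- rbind(manifest, data.frame(
            wav = if (is.null(out_dir)) "" else
              file.path(out_dir, paste0(file_id, ".csv")),
            labels = "", health_class = cls, infant_id = infant_id,
            split = split, file_id = file_id, stringsAsFactors = FALSE))
        }
      }
    }
  }

  if (mode == "audio") {
    manifest <- write_audio_corpus(manifest, units, spec, out_dir)
  } else if (!is.null(out_dir)) {
    for (fid in names(units)) {
      rows <- lapply(seq_along(units[[fid]]$features), function(j) {
        f <- units[[fid]]$features[[j]]
        cbind(data.frame(cry_type = f$cry_type, unit_index = f$unit_index,
                         partial = units[[fid]]$partial[j]),
              as.data.frame(f$X))
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(out_dir, paste0(fid, ".csv")),
                       row.names = FALSE)
    }
    write_manifest(manifest[, c("wav", "labels", "health_class", "infant_id",
                                "split")],
                   file.path(out_dir, "manifest.csv"))
  }

  structure(list(manifest = validate_manifest(manifest), units = units,
                 class_models = class_models, base_model = base, spec = spec),
            class = "cry_corpus")
}

write_audio_corpus <- function(manifest, units, spec, out_dir) {
  fs <- 44100
  for (j in seq_len(nrow(manifest))) {
    fid <- manifest$file_id[j]
    cls_idx <- match(manifest$health_class[j], spec$class_names)
    f0 <- 450 + (cls_idx - 1L) * spec$separation * 30
    form1 <- 1100 + (cls_idx - 1L) * spec$separation * 100
    segs <- list(); labels <- NULL; t0 <- 0
    for (k in seq_along(units[[fid]]$features)) {
      f <- units[[fid]]$features[[k]]
      dur <- nrow(f$X) / spec$frames_per_s
      is_insv <- identical(f$cry_type, "INSV")
      pars <- synthetic_audio_params(
        f0_hz = if (is_insv) f0 * 0.8 else f0,
        formants_hz = c(form1, 3300),
        breathiness = if (is_insv) 0.3 else 0.05,
        noise_snr_db = 15)
      a <- synth_cry_audio(pars, dur, fs)
      if (is_insv) a$samples <- 0.4 * a$samples
      gap <- audio_signal(stats::rnorm(round(0.2 * fs), sd = 1e-3), fs)
      segs <- c(segs, list(a, gap))
      labels <- rbind(labels, data.frame(start_s = t0, end_s = t0 + dur,
                                         label = f$cry_type))
      t0 <- t0 + dur + 0.2
    }
    x <- unlist(lapply(segs, `[[`, "samples"))
    wav_path <- file.path(out_dir, paste0(fid, ".wav"))
    lab_path <- file.path(out_dir, paste0(fid, ".txt"))
    write_wav(audio_signal(x, fs), wav_path)
    write_segment_labels(labels, lab_path)
    manifest$wav[j] <- wav_path
    manifest$labels[j] <- lab_path
  }
  write_manifest(manifest[, c("wav", "labels", "health_class", "infant_id",
                              "split")],
                 file.path(out_dir, "manifest.csv"))
  manifest
}

#' Load a feature-mode corpus written by [make_corpus()]
#' @param dir directory containing `manifest.csv` and per-recording feature
#'   CSVs.
#' @return a `cry_corpus` (without generator models).
#' @export
read_feature_corpus <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  manifest$file_id <- sub("\\.csv$", "", basename(manifest$wav))
  units <- list()
  for (j in seq_len(nrow(manifest))) {
    df <- utils::read.csv(manifest$wav[j])
    fid <- manifest$file_id[j]
    feats <- list(); partial <- logical(0)
    for (u in unique(df$unit_index)) {
      sub <- df[df$unit_index == u, , drop = FALSE]
      feats[[length(feats) + 1L]] <- feature_sequence(
        as.matrix(sub[, -(1:3), drop = FALSE]),
        cry_type = sub$cry_type[1L], source_file = fid, unit_index = u)
      partial <- c(partial, sub$partial[1L])
    }
    units[[fid]] <- list(features = feats, partial = partial)
  }
  structure(list(manifest = manifest, units = units, class_models = NULL,
                 base_model = NULL, spec = NULL),
            class = "cry_corpus")
}
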