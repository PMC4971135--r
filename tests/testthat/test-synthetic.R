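test_that("GMM sampling matches the model moments and is seed-deterministic", {
  g <- gmm_params(c(0.3, 0.7), rbind(c(-2, 0), c(2, 1)),
                  rbind(c(1, 0.5), c(0.5, 2)))
  X <- sample_gmm(g, 60000L, seed = 81L)
  # law of large numbers on the mixture mean
  want_mean <- colSums(g$weights * g$means)
  expect_lt(max(abs(colMeans(X) - want_mean)), 0.05)
  # mixture variance = E[var] + var[means]
  want_var <- colSums(g$weights * (g$variances + g$means^2)) - want_mean^2
  expect_lt(max(abs(apply(X, 2L, stats::var) - want_var)), 0.1)
  expect_identical(sample_gmm(g, 100L, seed = 5L), sample_gmm(g, 100L, seed = 5L))
  # degenerate weights: all frames from the surviving component
  g0 <- gmm_params(c(1, 0), rbind(c(10, 10), c(-10, -10)),
                   rbind(c(0.1, 0.1), c(0.1, 0.1)))
  X0 <- sample_gmm(g0, 200L, seed = 6L)
  expect_true(all(X0 > 5))
  expect_error(sample_gmm(g, 0L), "at least 1")
})

test_that("class models coincide at delta = 0 and separate monotonically", {
  set.seed(82)
  base <- crydx:::random_base_gmm(3L, 8L)
  same <- make_class_models(base, 0, 2L, seed = 3L)
  expect_equal(same[[1L]]$means, base$means)
  expect_equal(same[[2L]]$means, base$means)

  shift_size <- function(delta) {
    ms <- make_class_models(base, delta, 2L, seed = 3L)
    sqrt(mean(((ms[[1L]]$means - ms[[2L]]$means) / sqrt(base$variances))^2))
  }
  sizes <- vapply(c(0.5, 1, 2, 4), shift_size, numeric(1))
  expect_true(all(diff(sizes) > 0))
  # per-component shift has exactly magnitude delta in sd units
  m <- make_class_models(base, 2, 1L, seed = 3L)[[1L]]
  shifts <- (m$means - base$means) / sqrt(base$variances)
  expect_equal(sqrt(rowSums(shifts^2)), rep(2, 3L), tolerance = 1e-9)
  expect_error(make_class_models(base, -1, 2L), "nonnegative")
})

test_that("detection difficulty decreases with the separation knob", {
  set.seed(83)
  base <- crydx:::random_base_gmm(3L, 6L)
  auc_at <- function(delta) {
    ms <- make_class_models(base, delta, 2L, seed = 4L)
    Xa <- sample_gmm(ms[[1L]], 800L)
    Xb <- sample_gmm(ms[[2L]], 800L)
    ts <- gmm_logpdf(Xa, ms[[1L]]) - gmm_logpdf(Xa, ms[[2L]])
    ns <- gmm_logpdf(Xb, ms[[1L]]) - gmm_logpdf(Xb, ms[[2L]])
    roc_auc(ts, ns)
  }
  a0 <- auc_at(0); a1 <- auc_at(1); a5 <- auc_at(5)
  expect_lt(abs(a0 - 0.5), 0.06)
  expect_gt(a5, 0.95)
  expect_true(a0 < a1 && a1 < a5)
})

test_that("synthetic audio has the requested fundamental and is reproducible", {
  p <- synthetic_audio_params(f0_hz = 450, noise_snr_db = Inf,
                              breathiness = 0)
  a <- synth_cry_audio(p, 1.0, fs = 44100, seed = 84L)
  expect_equal(a$sample_rate, 44100)
  expect_length(a$samples, 44100L)
  expect_equal(max(abs(a$samples)), 0.8, tolerance = 1e-12)
  # strongest low-frequency harmonic sits at a multiple of ~450 Hz
  sp <- Mod(stats::fft(a$samples * hamming_window(length(a$samples))))^2
  freqs <- (seq_along(sp) - 1L) * 44100 / length(sp)
  keep <- freqs > 200 & freqs < 4000
  peak <- freqs[keep][which.max(sp[keep])]
  harmonic_offset <- abs(peak / 450 - round(peak / 450)) * 450
  expect_lt(harmonic_offset, 25)
  expect_identical(synth_cry_audio(p, 0.5, seed = 7L)$samples,
                   synth_cry_audio(p, 0.5, seed = 7L)$samples)
  expect_error(synth_cry_audio(p, 0), "positive")
  expect_error(synth_cry_audio(synthetic_audio_params(f0_hz = 3000), 1,
                               fs = 8000), "f0 too high")
})

test_that("feature-mode corpus bookkeeping matches the specification", {
  spec <- synthetic_corpus_spec(
    n_infants = c(ubm = 2L, adapt = 2L, test = 3L),
    recordings_per_infant = 2L, seed = 85L)
  corp <- make_corpus(spec, "feature")
  # 2 classes x (2 + 2 + 3) infants x 2 recordings = 28 files
  expect_equal(nrow(corp$manifest), 28L)
  expect_length(corp$units, 28L)
  expect_setequal(unique(corp$manifest$split), c("ubm", "adapt", "test"))
  expect_silent(validate_manifest(corp$manifest))
  # every recording has expiration; cry types come from the allowed pair
  for (fid in names(corp$units)) {
    types <- vapply(corp$units[[fid]]$features, function(f) f$cry_type,
                    character(1))
    expect_true("EXP" %in% types)
    expect_true(all(types %in% c("EXP", "INSV")))
    # full units have round(3 * 142) frames; partial flags match short units
    for (j in seq_along(types)) {
      f <- corp$units[[fid]]$features[[j]]
      if (!corp$units[[fid]]$partial[j])
        expect_equal(nrow(f$X), 426L)
      else expect_lt(nrow(f$X), 426L)
      expect_equal(ncol(f$X), 39L)
    }
  }
  # deterministic regeneration
  corp2 <- make_corpus(spec, "feature")
  expect_identical(corp$manifest, corp2$manifest)
  expect_identical(corp$units[[5L]]$features[[1L]]$X,
                   corp2$units[[5L]]$features[[1L]]$X)
})

test_that("feature-mode corpus round-trips through CSV files", {
  spec <- synthetic_corpus_spec(
    n_infants = c(ubm = 1L, adapt = 1L, test = 1L),
    recordings_per_infant = 1L, exp_range = c(2, 4), seed = 86L)
  dir <- withr::local_tempdir()
  corp <- make_corpus(spec, "feature", out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_feature_corpus(dir)
  expect_equal(nrow(back$manifest), nrow(corp$manifest))
  fid <- corp$manifest$file_id[1L]
  expect_equal(unname(back$units[[fid]]$features[[1L]]$X),
               unname(corp$units[[fid]]$features[[1L]]$X), tolerance = 1e-10)
  expect_equal(back$units[[fid]]$partial, corp$units[[fid]]$partial)
})

test_that("audio-mode corpus writes parseable WAV and label files", {
  spec <- synthetic_corpus_spec(
    n_infants = c(ubm = 1L, adapt = 1L, test = 1L),
    recordings_per_infant = 1L, exp_range = c(2, 3), insv_range = c(1, 2),
    seed = 87L)
  dir <- withr::local_tempdir()
  corp <- make_corpus(spec, "audio", out_dir = dir)
  expect_equal(nrow(corp$manifest), 6L)
  for (j in seq_len(nrow(corp$manifest))) {
    a <- read_wav(corp$manifest$wav[j])
    labs <- read_segment_labels(corp$manifest$labels[j])
    expect_gt(nrow(labs), 0L)
    expect_true(all(labs$label %in% c("EXP", "INSV")))
    # labeled regions stay inside the audio
    expect_lte(max(labs$end_s), length(a$samples) / a$sample_rate + 1e-6)
    rec <- cry_recording(a, labs, corp$manifest$health_class[j],
                         corp$manifest$infant_id[j])
    expect_gt(length(extract_segments(rec, "EXP")), 0L)
  }
  expect_error(make_corpus(spec, "audio"), "out_dir")
})

test_that("between-infant offsets move recordings of one infant coherently", {
  mk <- function(isd) synthetic_corpus_spec(
    n_infants = c(ubm = 4L, adapt = 1L, test = 1L),
    recordings_per_infant = 2L, exp_range = c(4, 6), p_insv = 0,
    noise_level = 0, infant_sd = isd, separation = 0, seed = 88L)
  mean_of <- function(corp, fid)
    colMeans(do.call(rbind, lapply(corp$units[[fid]]$features,
                                   function(f) f$X)))
  spread <- function(isd) {
    corp <- make_corpus(mk(isd), "feature")
    m <- corp$manifest[corp$manifest$split == "ubm", ]
    per_infant <- tapply(m$file_id, m$infant_id, function(ids)
      colMeans(do.call(rbind, lapply(ids, mean_of, corp = corp))))
    stats::var(vapply(per_infant, `[[`, numeric(1), 1L))
  }
  expect_gt(spread(1.0), 4 * spread(0))
})
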