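# Shared fixtures: small random mixtures and feature matrices built in code.

random_gmm <- function(K, D, seed = NULL, sep = 3) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rgamma(K, 2) + 0.1
  gmm_params(w / sum(w),
             matrix(stats::rnorm(K * D, sd = sep), K, D),
             matrix(stats::runif(K * D, 0.5, 2), K, D))
}

random_frames <- function(T_, D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(T_ * D), T_, D)
}

# brute-force linear-domain GMM density (independent oracle)
naive_gmm_logpdf <- function(x, gmm) {
  if (is.matrix(x))
    return(apply(x, 1L, naive_gmm_logpdf, gmm = gmm))
  K <- length(gmm$weights)
  dens <- 0
  for (k in seq_len(K)) {
    dens <- dens + gmm$weights[k] *
      prod(stats::dnorm(x, gmm$means[k, ], sqrt(gmm$variances[k, ])))
  }
  log(dens)
}

sine_signal <- function(freq, duration_s, fs = 44100, amp = 0.5) {
  t <- seq(0, duration_s, length.out = round(duration_s * fs) + 1L)[-1L]
  audio_signal(amp * sin(2 * pi * freq * t), fs)
}
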