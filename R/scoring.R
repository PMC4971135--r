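# Likelihood-ratio scoring, the background-model-set alternative, HNORM score
# normalization, per-file aggregation and closed-set ML classification.

#' Average log-likelihood under the alternative hypothesis
#'
#' With a single background model this is just [avg_loglik()]. With a set of
#' B equally likely background models it is the log of their mean likelihood,
#' `logsumexp_b(avg_loglik(X, lambda_b)) - log(B)`, each term
#' duration-normalized.
#'
#' @param X frames (matrix or [feature_sequence()]).
#' @param background a single [gmm_params()] model or a list of them.
#' @return scalar log-likelihood (nats per frame).
#' @export
alt_loglik <- function(X, background) {
  if (inherits(background, "gmm")) return(avg_loglik(X, background))
  if (!is.list(background) || length(background) == 0L)
    stop("background must be a gmm or a non-empty list of gmms")
  lls <- vapply(background, function(b) avg_loglik(X, b), numeric(1L))
  m <- max(lls)
  m + log(mean(exp(lls - m)))
}

#' Duration-normalized log-likelihood-ratio score
#'
#' `Lambda(X) = log p(X | lambda_hyp) - log p(X | lambda_alt)`, both terms
#' averaged over frames so the score does not grow with sequence length. The
#' alternative may be a single UBM or a set of background models (see
#' [alt_loglik()]).
#'
#' @param X frames (matrix or [feature_sequence()]).
#' @param hyp hypothesized-class [gmm_params()] model.
#' @param alt alternative model or list of background models.
#' @return scalar LLR in nats per frame; positive favors the hypothesis.
#' @export
llr_score <- function(X, hyp, alt) {
  avg_loglik(X, hyp) - alt_loglik(X, alt)
}

#' Fit HNORM parameters from imposter scores
#'
#' Mean and population standard deviation of the scores that non-target
#' (imposter) material produces on a given detector; used to rescale all of
#' that detector's scores to a zero-mean, unit-variance imposter
#' distribution.
#'
#' @param imposter_scores numeric vector of at least two scores with nonzero
#'   spread.
#' @return an `hnorm_params` list with `mu` and `sigma`.
#' @export
fit_hnorm <- function(imposter_scores) {
  s <- imposter_scores[is.finite(imposter_scores)]
  if (length(s) < 2L) stop("need at least two imposter scores")
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  if (sigma <= 0) stop("imposter scores have zero spread")
  structure(list(mu = mu, sigma = sigma), class = "hnorm_params")
}

#' Apply HNORM to scores
#'
#' @param score numeric score(s).
#' @param params an `hnorm_params` from [fit_hnorm()].
#' @return normalized score(s) `(score - mu) / sigma`.
#' @export
apply_hnorm <- function(score, params) {
  (score - params$mu) / params$sigma
}

#' Score the cry units of one feature list and aggregate to a file score
#'
#' Computes the per-unit LLR for every unit of the requested cry type and
#' averages them (unweighted) into one file-level score. The number of full
#' (non-partial) units is reported so downstream dataset filters can require
#' at least one or at least three full units.
#'
#' @param unit_features list of [feature_sequence()] objects for one
#'   recording (any mix of cry types).
#' @param hyp,alt hypothesis and alternative models as in [llr_score()].
#' @param cry_type `"EXP"` or `"INSV"`.
#' @param partial_flags optional logical vector marking partial units (same
#'   order as `unit_features`); defaults to all-full.
#' @return list with `score` (NA if the recording has no unit of the type —
#'   an absent score, never zero), `n_units`, `n_full_units` and
#'   `unit_scores`.
#' @export
score_units <- function(unit_features, hyp, alt, cry_type,
                        partial_flags = NULL) {
  types <- vapply(unit_features, function(u) u$cry_type, character(1L))
  sel <- which(types == cry_type)
  if (is.null(partial_flags)) partial_flags <- rep(FALSE, length(unit_features))
  if (length(sel) == 0L)
    return(list(score = NA_real_, n_units = 0L, n_full_units = 0L,
                unit_scores = numeric(0)))
  us <- vapply(unit_features[sel], function(u) llr_score(u, hyp, alt),
               numeric(1L))
  list(score = mean(us), n_units = length(sel),
       n_full_units = sum(!partial_flags[sel]), unit_scores = us)
}

#' Score a whole recording for one cry type
#'
#' Extracts the target segments, splits them into ~3-s cry units, extracts
#' features and aggregates per-unit LLRs with [score_units()].
#'
#' @param recording a [cry_recording()].
#' @param hyp,alt models as in [llr_score()].
#' @param cry_type `"EXP"` or `"INSV"`.
#' @param config a [feature_config()].
#' @param unit_s cry unit duration in seconds (default 3).
#' @param keep_partial keep trailing partial units? Default `TRUE`.
#' @return as [score_units()].
#' @export
score_file <- function(recording, hyp, alt, cry_type,
                       config = feature_config(), unit_s = 3.0,
                       keep_partial = TRUE) {
  segs <- extract_segments(recording, cry_type)
  units <- split_cry_units(segs, unit_s = unit_s, cry_type = cry_type,
                           keep_partial = keep_partial)
  feats <- lapply(units, function(u)
    extract_features(u$audio, config, cry_type = cry_type,
                     unit_index = u$unit_index))
  feats <- feats[vapply(feats, function(f) nrow(f$X) > 0L, logical(1L))]
  partial <- vapply(units, function(u) u$partial, logical(1L))[
    seq_along(feats)]
  score_units(feats, hyp, alt, cry_type, partial_flags = partial)
}

#' Closed-set maximum-likelihood classification
#'
#' Assigns the sequence to the class model with the highest
#' duration-normalized average log-likelihood, assuming equal priors. Ties
#' are broken by the lowest index.
#'
#' @param X frames (matrix or [feature_sequence()]).
#' @param class_models list of at least two [gmm_params()] models.
#' @return index of the winning model; attribute `logliks` carries the
#'   per-class scores.
#' @export
ml_classify <- function(X, class_models) {
  if (!is.list(class_models) || length(class_models) < 2L)
    stop("need at least two class models")
  lls <- vapply(class_models, function(m) avg_loglik(X, m), numeric(1L))
  structure(which.max(lls), logliks = lls)
}
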