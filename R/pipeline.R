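# End-to-end orchestration: UBM training, class-model adaptation, scoring
# with HNORM, dataset filtering, per-cry-type evaluation, score fusion, and
# the hierarchical healthy-then-pathology decision.

stack_frames <- function(corpus, file_ids, cry_type) {
  mats <- list()
  for (fid in file_ids) {
    for (f in corpus$units[[fid]]$features)
      if (identical(f$cry_type, cry_type)) mats[[length(mats) + 1L]] <- f$X
  }
  if (length(mats) == 0L) return(matrix(numeric(0), 0L, 0L))
  do.call(rbind, mats)
}

score_corpus_files <- function(corpus, file_ids, hyp, alt, cry_type) {
  rows <- lapply(file_ids, function(fid) {
    rec <- corpus$units[[fid]]
    s <- score_units(rec$features, hyp, alt, cry_type,
                     partial_flags = rec$partial)
    data.frame(file_id = fid, score = s$score, n_units = s$n_units,
               n_full_units = s$n_full_units, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

apply_dataset_filter <- function(tab, filter) {
  switch(filter,
         A = tab[!is.na(tab$score), , drop = FALSE],
         B = tab[!is.na(tab$score) & tab$n_full_units >= 1L, , drop = FALSE],
         C = tab[!is.na(tab$score) & tab$n_full_units >= 3L, , drop = FALSE],
         stop("filter must be one of A/B/C"))
}

#' Experiment configuration for [run_detector_experiment()]
#'
#' @param target_class the hypothesized (positive) health class (default
#'   `"Healthy"`).
#' @param method adaptation method 1--4 (see [adaptation_config()]).
#' @param alternative `"ubm"` (single background model) or
#'   `"background_set"` (the adapted non-target class models as equally
#'   likely alternatives).
#' @param ubm_K UBM mixture components (default 16; the clinical-scale
#'   mixture counts of the original study are configuration values, not
#'   requirements).
#' @param filter test dataset filter: `"A"` any length, `"B"` at least one
#'   full 3-s unit, `"C"` at least three full units.
#' @param fusion_specs classifier bank for score fusion (default: the full
#'   bank of [fusion_classifier_bank()]).
#' @param plan a [cv_plan()] for fusion cross-validation.
#' @param relevance_factor relevance factor for methods 1 and 3 (default 16).
#' @param seed experiment seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(target_class = "Healthy", method = 2L,
                              alternative = c("ubm", "background_set"),
                              ubm_K = 16L, filter = "A",
                              fusion_specs = fusion_classifier_bank(),
                              plan = cv_plan(10L, rounds = 10L),
                              relevance_factor = 16, seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(filter %in% c("A", "B", "C"), method %in% 1:4)
  structure(list(target_class = target_class, method = as.integer(method),
                 alternative = alternative, ubm_K = as.integer(ubm_K),
                 filter = filter, fusion_specs = fusion_specs, plan = plan,
                 relevance_factor = relevance_factor,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full detector experiment on a corpus
#'
#' Trains a health-independent UBM per cry type on the `ubm` split (balanced
#' pooling of the healthy and sick classes), adapts the target-class model on
#' the `adapt` split by the configured method, fits HNORM on the adapt-split
#' non-target (imposter) file scores, scores the `test` split, applies the
#' dataset filter, evaluates EER/AUC/DET and the cost-optimal operating point
#' per cry type, and fuses the two experts' normalized scores with the
#' configured classifier bank.
#'
#' @param corpus a `cry_corpus` (see [make_corpus()]).
#' @param config an [experiment_config()].
#' @return an `experiment_report` list: per cry type `eer`, `auc`, `op`,
#'   `det`, `n_target`, `n_nontarget`, score table and models; plus `fusion`
#'   (a data frame from [evaluate_fusion()], `NULL` when too few joined
#'   files) and the config.
#' @export
run_detector_experiment <- function(corpus, config = experiment_config()) {
  manifest <- validate_manifest(corpus$manifest)
  if (!all(c("ubm", "adapt", "test") %in% manifest$split))
    stop("corpus must provide ubm/adapt/test splits")
  target <- config$target_class
  adapt_cfg <- adaptation_config(config$method,
                                 relevance_factor = config$relevance_factor)

  per_type <- list()
  score_tables <- list()
  for (ct in c("EXP", "INSV")) {
    ids_by <- function(split, cls = NULL) {
      sel <- manifest$split == split
      if (!is.null(cls)) sel <- sel & manifest$health_class == cls
      manifest$file_id[sel]
    }
    # balanced UBM training pool
    classes <- unique(manifest$health_class)
    pools <- lapply(classes, function(cl) stack_frames(corpus, ids_by("ubm", cl), ct))
    names(pools) <- classes
    pools <- pools[vapply(pools, nrow, integer(1L)) > 0L]
    stacked <- pool_balanced(pools, "health_independent",
                             seed = config$seed)
    ubm <- train_gmm_em(stacked, config$ubm_K, seed = config$seed,
                        tag = paste0("HI-UBM-", ct))

    # adapt target model; background set = adapted non-target models
    target_frames <- stack_frames(corpus, ids_by("adapt", target), ct)
    hyp <- adapt_gmm(ubm, target_frames, adapt_cfg)
    alt <- if (config$alternative == "ubm") ubm else {
      nt_classes <- setdiff(classes, target)
      lapply(nt_classes, function(cl)
        adapt_gmm(ubm, stack_frames(corpus, ids_by("adapt", cl), ct),
                  adapt_cfg))
    }

    # HNORM from adapt-split imposters (never test data)
    imp_ids <- manifest$file_id[manifest$split == "adapt" &
                                  manifest$health_class != target]
    imp <- score_corpus_files(corpus, imp_ids, hyp, alt, ct)
    hn <- fit_hnorm(imp$score[!is.na(imp$score)])

    # score and filter the test split
    tst_ids <- ids_by("test")
    tab <- score_corpus_files(corpus, tst_ids, hyp, alt, ct)
    tab$hnorm_score <- apply_hnorm(tab$score, hn)
    tab$label <- ifelse(manifest$health_class[match(tab$file_id,
                                                    manifest$file_id)] ==
                          target, "target", "nontarget")
    tab$infant_id <- manifest$infant_id[match(tab$file_id, manifest$file_id)]
    kept <- apply_dataset_filter(tab, config$filter)

    ts <- kept$hnorm_score[kept$label == "target"]
    ns <- kept$hnorm_score[kept$label == "nontarget"]
    # a strict dataset filter can empty one side (e.g. inspirations rarely
    # reach three full units); the expert is then reported as unevaluable
    evaluable <- length(ts) > 0L && length(ns) > 0L
    per_type[[ct]] <- list(
      eer = if (evaluable) eer(ts, ns) else NA_real_,
      auc = if (evaluable) roc_auc(ts, ns) else NA_real_,
      op = if (evaluable) optimal_operating_point(ts, ns) else NULL,
      det = if (evaluable) det_points(ts, ns) else NULL,
      n_target = length(ts), n_nontarget = length(ns),
      scores = kept, ubm = ubm, model = hyp, hnorm = hn)
    score_tables[[ct]] <- data.frame(file_id = kept$file_id,
                                     infant_id = kept$infant_id,
                                     score = kept$hnorm_score,
                                     label = kept$label,
                                     stringsAsFactors = FALSE)
  }

  vectors <- build_score_vectors(score_tables$EXP, score_tables$INSV)
  fusion <- if (nrow(vectors) >= 2L * config$plan$K &&
                length(unique(vectors$label)) == 2L)
    evaluate_fusion(vectors, config$fusion_specs, config$plan,
                    positive = "target")
  else NULL

  structure(list(EXP = per_type$EXP, INSV = per_type$INSV,
                 fusion = fusion, fusion_vectors = vectors, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: method %d, alternative %s, filter %s>\n",
              x$config$method, x$config$alternative, x$config$filter))
  for (ct in c("EXP", "INSV"))
    cat(sprintf("  %s: EER %.3f, AUC %.3f (%d target / %d non-target files)\n",
                ct, x[[ct]]$eer, x[[ct]]$auc, x[[ct]]$n_target,
                x[[ct]]$n_nontarget))
  if (!is.null(x$fusion)) {
    best <- x$fusion[which.max(x$fusion$accuracy), ]
    cat(sprintf("  fusion best: %s (accuracy %.3f, FNR %.3f, FPR %.3f)\n",
                best$classifier, best$accuracy, best$fnr, best$fpr))
  }
  invisible(x)
}

#' Hierarchical healthy-then-pathology decision
#'
#' Stage 1 decides healthy vs. sick from the available cry-type experts: the
#' fused classifier when both cry types are present, otherwise a threshold on
#' the single available expert's normalized score. Only for stage-1-sick
#' inputs does stage 2 run: a closed-set maximum-likelihood choice among the
#' pathology models, with rejection to `"others"` when the winner's average
#' LLR against the pathology-independent background falls below the rejection
#' threshold.
#'
#' @param exp_X,insv_X feature matrices (or [feature_sequence()]s) for the
#'   expiration and inspiration material; either may be `NULL`.
#' @param stage1 list with per-cry-type detectors `exp` and `insv` (each
#'   `list(hyp, alt, hnorm)`), optional `fusion_model`, and `threshold`
#'   (default 0) for the single-expert fallback.
#' @param pathology_models named list of per-pathology models, each
#'   `list(exp = gmm, insv = gmm)` (either entry may be `NULL`).
#' @param pathology_alt alternative models for stage-2 LLRs, `list(exp =,
#'   insv =)`.
#' @param reject_threshold winning stage-2 average LLR below this maps to
#'   `"others"` (default `-Inf`: no rejection).
#' @return a `hierarchical_decision` list: `stage1` (`"healthy"`/`"sick"`),
#'   `stage1_scores`, `fallback` flag, and (sick only) `stage2` label and
#'   `stage2_scores`.
#' @export
hierarchical_decide <- function(exp_X, insv_X, stage1, pathology_models,
                                pathology_alt, reject_threshold = -Inf) {
  score_one <- function(X, det) {
    if (is.null(X) || is.null(det)) return(NA_real_)
    apply_hnorm(llr_score(X, det$hyp, det$alt), det$hnorm)
  }
  s_exp <- score_one(exp_X, stage1$exp)
  s_insv <- score_one(insv_X, stage1$insv)
  if (all(is.na(c(s_exp, s_insv))))
    stop("need at least one cry type to decide")
  fallback <- FALSE
  threshold <- stage1$threshold %||% 0
  if (!is.na(s_exp) && !is.na(s_insv) && !is.null(stage1$fusion_model)) {
    nd <- data.frame(exp_score = s_exp, insv_score = s_insv)
    lab <- predict(stage1$fusion_model, nd)
    healthy <- identical(lab, "target") || identical(lab, "healthy")
  } else {
    fallback <- TRUE
    s <- if (!is.na(s_exp)) s_exp else s_insv
    healthy <- s >= threshold
  }
  res <- list(stage1 = if (healthy) "healthy" else "sick",
              stage1_scores = c(exp = s_exp, insv = s_insv),
              fallback = fallback)
  if (!healthy) {
    lls <- vapply(pathology_models, function(pm) {
      vals <- c(
        if (!is.null(exp_X) && !is.null(pm$exp))
          llr_score(exp_X, pm$exp, pathology_alt$exp),
        if (!is.null(insv_X) && !is.null(pm$insv))
          llr_score(insv_X, pm$insv, pathology_alt$insv))
      mean(vals)
    }, numeric(1L))
    win <- which.max(lls)
    res$stage2 <- if (lls[win] < reject_threshold) "others"
                  else names(pathology_models)[win]
    res$stage2_scores <- lls
  }
  structure(res, class = "hierarchical_decision")
}
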