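# Score-level fusion of the expiratory and inspiratory experts: the two
# normalized LLR scores form a 2-D feature vector classified by MLP, PNN or
# SVM under repeated stratified K-fold cross-validation.

#' Join per-file EXP and INSV score tables into fusion vectors
#'
#' Inner join on `file_id`; files lacking either score are dropped and
#' counted (attribute `n_dropped`).
#'
#' @param exp_table,insv_table data frames with columns `file_id`, `score`,
#'   `label` (and optionally `infant_id`); one row per file.
#' @return data frame with `file_id`, `infant_id`, `exp_score`, `insv_score`,
#'   `label`.
#' @export
build_score_vectors <- function(exp_table, insv_table) {
  for (tb in list(exp_table, insv_table))
    if (anyDuplicated(tb$file_id)) stop("duplicate file_id in a score table")
  exp_table <- exp_table[is.finite(exp_table$score), , drop = FALSE]
  insv_table <- insv_table[is.finite(insv_table$score), , drop = FALSE]
  m <- merge(exp_table, insv_table, by = "file_id",
             suffixes = c("_exp", "_insv"))
  out <- data.frame(file_id = m$file_id,
                    infant_id = if ("infant_id_exp" %in% names(m))
                      m$infant_id_exp else NA_character_,
                    exp_score = m$score_exp, insv_score = m$score_insv,
                    label = m$label_exp, stringsAsFactors = FALSE)
  n_dropped <- nrow(exp_table) + nrow(insv_table) - 2L * nrow(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Random oversampling of the minority class
#'
#' Duplicates seeded random rows of the minority class (sampling with
#' replacement) until the two class counts are equal; the majority class and
#' all original rows are kept untouched. No synthetic points are created.
#'
#' @param vectors data frame with a binary `label` column.
#' @param seed RNG seed.
#' @return the balanced data frame.
#' @export
random_oversample <- function(vectors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- table(vectors$label)
  if (length(tab) < 2L) stop("need two classes to oversample")
  if (tab[1L] == tab[2L]) return(vectors)
  minority <- names(tab)[which.min(tab)]
  deficit <- abs(diff(as.vector(tab)))
  idx <- which(vectors$label == minority)
  extra <- sample(idx, deficit, replace = TRUE)
  rbind(vectors, vectors[extra, , drop = FALSE])
}

#' Repeated stratified K-fold cross-validation plan
#'
#' @param K number of folds (3, 5 or 10 in typical use).
#' @param rounds number of repetitions; defaults to 400/200/100 for
#'   K = 3/5/10 and `100` otherwise.
#' @param seed RNG seed.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(K, rounds = NULL, seed = 1L) {
  if (K < 2L) stop("K must be at least 2")
  if (is.null(rounds))
    rounds <- c(`3` = 400L, `5` = 200L, `10` = 100L)[as.character(K)]
  if (is.na(rounds)) rounds <- 100L
  structure(list(K = as.integer(K), rounds = as.integer(rounds),
                 seed = as.integer(seed)), class = "cv_plan")
}

#' Stratified repeated K-fold splits
#'
#' Per round, each class is independently permuted (seeded) and dealt across
#' the K folds, so every fold's class proportions are within one sample of
#' the global proportions and each index lands in exactly one test fold per
#' round.
#'
#' @param labels class label vector.
#' @param plan a [cv_plan()].
#' @return list of rounds; each round is a list of K test-index vectors.
#' @export
stratified_repeated_kfold <- function(labels, plan) {
  classes <- unique(labels)
  if (any(table(labels) < plan$K))
    stop("every class must have at least K members")
  set.seed(plan$seed)
  lapply(seq_len(plan$rounds), function(round_i) {
    folds <- vector("list", plan$K)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(plan$K), length(idx))
      for (k in seq_len(plan$K))
        folds[[k]] <- c(folds[[k]], idx[assign_to == k])
    }
    lapply(folds, sort)
  })
}

#' Fusion classifier specification
#'
#' Available kinds and their settings:
#' \itemize{
#'   \item `mlp`: one hidden layer of 10 tanh units, softmax outputs,
#'     cross-entropy loss, at most 1000 iterations;
#'   \item `pnn`: probabilistic neural network, Gaussian radial basis layer
#'     with spread 0.1 (in standardized-score units), competitive output;
#'   \item `svm_linear`, `svm_quadratic`, `svm_poly3`, `svm_rbf`, `svm_mlp`:
#'     support vector machines with linear, order-2 polynomial, order-3
#'     polynomial, Gaussian RBF and sigmoid (`tanh(gamma * <x, x'> + coef0)`,
#'     gamma = 1, coef0 = -1) kernels.
#' }
#'
#' @param kind one of the names above.
#' @param ... overrides: `hidden` (MLP), `maxit` (MLP), `spread` (PNN),
#'   `gamma`, `coef0`, `cost` (SVM).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("mlp", "pnn", "svm_linear",
                                     "svm_quadratic", "svm_poly3", "svm_rbf",
                                     "svm_mlp"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    mlp = list(hidden = 10L, maxit = 1000L),
    pnn = list(spread = 0.1),
    svm_linear = list(kernel = "linear", cost = 1),
    svm_quadratic = list(kernel = "polynomial", degree = 2L, gamma = 1,
                         coef0 = 1, cost = 1),
    svm_poly3 = list(kernel = "polynomial", degree = 3L, gamma = 1,
                     coef0 = 1, cost = 1),
    svm_rbf = list(kernel = "radial", gamma = 1, cost = 1),
    svm_mlp = list(kernel = "sigmoid", gamma = 1, coef0 = -1, cost = 1))
  spec <- utils::modifyList(defaults, list(...))
  spec$kind <- kind
  structure(spec, class = "classifier_spec")
}

#' The full classifier bank used for fusion experiments
#' @return named list of [classifier_spec()] objects.
#' @export
fusion_classifier_bank <- function() {
  kinds <- c("mlp", "pnn", "svm_linear", "svm_quadratic", "svm_poly3",
             "svm_rbf", "svm_mlp")
  stats::setNames(lapply(kinds, classifier_spec), kinds)
}

score_matrix <- function(vectors) {
  as.matrix(vectors[, c("exp_score", "insv_score")])
}

#' Train a fusion classifier on score vectors
#'
#' Inputs are standardized with the training-fold mean and standard
#' deviation; the same transform is stored and applied at prediction time.
#'
#' @param spec a [classifier_spec()].
#' @param train data frame of score vectors (see [build_score_vectors()])
#'   with a binary `label` column containing both classes.
#' @param seed RNG seed (MLP weight initialization).
#' @return a `fusion_model` with a [predict()] method returning labels.
#' @export
train_fusion_classifier <- function(spec, train, seed = 1L) {
  y <- factor(train$label)
  if (nlevels(y) < 2L) stop("training fold contains a single class")
  X <- score_matrix(train)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, `-`), 2L, sd_, `/`)

  fit <- switch(spec$kind,
    mlp = {
      set.seed(seed)
      nnet::nnet(Xs, nnet::class.ind(y), size = spec$hidden,
                 softmax = TRUE, maxit = spec$maxit, trace = FALSE)
    },
    pnn = list(X = Xs, y = y, spread = spec$spread),
    {
      set.seed(seed)
      args <- list(x = Xs, y = y, kernel = spec$kernel, scale = FALSE,
                   cost = spec$cost)
      for (p in c("degree", "gamma", "coef0"))
        if (!is.null(spec[[p]])) args[[p]] <- spec[[p]]
      do.call(e1071::svm, args)
    })
  structure(list(spec = spec, fit = fit, mu = mu, sd = sd_,
                 levels = levels(y)),
            class = "fusion_model")
}

#' @export
predict.fusion_model <- function(object, newdata, ...) {
  X <- score_matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$mu, `-`), 2L, object$sd, `/`)
  kind <- object$spec$kind
  if (kind == "mlp") {
    p <- stats::predict(object$fit, Xs)
    object$levels[max.col(p, ties.method = "first")]
  } else if (kind == "pnn") {
    tr <- object$fit
    pred <- character(nrow(Xs))
    two_s2 <- 2 * tr$spread^2
    for (i in seq_len(nrow(Xs))) {
      d2 <- rowSums(sweep(tr$X, 2L, Xs[i, ], `-`)^2)
      kern <- exp(-d2 / two_s2)
      scores <- tapply(kern, tr$y, mean)
      scores[is.na(scores)] <- 0
      pred[i] <- names(scores)[which.max(scores)]
    }
    pred
  } else {
    as.character(stats::predict(object$fit, Xs))
  }
}

#' Evaluate fusion classifiers by repeated stratified K-fold CV
#'
#' Per round and fold: the minority class of the training fold is randomly
#' oversampled (never the test fold), the classifier is trained on the
#' standardized training scores, and the test fold is predicted. Rates are
#' averaged over all rounds x folds and a Wald confidence interval is put on
#' the mean error.
#'
#' @param vectors score-vector data frame ([build_score_vectors()]).
#' @param specs list of [classifier_spec()] objects (default: the full bank).
#' @param plan a [cv_plan()].
#' @param positive the label treated as the positive (hypothesis) class;
#'   default the first level.
#' @param alpha confidence parameter for the Wald interval (default 0.2,
#'   i.e. 80%).
#' @param oversample balance training folds by random oversampling? Default
#'   `TRUE`.
#' @return data frame with one row per classifier: mean `accuracy`,
#'   `sensitivity`, `specificity`, `fpr`, `fnr`, `error`, and Wald interval
#'   `ci_lo`, `ci_hi`.
#' @export
evaluate_fusion <- function(vectors, specs = fusion_classifier_bank(),
                            plan = cv_plan(10L, rounds = 20L),
                            positive = NULL, alpha = 0.2, oversample = TRUE) {
  labels <- as.character(vectors$label)
  if (is.null(positive)) positive <- sort(unique(labels))[1L]
  splits <- stratified_repeated_kfold(labels, plan)
  n <- nrow(vectors)
  out <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    acc <- sens <- spec_r <- numeric(0)
    for (ri in seq_along(splits)) {
      for (ki in seq_along(splits[[ri]])) {
        test_idx <- splits[[ri]][[ki]]
        train <- vectors[-test_idx, , drop = FALSE]
        test <- vectors[test_idx, , drop = FALSE]
        if (length(unique(train$label)) < 2L) next
        fold_seed <- plan$seed + ri * 1000L + ki
        if (oversample) train <- random_oversample(train, seed = fold_seed)
        model <- train_fusion_classifier(spec, train, seed = fold_seed)
        pred <- predict(model, test)
        cs <- confusion_stats(pred == positive, test$label == positive)
        acc <- c(acc, cs$accuracy)
        sens <- c(sens, cs$sensitivity)
        spec_r <- c(spec_r, cs$specificity)
      }
    }
    err <- 1 - mean(acc)
    ci <- wald_ci(err, n, alpha)
    data.frame(classifier = nm, accuracy = mean(acc),
               sensitivity = mean(sens, na.rm = TRUE),
               specificity = mean(spec_r, na.rm = TRUE),
               fpr = 1 - mean(spec_r, na.rm = TRUE),
               fnr = 1 - mean(sens, na.rm = TRUE),
               error = err, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
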