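make_tables <- function(n_exp, n_insv, n_common, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("f%03d", seq_len(n_exp + n_insv - n_common))
  exp_ids <- ids[seq_len(n_exp)]
  insv_ids <- ids[seq(n_exp - n_common + 1L, n_exp - n_common + n_insv)]
  lab <- function(k) rep(c("target", "nontarget"), length.out = k)
  list(exp = data.frame(file_id = exp_ids, score = stats::rnorm(n_exp),
                        label = lab(n_exp), stringsAsFactors = FALSE),
       insv = data.frame(file_id = insv_ids, score = stats::rnorm(n_insv),
                         label = lab(n_insv), stringsAsFactors = FALSE))
}

make_separable <- function(n_per_class, gap = 4, seed = 2L) {
  set.seed(seed)
  data.frame(
    file_id = sprintf("f%03d", seq_len(2L * n_per_class)),
    infant_id = NA_character_,
    exp_score = c(stats::rnorm(n_per_class, gap / 2),
                  stats::rnorm(n_per_class, -gap / 2)),
    insv_score = c(stats::rnorm(n_per_class, gap / 2),
                   stats::rnorm(n_per_class, -gap / 2)),
    label = rep(c("target", "nontarget"), each = n_per_class),
    stringsAsFactors = FALSE)
}

test_that("score-vector join keeps the intersection and counts the drops", {
  tb <- make_tables(86L, 93L, 80L)
  v <- build_score_vectors(tb$exp, tb$insv)
  expect_equal(nrow(v), 80L)
  expect_equal(attr(v, "n_dropped"), (86L - 80L) + (93L - 80L))
  expect_setequal(v$file_id, intersect(tb$exp$file_id, tb$insv$file_id))
  # non-finite scores are dropped before the join
  tb$exp$score[1L] <- NA
  v2 <- build_score_vectors(tb$exp, tb$insv)
  expect_equal(nrow(v2), 80L - as.integer(tb$exp$file_id[1L] %in% v$file_id))
  dup <- rbind(tb$exp, tb$exp[1L, ])
  expect_error(build_score_vectors(dup, tb$insv), "duplicate")
})

test_that("random oversampling balances the minority class deterministically", {
  v <- make_separable(40L)[c(1:29, 41:80), ]         # 29 target, 40 nontarget
  b <- random_oversample(v, seed = 5L)
  expect_equal(unname(table(b$label)["target"]), 40L, ignore_attr = TRUE)
  expect_equal(unname(table(b$label)["nontarget"]), 40L, ignore_attr = TRUE)
  # all original rows kept, extras are copies of minority rows
  expect_equal(b[seq_len(nrow(v)), ], v, ignore_attr = TRUE)
  extras <- b[-seq_len(nrow(v)), ]
  expect_true(all(extras$label == "target"))
  expect_true(all(extras$file_id %in% v$file_id[v$label == "target"]))
  # deterministic under a fixed seed
  expect_identical(random_oversample(v, seed = 5L), b)
  # already balanced input is returned untouched
  bal <- make_separable(10L)
  expect_identical(random_oversample(bal, seed = 1L), bal)
})

test_that("cv_plan maps folds to the standard round counts", {
  expect_equal(cv_plan(3L)$rounds, 400L)
  expect_equal(cv_plan(5L)$rounds, 200L)
  expect_equal(cv_plan(10L)$rounds, 100L)
  expect_equal(cv_plan(7L)$rounds, 100L)
  expect_equal(cv_plan(5L, rounds = 2L)$rounds, 2L)
  expect_error(cv_plan(1L), "at least 2")
})

test_that("stratified K-fold partitions indices with balanced class shares", {
  labels <- rep(c("a", "b"), c(30L, 20L))
  plan <- cv_plan(5L, rounds = 3L, seed = 9L)
  rounds <- stratified_repeated_kfold(labels, plan)
  expect_length(rounds, 3L)
  for (folds in rounds) {
    expect_length(folds, 5L)
    all_idx <- sort(unlist(folds))
    expect_identical(all_idx, seq_along(labels))   # exact partition
    for (f in folds) {
      expect_equal(sum(labels[f] == "a"), 6L)
      expect_equal(sum(labels[f] == "b"), 4L)
    }
  }
  # reproducible
  expect_identical(stratified_repeated_kfold(labels, plan), rounds)
  expect_error(stratified_repeated_kfold(c("a", "a", "b"), cv_plan(3L)),
               "at least K")
})

test_that("every classifier in the bank separates well-separated scores", {
  v <- make_separable(30L, gap = 6)
  for (nm in names(fusion_classifier_bank())) {
    spec <- classifier_spec(nm)
    model <- train_fusion_classifier(spec, v, seed = 3L)
    pred <- predict(model, v)
    expect_gt(mean(pred == v$label), 0.95)
  }
})

test_that("fusion evaluation reports near-perfect and near-chance extremes", {
  v <- make_separable(25L, gap = 6)
  plan <- cv_plan(5L, rounds = 2L, seed = 4L)
  res <- evaluate_fusion(v, list(svm_linear = classifier_spec("svm_linear")),
                         plan, positive = "target")
  expect_equal(nrow(res), 1L)
  expect_gt(res$accuracy, 0.95)
  expect_true(res$ci_lo <= res$error && res$error <= res$ci_hi)

  set.seed(5)
  chance <- make_separable(25L, gap = 0)
  res2 <- evaluate_fusion(chance,
                          list(svm_linear = classifier_spec("svm_linear")),
                          plan, positive = "target")
  expect_lt(abs(res2$accuracy - 0.5), 0.25)
})

test_that("the PNN memorizes its training set at small spread", {
  v <- make_separable(15L, gap = 1, seed = 8L)
  model <- train_fusion_classifier(classifier_spec("pnn", spread = 0.01), v)
  expect_equal(predict(model, v), v$label)
})

test_that("fusion training is invariant to row order at prediction time", {
  v <- make_separable(20L, gap = 4, seed = 10L)
  model <- train_fusion_classifier(classifier_spec("svm_rbf"), v, seed = 1L)
  shuffled <- v[sample(nrow(v)), ]
  expect_identical(predict(model, shuffled),
                   predict(model, v)[match(shuffled$file_id, v$file_id)])
  expect_error(train_fusion_classifier(classifier_spec("mlp"),
                                       v[v$label == "target", ]),
               "single class")
})
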