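test_that("stratified split reproduces the balanced-corpus test size", {
  labs <- rep(sleep_stages(), times = default_stage_counts())
  sp <- stratified_split(labs, 0.2, seed = 1)
  expect_length(sp$test, 1940)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  # per-class proportions preserved to within one sample
  for (st in sleep_stages()) {
    got <- sum(labs[sp$test] == st)
    expect_lte(abs(got - 0.2 * sum(labs == st)), 1)
  }
  sp2 <- stratified_split(labs, 0.2, seed = 1)
  expect_identical(sp, sp2)
  expect_length(stratified_split(labs, 0, seed = 1)$test, 0)
  expect_error(stratified_split(c("W", "N1"), 0.5), "at least 2")
})

test_that("cross-validation folds partition the data and score sensibly", {
  tab <- blob_table(n = 50, gap = 8) # separable along every axis
  cv <- kfold_cv(tab, model_spec("DT", seed = 1), k = 5, seed = 2)
  expect_equal(nrow(cv), 5)
  expect_true(all(cv$accuracy == 1)) # separable blobs
  folds <- attr(cv, "folds")
  expect_setequal(unique(folds), 1:5)
  expect_equal(sum(cv$n_test), nrow(tab))

  # shuffled labels: accuracy collapses to chance on 5 balanced classes
  tab5 <- small_feature_table()
  withr::with_seed(9, tab5$stage <- sample(tab5$stage))
  cv5 <- kfold_cv(tab5, model_spec("DT", seed = 1), k = 5, seed = 2)
  n_per_fold <- mean(cv5$n_test)
  se <- sqrt(0.2 * 0.8 / n_per_fold)
  expect_lt(abs(mean(cv5$accuracy) - 0.2), 3 * se)

  expect_error(kfold_cv(blob_table(n = 3), k = 5), "smallest class")
})

test_that("confusion matrix matches the tally oracle", {
  y <- stage_factor(c("W", "N1"))
  cm <- confusion_matrix(y, y)
  expect_equal(sum(diag(unclass(cm))), 2)
  cm2 <- confusion_matrix("W", "N1")
  expect_equal(unclass(cm2)["W", "N1"], 1, ignore_attr = TRUE)
  expect_equal(sum(cm2), 1)
  withr::with_seed(71, {
    t5 <- sample(sleep_stages(), 200, replace = TRUE)
    p5 <- sample(sleep_stages(), 200, replace = TRUE)
  })
  expect_equal(unclass(confusion_matrix(t5, p5)), oracle_confusion(t5, p5),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(t5, p5[-1]), "same length")
  expect_error(confusion_matrix("S5", "W"), "unknown stage")
})

test_that("report metrics satisfy their defining identities", {
  withr::with_seed(72, y <- sample(sleep_stages(), 300, replace = TRUE))
  rep_self <- classification_report(confusion_matrix(y, y))
  expect_equal(attr(rep_self, "accuracy"), 1)
  expect_true(all(rep_self$f1 == 1))

  withr::with_seed(73, p <- sample(sleep_stages(), 300, replace = TRUE))
  cm <- confusion_matrix(y, p)
  rp <- classification_report(cm)
  # f1 is the harmonic mean of its own precision and recall
  expect_equal(rp$f1, f1_score(rp$precision, rp$recall), tolerance = 1e-12)
  # pooled accuracy is trace/total
  m <- unclass(cm)
  expect_equal(attr(rp, "accuracy"), sum(diag(m)) / sum(m))
  # micro-averaged precision = micro recall = accuracy
  tp <- diag(m)
  expect_equal(sum(tp) / sum(colSums(m)), attr(rp, "accuracy"))
  expect_equal(sum(tp) / sum(rowSums(m)), attr(rp, "accuracy"))
  g <- glance(rp)
  expect_equal(g$accuracy, attr(rp, "accuracy"))
  expect_equal(g$n, 300)
})

test_that("agreement rate counts identical positions", {
  a <- stage_factor(rep("W", 100))
  expect_equal(agreement_rate(a, a), 1)
  b <- stage_factor(rep("N1", 100))
  expect_equal(agreement_rate(a, b), 0)
  b2 <- a; b2[1] <- "N1"
  expect_equal(agreement_rate(a, b2), 0.99)
  expect_error(agreement_rate(a, b[-1]), "same length")
})

test_that("Cohen's kappa matches closed forms and chance behaviour", {
  y <- stage_factor(rep(sleep_stages(), 10))
  expect_equal(cohen_kappa(confusion_matrix(y, y)), 1)
  # 2x2 toy with 50/50 marginals and 80% agreement
  expect_equal(cohen_kappa(matrix(c(40, 10, 10, 40), 2, 2)), 0.6)
  # independent predictions: kappa near zero
  ks <- vapply(1:50, function(i) {
    withr::with_seed(1300 + i, {
      t5 <- sample(sleep_stages(), 400, replace = TRUE)
      p5 <- sample(sleep_stages(), 400, replace = TRUE)
    })
    cohen_kappa(confusion_matrix(t5, p5))
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("plot builders return ggplot objects", {
  withr::with_seed(74, {
    y <- sample(sleep_stages(), 120, replace = TRUE)
    p <- sample(sleep_stages(), 120, replace = TRUE)
  })
  expect_s3_class(autoplot(confusion_matrix(y, p)), "ggplot")
  expect_s3_class(plot_hypnogram(y, p), "ggplot")
  td <- tidy(confusion_matrix(y, p))
  expect_equal(sum(td$n), 120)
})
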