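# Evaluation protocol: stratified held-out split, stratified k-fold CV,
# confusion matrices, per-stage precision/recall/F1 reports, agreement
# rate between staging runs, and Cohen's kappa.

#' Stratified train/test split
#'
#' Splits indices so that each class contributes its share of the test set.
#' The total test size is `ceiling(n * test_frac)`; per-class sizes use
#' largest-remainder rounding (floors first, then one extra to the classes
#' with the largest fractional remainder, ties to the larger class), so a
#' 9696-epoch balanced corpus at 20% yields exactly 1940 test epochs.
#'
#' @param labels Stage labels (any factor/character vector).
#' @param test_frac Test fraction in [0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_frac = 0.2, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (test_frac > 0 && any(sizes < 2)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  total_test <- ceiling(n * test_frac)
  ideal <- sizes * test_frac
  base <- floor(ideal)
  extra <- total_test - sum(base)
  rem_order <- order(-(ideal - base), -sizes, seq_along(classes))
  take <- base
  if (extra > 0) {
    bump <- rem_order[seq_len(extra)]
    take[bump] <- take[bump] + 1
  }
  test <- integer(0)
  withr::with_seed(seed, {
    for (i in seq_along(classes)) {
      pool <- which(labels == classes[i])
      test <- c(test, pool[sample.int(length(pool), take[i])])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Stratified k-fold cross-validation
#'
#' Assigns samples to `k` stratified folds (per class: shuffle, then deal
#' round-robin), fits the classifier on each training complement and scores
#' accuracy on the held-out fold. Every sample is tested exactly once.
#'
#' @param data Labelled feature table (see [fit_stager()]).
#' @param spec A [model_spec()].
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param features Optional feature subset.
#' @param stage_col Name of the label column.
#' @return Tibble with columns `fold`, `n_test`, `accuracy`; the fold
#'   assignment is stored in `attr(, "folds")`.
#' @export
kfold_cv <- function(data, spec = model_spec("RF"), k = 5, seed = 1,
                     features = NULL, stage_col = "stage") {
  stopifnot(k >= 2)
  labels <- as.character(data[[stage_col]])
  sizes <- table(labels)
  if (min(sizes) < k) {
    stop("k exceeds the smallest class size (", min(sizes), ")",
         call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(sizes)) {
      pool <- which(labels == cl)
      fold[pool[sample.int(length(pool))]] <-
        rep_len(seq_len(k), length(pool))
    }
  })
  res <- purrr::map_dfr(seq_len(k), function(f) {
    held <- which(fold == f)
    fit <- fit_stager(data[-held, , drop = FALSE], spec,
                      features = features, stage_col = stage_col)
    pred <- predict(fit, data[held, , drop = FALSE])
    acc <- mean(as.character(pred) ==
                  as.character(data[[stage_col]][held]))
    tibble(fold = f, n_test = length(held), accuracy = acc)
  })
  attr(res, "folds") <- fold
  res
}

#' Confusion matrix over the five stages
#'
#' @param truth True stage labels.
#' @param estimate Predicted stage labels (same length).
#' @return 5x5 integer matrix of class `stage_confusion`; rows are the
#'   true stage, columns the predicted stage.
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have the same length", call. = FALSE)
  }
  cm <- table(truth = stage_factor(truth), estimate = stage_factor(estimate))
  cm <- unclass(as.matrix(cm))
  structure(cm, class = c("stage_confusion", class(cm)))
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("<stage_confusion> rows = truth, columns = estimate\n")
  print(unclass(x))
  invisible(x)
}

#' Tidy a confusion matrix
#'
#' @param x A `stage_confusion`.
#' @param ... Unused.
#' @return Tibble with columns `truth`, `estimate`, `n`.
#' @export
tidy.stage_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "estimate", "n")
  as_tibble(df)
}

#' Harmonic-mean F1 score
#'
#' `2 p r / (p + r)`, equivalently `TP / (TP + (FN + FP)/2)` on counts;
#' returns 0 when both precision and recall are 0.
#'
#' @param precision,recall Numeric vectors in [0, 1].
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Per-stage classification report
#'
#' One-vs-rest precision, recall and F1 per stage, plus pooled accuracy
#' (`trace / total`). Stages with a zero denominator (never predicted or
#' absent from the test set) get 0 for the affected metric and are listed
#' in `attr(, "flagged")`.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble of class `stage_report` with columns `stage`, `n_test`,
#'   `n_correct`, `precision`, `recall`, `f1`; overall accuracy in
#'   `attr(, "accuracy")`, the confusion matrix in `attr(, "confusion")`.
#' @export
classification_report <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  precision <- ifelse(col_tot > 0, tp / col_tot, 0)
  recall <- ifelse(row_tot > 0, tp / row_tot, 0)
  out <- tibble(
    stage = stage_factor(rownames(m)),
    n_test = as.integer(row_tot),
    n_correct = as.integer(tp),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = f1_score(as.numeric(precision), as.numeric(recall))
  )
  attr(out, "accuracy") <- sum(tp) / total
  attr(out, "confusion") <- cm
  attr(out, "flagged") <- rownames(m)[col_tot == 0 | row_tot == 0]
  class(out) <- c("stage_report", class(out))
  out
}

#' One-row summary of a classification report
#'
#' @param x A `stage_report`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `macro_f1`, `kappa`, `n`.
#' @export
glance.stage_report <- function(x, ...) {
  cm <- attr(x, "confusion")
  tibble(
    accuracy = attr(x, "accuracy"),
    macro_f1 = mean(x$f1),
    kappa = cohen_kappa(cm),
    n = sum(x$n_test)
  )
}

#' Agreement (coincidence) rate between two staging runs
#'
#' @param pred_a,pred_b Stage vectors of equal length.
#' @return Fraction of positions assigned the same stage.
#' @export
agreement_rate <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    stop("staging runs must have the same length", call. = FALSE)
  }
  mean(as.character(pred_a) == as.character(pred_b))
}

#' Cohen's kappa of a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from the
#' marginal products.
#'
#' @param cm A [confusion_matrix()] (or any square count matrix).
#' @return Scalar kappa.
#' @export
cohen_kappa <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) stop("degenerate marginals: chance agreement is 1",
                    call. = FALSE)
  (po - pe) / (1 - pe)
}
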