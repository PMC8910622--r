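# The four classifier configurations. Each model owns its feature scaling
# (z-score for the SVM, min-max for the neural network, none for the
# trees), fitted on training data only and replayed at prediction time.

#' Classifier specification
#'
#' Builds the configuration for one of the four supported classifiers with
#' the package defaults:
#' * `"SVM"`: RBF kernel, `cost = 1.3`, `gamma = 0.03`, one-vs-rest over
#'   the five stages, z-score feature scaling. (`kernel = "linear"` is
#'   accepted for a linear machine, in which case `gamma` is ignored.)
#' * `"BPNN"`: backpropagation multilayer perceptron, two hidden layers of
#'   18 sigmoid units, softmax output over the five stages, learning rate
#'   0.1, at most 500 epochs with early stopping on a 10% validation
#'   split, min-max scaling to [0, 1].
#' * `"DT"`: entropy-criterion decision tree, maximum depth 11, minimum
#'   leaf size 11, no scaling.
#' * `"RF"`: random forest of 100 Gini trees, maximum depth 22, minimum
#'   leaf size 5, no scaling.
#'
#' @param kind One of `"SVM"`, `"BPNN"`, `"DT"`, `"RF"`.
#' @param seed Integer seed governing every stochastic element of the fit.
#' @param ... Overrides of the kind-specific defaults listed above.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(kind = c("RF", "SVM", "BPNN", "DT"), seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    SVM = list(kernel = "radial", cost = 1.3, gamma = 0.03,
               scaling = "zscore"),
    BPNN = list(hidden = c(18, 18), learn_rate = 0.1, max_epochs = 500,
                momentum = 0.9, val_frac = 0.1, patience = 25,
                scaling = "minmax"),
    DT = list(max_depth = 11, min_leaf = 11, scaling = "none"),
    RF = list(num_trees = 100, max_depth = 22, min_leaf = 5,
              scaling = "none")
  )
  spec <- modifyList(defaults, list(...))
  spec$kind <- kind
  spec$seed <- as.integer(seed)
  structure(spec, class = "model_spec")
}

fit_scaler <- function(x, type) {
  switch(type,
    none = list(type = "none"),
    zscore = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0] <- 1
      list(type = "zscore", center = ctr, scale = scl)
    },
    minmax = {
      lo <- apply(x, 2, min)
      rg <- apply(x, 2, max) - lo
      rg[rg == 0] <- 1
      list(type = "minmax", center = lo, scale = rg)
    },
    stop("unknown scaling type: ", type, call. = FALSE)
  )
}

apply_scaler <- function(scaler, x) {
  if (scaler$type == "none") return(as.matrix(x))
  sweep(sweep(as.matrix(x), 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Fit a sleep-stage classifier
#'
#' Fits the classifier described by `spec` to a labelled feature table.
#' The feature scaler (if any) is fitted on this data only and stored with
#' the model; prediction matches columns by name, not position.
#'
#' @param data Tibble with a `stage` column and numeric feature columns.
#' @param spec A [model_spec()].
#' @param features Optional character vector restricting the feature set
#'   (e.g. from [select_by_threshold()]); default: all non-label columns.
#' @param stage_col Name of the label column.
#' @return Object of class `sleep_stager`.
#' @export
fit_stager <- function(data, spec = model_spec("RF"), features = NULL,
                       stage_col = "stage") {
  stopifnot(inherits(spec, "model_spec"))
  y <- stage_factor(data[[stage_col]])
  features <- features %||% setdiff(names(data), stage_col)
  x <- as.matrix(data[features])
  if (!all(is.finite(x))) stop("feature table contains non-finite values",
                               call. = FALSE)
  if (length(unique(as.character(y))) < 2) {
    stop("training labels must cover at least two stages", call. = FALSE)
  }
  scaler <- fit_scaler(x, spec$scaling)
  xs <- apply_scaler(scaler, x)
  fit <- switch(spec$kind,
    SVM = fit_svm_ovr(xs, y, spec),
    BPNN = fit_mlp(xs, y, spec),
    DT = fit_dt(xs, y, spec),
    RF = ranger::ranger(
      x = as.data.frame(xs), y = droplevels(y),
      num.trees = spec$num_trees, max.depth = spec$max_depth,
      min.node.size = spec$min_leaf, seed = spec$seed, num.threads = 1,
      importance = "impurity"
    )
  )
  structure(
    list(spec = spec, scaler = scaler, feature_names = features,
         levels = levels(y), fit = fit, n_train = nrow(xs)),
    class = "sleep_stager"
  )
}

# One-vs-rest RBF/linear SVM: one binary machine per stage, prediction by
# the largest decision value.
fit_svm_ovr <- function(xs, y, spec) {
  present <- levels(droplevels(y))
  fits <- lapply(present, function(lvl) {
    yy <- factor(ifelse(y == lvl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x = xs, y = yy, kernel = spec$kernel, cost = spec$cost,
               gamma = if (spec$kernel == "radial") spec$gamma else 1,
               scale = FALSE)
  })
  names(fits) <- present
  fits
}

predict_svm_ovr <- function(fits, xs, all_levels) {
  dv <- vapply(fits, function(f) {
    d <- attr(predict(f, xs, decision.values = TRUE), "decision.values")
    as.numeric(d) * if (colnames(d) == "pos/neg") 1 else -1
  }, numeric(nrow(xs)))
  if (nrow(xs) == 1) dv <- matrix(dv, nrow = 1, dimnames = list(NULL, names(fits)))
  factor(names(fits)[max.col(dv, ties.method = "first")], levels = all_levels)
}

fit_dt <- function(xs, y, spec) {
  df <- as.data.frame(xs)
  df$.stage <- droplevels(y)
  rpart::rpart(
    .stage ~ ., data = df, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(
      maxdepth = spec$max_depth, minbucket = spec$min_leaf,
      minsplit = 2 * spec$min_leaf, cp = 0, xval = 0
    )
  )
}

# ---- backpropagation MLP ----------------------------------------------------
# Compact two-hidden-layer perceptron: sigmoid hidden units, softmax
# output, cross-entropy loss, mini-batch stochastic gradient descent with
# momentum, early stopping on a held-out validation fraction.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(w, x) {
  a1 <- sigmoid(sweep(x %*% w$W1, 2, w$b1, "+"))
  a2 <- sigmoid(sweep(a1 %*% w$W2, 2, w$b2, "+"))
  z3 <- sweep(a2 %*% w$W3, 2, w$b3, "+")
  z3 <- z3 - apply(z3, 1, max)
  p <- exp(z3)
  p <- p / rowSums(p)
  list(a1 = a1, a2 = a2, p = p)
}

fit_mlp <- function(xs, y, spec) {
  y <- droplevels(y)
  k <- nlevels(y)
  d <- ncol(xs)
  h <- spec$hidden
  n <- nrow(xs)
  batch <- 32L
  withr::with_seed(spec$seed, {
    init <- function(nr, nc) matrix(runif(nr * nc, -0.5, 0.5) / sqrt(nr),
                                    nr, nc)
    w <- list(W1 = init(d, h[1]), b1 = numeric(h[1]),
              W2 = init(h[1], h[2]), b2 = numeric(h[2]),
              W3 = init(h[2], k), b3 = numeric(k))
    n_val <- max(1L, floor(spec$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0) tr_idx <- seq_len(n)
    Y <- diag(k)[as.integer(y), , drop = FALSE]
    xt <- xs[tr_idx, , drop = FALSE]; yt <- Y[tr_idx, , drop = FALSE]
    xv <- xs[val_idx, , drop = FALSE]; yv <- Y[val_idx, , drop = FALSE]
    vel <- lapply(w, function(z) z * 0)
    best <- w; best_loss <- Inf; stall <- 0L
    nt <- nrow(xt)
    for (ep in seq_len(spec$max_epochs)) {
      ord <- sample.int(nt)
      for (start in seq(1L, nt, by = batch)) {
        sel <- ord[start:min(start + batch - 1L, nt)]
        xb <- xt[sel, , drop = FALSE]; yb <- yt[sel, , drop = FALSE]
        fw <- mlp_forward(w, xb)
        dz3 <- (fw$p - yb) / nrow(xb)
        g <- list()
        g$W3 <- crossprod(fw$a2, dz3); g$b3 <- colSums(dz3)
        dz2 <- (dz3 %*% t(w$W3)) * fw$a2 * (1 - fw$a2)
        g$W2 <- crossprod(fw$a1, dz2); g$b2 <- colSums(dz2)
        dz1 <- (dz2 %*% t(w$W2)) * fw$a1 * (1 - fw$a1)
        g$W1 <- crossprod(xb, dz1); g$b1 <- colSums(dz1)
        for (nm in names(w)) {
          vel[[nm]] <- spec$momentum * vel[[nm]] -
            spec$learn_rate * g[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
      }
      pv <- mlp_forward(w, xv)$p
      val_loss <- -mean(log(pmax(rowSums(pv * yv), 1e-12)))
      if (val_loss < best_loss - 1e-6) {
        best <- w; best_loss <- val_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$patience) break
      }
    }
  })
  list(weights = best, classes = levels(y))
}

#' Predict stages with a fitted classifier
#'
#' @param object A `sleep_stager` from [fit_stager()].
#' @param newdata Tibble containing (at least) the feature columns the
#'   model was trained on; order is irrelevant, names are matched.
#' @param ... Unused.
#' @return Factor of predicted stages, one per row.
#' @export
predict.sleep_stager <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[object$feature_names])
  if (nrow(x) == 0) return(factor(character(0), levels = object$levels))
  xs <- apply_scaler(object$scaler, x)
  out <- switch(object$spec$kind,
    SVM = predict_svm_ovr(object$fit, xs, object$levels),
    BPNN = {
      p <- mlp_forward(object$fit$weights, xs)$p
      factor(object$fit$classes[max.col(p, ties.method = "first")],
             levels = object$levels)
    },
    DT = {
      cls <- predict(object$fit, as.data.frame(xs), type = "class")
      factor(as.character(cls), levels = object$levels)
    },
    RF = {
      pr <- predict(object$fit, data = as.data.frame(xs),
                    num.threads = 1)$predictions
      factor(as.character(pr), levels = object$levels)
    }
  )
  out
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat(sprintf("<sleep_stager> %s, %d features, %d training epochs\n",
              x$spec$kind, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Tidy a fitted classifier
#'
#' For a random forest, per-feature impurity importances (normalized to
#' sum 1); for the other kinds, the feature names in training order.
#'
#' @param x A `sleep_stager`.
#' @param ... Unused.
#' @return Tibble with column `feature` (plus `weight` for `"RF"`).
#' @export
tidy.sleep_stager <- function(x, ...) {
  if (x$spec$kind == "RF" && !is.null(x$fit$variable.importance)) {
    w <- x$fit$variable.importance
    return(tibble(feature = names(w), weight = as.numeric(w / sum(w))))
  }
  tibble(feature = x$feature_names)
}

#' One-row summary of a fitted classifier
#'
#' @param x A `sleep_stager`.
#' @param ... Unused.
#' @return Tibble with `kind`, `n_features`, `n_train`, `scaling`, `seed`.
#' @export
glance.sleep_stager <- function(x, ...) {
  tibble(kind = x$spec$kind, n_features = length(x$feature_names),
         n_train = x$n_train, scaling = x$spec$scaling, seed = x$spec$seed)
}
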