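#' Stratified train/test split of a labelled dataset
#'
#' The classifier comparison uses a 7:3 split; stratification keeps the
#' per-class proportions (the corpus is balanced at 100 curves per class, so
#' the default yields 70/30 per class, 420/180 overall).
#'
#' @param ds a `curve_dataset`.
#' @param train_fraction fraction of samples for training, in (0, 1).
#' @param stratified split within each class (default TRUE).
#' @param seed integer seed controlling membership.
#' @return list with `train` and `test`, both `curve_dataset`s.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, stratified = TRUE,
                          seed = 1L) {
  stopifnot(inherits(ds, "curve_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  n <- nrow(ds$rfu)
  if (n == 0L) stop("dataset is empty", call. = FALSE)
  take <- function(ds, idx) {
    structure(list(rfu = ds$rfu[idx, , drop = FALSE],
                   label = ds$label[idx],
                   well_id = ds$well_id[idx],
                   config = ds$config),
              class = "curve_dataset")
  }
  idx_train <- .with_seed(seed, {
    if (stratified) {
      present <- levels(droplevels(ds$label))
      small <- present[vapply(present, function(l) sum(ds$label == l), 0L) < 2L]
      if (length(small))
        stop("stratified split needs >= 2 samples per class; too few in: ",
             paste(small, collapse = ", "), call. = FALSE)
      unlist(lapply(present, function(l) {
        members <- which(ds$label == l)
        k <- round(length(members) * train_fraction)
        k <- min(max(k, 1L), length(members) - 1L)
        sample(members, k)
      }), use.names = FALSE)
    } else {
      sample.int(n, round(n * train_fraction))
    }
  })
  list(train = take(ds, sort(idx_train)),
       test = take(ds, setdiff(seq_len(n), idx_train)))
}

#' Model specification: family plus hyperparameter grid
#'
#' The five families compared for curve classification, with small
#' exhaustive grids (the published comparison names only the winning SVC
#' point, C = 0.5, RBF kernel, gamma = 1, which the default SVC grid
#' contains):
#' * `svc` -- support vector classifier, C in \{0.1, 0.5, 1, 10\},
#'   gamma in \{0.1, 0.5, 1, "scale"\} for the RBF kernel, plus linear.
#' * `lrc` -- ridge multinomial logistic regression, C in \{0.1, 1, 10\}.
#' * `knn` -- k-nearest neighbours, k in \{1, 3, 5, 7\}.
#' * `dtc` -- CART decision tree, depth in \{3, 5, 10, unlimited\}.
#' * `lda` -- linear discriminant analysis (no tunables).
#'
#' @param family one of `"svc"`, `"lrc"`, `"knn"`, `"dtc"`, `"lda"`.
#' @param grid list of named hyperparameter lists; defaults per family.
#' @param cv_folds cross-validation folds (default 5, >= 2).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("svc", "lrc", "knn", "dtc", "lda"),
                       grid = NULL, cv_folds = 5L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (!length(grid)) stop("hyperparameter grid is empty", call. = FALSE)
  if (cv_folds < 2L) stop("`cv_folds` must be >= 2", call. = FALSE)
  structure(list(family = family, grid = grid,
                 cv_folds = as.integer(cv_folds)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_grid <- function(family) {
  switch(family,
    svc = {
      g <- list()
      for (C in c(0.1, 0.5, 1, 10))
        for (gamma in list(0.1, 0.5, 1, "scale"))
          g[[length(g) + 1L]] <- list(C = C, kernel = "rbf", gamma = gamma)
      for (C in c(0.1, 0.5, 1, 10))
        g[[length(g) + 1L]] <- list(C = C, kernel = "linear", gamma = NA)
      g
    },
    lrc = lapply(c(0.1, 1, 10), function(C) list(C = C)),
    knn = lapply(c(1L, 3L, 5L, 7L), function(k) list(k = k)),
    dtc = lapply(list(3, 5, 10, Inf), function(d) list(max_depth = d)),
    lda = list(list()),
    stop("unknown family: ", family, call. = FALSE)
  )
}

# dispatch one (family, params) fit; x normalized, y factor
.fit_family <- function(family, params, x, y) {
  switch(family,
    svc = svc_fit(x, y, C = params$C, kernel = params$kernel,
                  gamma = if (identical(params$gamma, "scale") ||
                              is.na(params$gamma)) "scale" else params$gamma),
    knn = knn_fit(x, y, k = params$k),
    dtc = tree_fit(x, y, max_depth = params$max_depth),
    lrc = {
      # fit along a decreasing lambda path for stability, keep the target
      lam <- 1 / (nrow(x) * params$C)
      path <- exp(seq(log(max(lam * 1e3, 1)), log(lam), length.out = 30))
      fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                            lambda = path, standardize = FALSE, maxit = 1e6)
      structure(list(fit = fit, lambda = lam, levels = levels(y)),
                class = "lrc_model")
    },
    lda = {
      fit <- suppressWarnings(MASS::lda(x, grouping = y))
      structure(list(fit = fit, levels = levels(y)), class = "lda_model")
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' @export
predict.lrc_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  cls <- as.character(predict(object$fit, newx = newdata, type = "class",
                              s = object$lambda))
  factor(cls, levels = object$levels)
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  colnames(newdata) <- colnames(object$fit$means)
  factor(as.character(predict(object$fit, newdata)$class),
         levels = object$levels)
}

# stratified fold assignment, deterministic given seed
.cv_folds <- function(y, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(y))
    for (l in levels(droplevels(y))) {
      members <- sample(which(y == l))
      fold[members] <- rep_len(seq_len(k), length(members))
    }
    fold
  })
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Every grid point is scored by mean accuracy over the same stratified
#' folds of the training split; the best point is the argmax, ties broken by
#' grid order.
#'
#' @param spec a [model_spec()].
#' @param x normalized training feature matrix.
#' @param y factor of training labels.
#' @param seed integer seed for the fold assignment.
#' @return list with `best_params`, `best_score`, and `results` (a
#'   data.frame with one row per grid point, in grid order).
#' @export
grid_search <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  smallest <- min(table(y))
  if (spec$cv_folds > smallest)
    stop("cv_folds (", spec$cv_folds, ") exceeds the smallest class count (",
         smallest, ")", call. = FALSE)
  fold <- .cv_folds(y, spec$cv_folds, seed)
  scores <- vapply(spec$grid, function(params) {
    accs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold != f
      model <- .fit_family(spec$family, params, x[tr, , drop = FALSE], y[tr])
      mean(predict(model, x[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(accs)
  }, 0)
  best <- which.max(scores) # first max = grid order tie-break
  list(best_params = spec$grid[[best]],
       best_score = scores[best],
       results = data.frame(
         point = vapply(spec$grid, function(p)
           paste(names(p), vapply(p, format, ""), sep = "=", collapse = ","),
           ""),
         cv_accuracy = scores))
}

#' Train the final (frozen) classifier
#'
#' @param family model family, see [model_spec()].
#' @param params named list of hyperparameters (e.g. the `best_params` of
#'   [grid_search()]).
#' @param x normalized training feature matrix.
#' @param y factor of training labels.
#' @return A `curve_model` wrapping the fitted classifier; all families are
#'   deterministic given the data, and the object survives
#'   [model_save()] / [model_load()] with identical predictions.
#' @export
train_final <- function(family, params, x, y) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  fit <- .fit_family(family, params, x, y)
  structure(list(family = family, params = params, fit = fit,
                 levels = levels(y)),
            class = "curve_model")
}

#' @export
predict.curve_model <- function(object, newdata, ...) {
  predict(object$fit, newdata)
}

#' @rdname train_final
#' @param model a `curve_model`.
#' @param path file path for the serialized model.
#' @export
model_save <- function(model, path) {
  stopifnot(inherits(model, "curve_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname train_final
#' @export
model_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "curve_model"))
    stop("file does not contain a curve_model: ", path, call. = FALSE)
  model
}

#' Evaluate a classifier on a held-out set
#'
#' Produces the four macro-averaged scores and the 6x6 confusion matrix
#' (rows = true class, columns = predicted class): the row sums are the true
#' per-class counts and accuracy is the trace over the total. Per-class
#' precision/recall with an empty denominator count as 0 before averaging.
#'
#' @param model a `curve_model` (or any object with a `predict` method
#'   returning a factor on the same levels).
#' @param x normalized feature matrix of the held-out set.
#' @param y factor of true labels.
#' @return An `eval_report`: list with `precision`, `recall`, `accuracy`,
#'   `f1` and `confusion`.
#' @export
evaluate <- function(model, x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("test set is empty", call. = FALSE)
  lv <- if (!is.null(model$levels)) model$levels else levels(as.factor(y))
  y <- as.character(y)
  bad <- setdiff(unique(y), lv)
  if (length(bad))
    stop("test labels outside the model's classes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  truth <- factor(y, levels = lv)
  pred <- factor(as.character(predict(model, x)), levels = lv)
  confusion <- table(truth = truth, predicted = pred)
  tp <- diag(confusion)
  per_prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  per_rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  per_f1 <- ifelse(per_prec + per_rec > 0,
                   2 * per_prec * per_rec / (per_prec + per_rec), 0)
  structure(list(precision = mean(per_prec),
                 recall = mean(per_rec),
                 accuracy = sum(tp) / sum(confusion),
                 f1 = mean(per_f1),
                 confusion = unclass(confusion)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  accuracy %.4f  f1 %.4f\n",
              x$precision, x$recall, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Classify a single curve
#'
#' Normalizes the trace with the training-set normalizer, predicts the
#' six-way morphology class and returns it with its three-way verdict group.
#'
#' @param model a `curve_model`.
#' @param normalizer a `curve_normalizer` from [normalize_fit()].
#' @param curve a [fluorescence_curve()] (or numeric vector).
#' @return list with `label` and `group`.
#' @export
predict_curve <- function(model, normalizer, curve) {
  z <- normalize_apply(normalizer, curve)
  label <- as.character(predict(model, matrix(z, nrow = 1)))
  list(label = label, group = curve_group(label))
}
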