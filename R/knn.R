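#' k-nearest-neighbour classifier
#'
#' Plain Euclidean kNN with majority vote; vote ties resolved toward the
#' earlier class in level order (deterministic).
#'
#' @param x numeric training matrix (rows = samples), normalized.
#' @param y factor of labels.
#' @param k number of neighbours.
#' @return A `knn_model` (the training data plus `k`).
#' @export
knn_fit <- function(x, y, k = 5L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(k >= 1, k <= nrow(x), nrow(x) == length(y))
  structure(list(x = x, y = y, k = as.integer(k)), class = "knn_model")
}

#' @rdname knn_fit
#' @param object a `knn_model`.
#' @param newdata numeric matrix or vector.
#' @param ... unused.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  tr <- object$x
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(newdata^2), rowSums(tr^2), "+") -
    2 * newdata %*% t(tr)
  lv <- levels(object$y)
  out <- apply(d2, 1, function(row) {
    nb <- object$y[order(row)[seq_len(object$k)]]
    counts <- tabulate(nb, nbins = length(lv))
    which.max(counts) # first max = earlier level on ties
  })
  factor(lv[out], levels = lv)
}
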