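#' CART decision-tree classifier
#'
#' Greedy binary CART on numeric features with Gini impurity, grown to
#' `max_depth` (Inf = unlimited) with a minimum node size to split. Split
#' thresholds are midpoints between consecutive distinct feature values;
#' ties in impurity gain go to the earlier feature / lower threshold, so
#' training is deterministic.
#'
#' @param x numeric feature matrix.
#' @param y factor of labels.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_split smallest node size that may be split (default 2).
#' @return A `tree_model`.
#' @export
tree_fit <- function(x, y, max_depth = Inf, min_split = 2L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y), max_depth >= 0)
  lv <- levels(y)
  yi <- as.integer(y)

  gini <- function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    1 - sum((counts / n)^2)
  }

  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], nbins = length(lv))
    node_pred <- which.max(counts)
    if (depth >= max_depth || length(idx) < min_split ||
        sum(counts > 0) == 1L)
      return(list(leaf = TRUE, pred = node_pred, n = length(idx)))
    parent_imp <- gini(counts)
    best <- NULL
    n <- length(idx)
    for (f in seq_len(ncol(x))) {
      xv <- x[idx, f]
      ord <- order(xv)
      xs <- xv[ord]; ys <- yi[idx][ord]
      cut_at <- which(diff(xs) > 0) # split between positions i and i+1
      if (!length(cut_at)) next
      # cumulative class counts along the sorted order, vectorized per class
      csum <- vapply(seq_along(lv), function(cl) cumsum(ys == cl),
                     numeric(n))
      nL <- seq_len(n)
      nR <- n - nL
      giniL <- 1 - rowSums((csum / nL)^2)
      rcounts <- sweep(-csum, 2, counts, "+")
      giniR <- 1 - rowSums((rcounts / pmax(nR, 1))^2)
      gain <- parent_imp - (nL * giniL + nR * giniR) / n
      gi <- gain[cut_at]
      i <- cut_at[which.max(gi)]
      g <- gain[i]
      if (g > 1e-12 && (is.null(best) || g > best$gain + 1e-12)) {
        best <- list(gain = g, feature = f,
                     threshold = (xs[i] + xs[i + 1]) / 2)
      }
    }
    if (is.null(best))
      return(list(leaf = TRUE, pred = node_pred, n = length(idx)))
    go_left <- x[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         n = length(idx), pred = node_pred,
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }

  structure(list(root = grow(seq_len(nrow(x)), 0), levels = lv),
            class = "tree_model")
}

#' @rdname tree_fit
#' @param object a `tree_model`.
#' @param newdata numeric matrix or vector.
#' @param ... unused.
#' @export
predict.tree_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  one <- function(v) {
    node <- object$root
    while (!node$leaf)
      node <- if (v[node$feature] <= node$threshold) node$left else node$right
    node$pred
  }
  idx <- apply(newdata, 1, one)
  factor(object$levels[idx], levels = object$levels)
}
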