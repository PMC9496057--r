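#' Support vector classifier (RBF / linear kernel, one-vs-one multiclass)
#'
#' C-SVC trained by sequential minimal optimization with maximal-violating-
#' pair working-set selection (compiled). Multiclass is handled by
#' one-vs-one voting over all class pairs; vote ties go to the earlier class
#' in level order. `gamma = "scale"` uses `1 / (n_features * var(x))`, the
#' convention of the reference toolkit the platform was prototyped with.
#'
#' @param x numeric feature matrix (rows = samples), already normalized.
#' @param y factor of class labels.
#' @param C box constraint (> 0).
#' @param kernel `"rbf"` or `"linear"`.
#' @param gamma RBF width, a positive number or `"scale"`; ignored for the
#'   linear kernel.
#' @param eps SMO stopping tolerance on the KKT gap.
#' @return An `svc_model`.
#' @export
svc_fit <- function(x, y, C = 1, kernel = c("rbf", "linear"), gamma = "scale",
                    eps = 1e-3) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(C > 0, nrow(x) == length(y), nlevels(y) >= 2)
  gamma_num <- if (identical(gamma, "scale")) {
    v <- mean(apply(x, 2, var)) * (nrow(x) - 1) / nrow(x) # population variance
    if (v <= 0) 1 else 1 / (ncol(x) * v)
  } else as.numeric(gamma)
  ktype <- if (kernel == "rbf") 0L else 1L
  lv <- levels(y)
  pairs <- utils::combn(seq_along(lv), 2)
  fits <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    idx <- which(y == lv[a] | y == lv[b])
    yy <- ifelse(y[idx] == lv[a], 1, -1)
    fits[[p]] <- .smo_train(x[idx, , drop = FALSE], yy, C, ktype, gamma_num,
                            eps = eps)
  }
  structure(list(fits = fits, pairs = pairs, levels = lv, kernel = kernel,
                 ktype = ktype, gamma = gamma_num, C = C),
            class = "svc_model")
}

#' @rdname svc_fit
#' @param object an `svc_model`.
#' @param newdata numeric matrix or vector of normalized features.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.svc_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  votes <- matrix(0L, nrow(newdata), length(object$levels))
  for (p in seq_len(ncol(object$pairs))) {
    f <- object$fits[[p]]
    dec <- .smo_decision(newdata, f$sv, f$coef, f$rho,
                         object$ktype, object$gamma)
    a <- object$pairs[1, p]; b <- object$pairs[2, p]
    pos <- dec >= 0
    votes[pos, a] <- votes[pos, a] + 1L
    votes[!pos, b] <- votes[!pos, b] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
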