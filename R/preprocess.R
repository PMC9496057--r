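#' Fit a per-feature z-score normalizer on a training set
#'
#' Classification consumes distance- and kernel-based models, so features
#' (the per-cycle fluorescence readings) are brought to a common scale by
#' per-feature standardization fitted on the training split only: each cycle
#' column is centred at its training mean and divided by its training
#' standard deviation. Zero-variance columns keep scale 1 so they map to 0.
#'
#' @param train a `curve_dataset` (or plain numeric matrix) of training
#'   curves, one row per curve.
#' @return A `curve_normalizer` with fields `center` and `scale`
#'   (length = number of cycles).
#' @seealso [normalize_apply()], [normalize_invert()]
#' @export
normalize_fit <- function(train) {
  x <- if (inherits(train, "curve_dataset")) train$rfu else as.matrix(train)
  if (nrow(x) == 0L) stop("training set is empty", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "curve_normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param state a `curve_normalizer` from [normalize_fit()].
#' @param x a [fluorescence_curve()], numeric vector, or matrix with one row
#'   per curve; its length/width must match the normalizer.
#' @return Numeric vector or matrix of standardized features.
#' @export
normalize_apply <- function(state, x) {
  stopifnot(inherits(state, "curve_normalizer"))
  v <- if (inherits(x, "fluorescence_curve")) x$rfu
       else if (inherits(x, "curve_dataset")) x$rfu
       else x
  p <- length(state$center)
  if (is.matrix(v)) {
    if (ncol(v) != p)
      stop("curve length ", ncol(v), " does not match normalizer length ", p,
           call. = FALSE)
    sweep(sweep(v, 2, state$center), 2, state$scale, "/")
  } else {
    if (length(v) != p)
      stop("curve length ", length(v), " does not match normalizer length ", p,
           call. = FALSE)
    (v - state$center) / state$scale
  }
}

#' @rdname normalize_apply
#' @export
normalize_invert <- function(state, x) {
  stopifnot(inherits(state, "curve_normalizer"))
  if (is.matrix(x))
    sweep(sweep(x, 2, state$scale, "*"), 2, state$center, "+")
  else x * state$scale + state$center
}

#' Principal-component projection of a dataset
#'
#' Mean-centred projection of the curves onto the leading orthogonal
#' directions of variance, used to eyeball class separation in 2-D. The sign
#' of each component is fixed so its largest-magnitude loading is positive,
#' making plots reproducible across runs and platforms.
#'
#' @param ds a `curve_dataset` or numeric matrix (rows = curves).
#' @param n_components number of components to keep (default 2).
#' @param scale. standardize columns first (default FALSE: raw features are
#'   already on one fluorescence scale).
#' @return A list: `coords` (n x n_components score matrix), `loadings`,
#'   `explained_variance` (descending), and `label` when `ds` carries one.
#' @export
pca_project <- function(ds, n_components = 2L, scale. = FALSE) {
  x <- if (inherits(ds, "curve_dataset")) ds$rfu else as.matrix(ds)
  if (n_components > ncol(x))
    stop("n_components (", n_components, ") exceeds the number of features (",
         ncol(x), ")", call. = FALSE)
  if (nrow(x) < n_components)
    stop("need at least ", n_components, " samples", call. = FALSE)
  constant <- all(abs(sweep(x, 2, colMeans(x))) < .Machine$double.eps * 100)
  if (constant) {
    coords <- matrix(0, nrow(x), n_components)
    load <- matrix(0, ncol(x), n_components)
    ev <- rep(0, n_components)
  } else {
    pc <- prcomp(x, center = TRUE, scale. = scale., rank. = n_components)
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    coords <- sweep(pc$x, 2, flip, "*")
    load <- sweep(pc$rotation, 2, flip, "*")
    ev <- pc$sdev[seq_len(n_components)]^2
  }
  colnames(coords) <- paste0("pc", seq_len(n_components))
  out <- list(coords = coords, loadings = load, explained_variance = ev)
  if (inherits(ds, "curve_dataset")) out$label <- ds$label
  out
}

#' Cluster-separation summary of a 2-D projection
#'
#' For each class, the centroid in PC space and the mean member distance to
#' it; plus the pairwise centroid distance matrix. Quantifies the "visibly
#' separated clusters" check on the simulated corpus.
#'
#' @param proj result of [pca_project()] carrying a `label`.
#' @return list with `centroids`, `within` (named mean distance-to-centroid
#'   per class) and `between` (centroid distance matrix).
#' @export
pca_separation <- function(proj) {
  stopifnot(!is.null(proj$label))
  lv <- levels(proj$label)
  cent <- t(vapply(lv, function(l) colMeans(proj$coords[proj$label == l, , drop = FALSE]),
                   numeric(ncol(proj$coords))))
  within <- vapply(lv, function(l) {
    d <- sweep(proj$coords[proj$label == l, , drop = FALSE], 2, cent[l, ])
    mean(sqrt(rowSums(d^2)))
  }, 0)
  between <- as.matrix(dist(cent))
  list(centroids = cent, within = within, between = between)
}
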