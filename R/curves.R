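#' Amplification-curve container
#'
#' A `fluorescence_curve` holds one well's trace: the ordered cycle indices
#' (1-based consecutive integers) and the relative fluorescence read at the
#' end of each cycle.
#'
#' @param rfu numeric vector of fluorescence values (arbitrary relative
#'   units), one per cycle, all finite, length >= 10.
#' @param cycles integer cycle indices; defaults to `1:length(rfu)`. Must be
#'   consecutive integers starting at 1.
#' @param well_id optional identifier string.
#' @return An object of class `fluorescence_curve`.
#' @examples
#' fc <- fluorescence_curve(c(rep(0.05, 20), plogis(seq(-3, 6, length.out = 20))))
#' length(fc$rfu)
#' @export
fluorescence_curve <- function(rfu, cycles = seq_along(rfu), well_id = NULL) {
  rfu <- as.numeric(rfu)
  cycles <- as.integer(cycles)
  if (length(cycles) != length(rfu))
    stop("`cycles` and `rfu` must have the same length", call. = FALSE)
  if (length(rfu) < 10)
    stop("a curve needs at least 10 cycles, got ", length(rfu), call. = FALSE)
  if (!all(is.finite(rfu)))
    stop("all `rfu` values must be finite", call. = FALSE)
  if (cycles[1] != 1L || any(diff(cycles) != 1L))
    stop("`cycles` must be consecutive integers starting at 1", call. = FALSE)
  structure(list(cycles = cycles, rfu = rfu, well_id = well_id),
            class = "fluorescence_curve")
}

#' @export
print.fluorescence_curve <- function(x, ...) {
  cat("<fluorescence_curve>",
      if (!is.null(x$well_id)) paste0("well ", x$well_id) else "",
      sprintf("%d cycles, rfu range [%.4g, %.4g]\n",
              length(x$cycles), min(x$rfu), max(x$rfu)))
  invisible(x)
}

#' Curve morphology classes and verdict groups
#'
#' The six morphology labels and the fixed mapping onto the three-way verdict
#' (positive / negative / abnormal).
#'
#' @return `curve_classes()` returns the six labels in canonical order;
#'   `curve_group(label)` returns the verdict group for each label.
#' @examples
#' curve_group("class_F")
#' @export
curve_classes <- function() {
  c("class_A", "class_B", "class_C", "class_D", "class_E", "class_F")
}

.class_groups <- c(class_A = "positive", class_B = "positive",
                   class_C = "negative",
                   class_D = "abnormal", class_E = "abnormal",
                   class_F = "abnormal")

#' @rdname curve_classes
#' @param label character vector of class labels.
#' @export
curve_group <- function(label) {
  label <- as.character(label)
  bad <- setdiff(label, curve_classes())
  if (length(bad))
    stop("unknown curve class: ", paste(bad, collapse = ", "), call. = FALSE)
  unname(.class_groups[label])
}
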