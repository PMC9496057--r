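#' Configuration for the curve simulator
#'
#' The simulator is a stand-in for the instrument corpus: the published work
#' gives the six morphologies and their causes but not generator equations,
#' so each class is the simplest parametric family matching its shape, on a
#' normalized full scale of 1 fluorescence unit.
#'
#' Class forms (before noise):
#' * `class_A`/`class_B`: 5PL sigmoid `b + A/(1+exp(-(x-x0)/k))^s` with
#'   midpoint `x0` drawn from `[18, 32]` (A, plateau reached) or `[30, 38]`
#'   (B, late onset). Class B's defining property -- the plateau is not
#'   reached by the final cycle -- is enforced by resampling `(x0, k, s)`
#'   within their ranges until the amplified fraction at the last cycle is
#'   at most `plateau_frac` (0.9).
#' * `class_C`: constant baseline.
#' * `class_D`: baseline plus a step of 10--30% of full scale in the last
#'   1--3 cycles.
#' * `class_E`: sigmoid whose amplified part is multiplied by a linear decay
#'   beyond its peak, so the trace rises then declines ("hook").
#' * `class_F`: linear ramp across all cycles (drift).
#'
#' Baseline `b ~ U(0.02, 0.10)` and amplitude `A ~ U(0.6, 1.0)` of full
#' scale; i.i.d. additive Gaussian noise (default sd 0.01 of full scale),
#' clipped at zero.
#'
#' @param n_cycles number of thermal cycles per curve (default 40, >= 10).
#' @param per_class_n curves per class (default 100, so 600 in total).
#' @param noise_sd additive Gaussian noise sd in normalized units (>= 0).
#' @param seed root integer seed; per-curve substreams are derived from it by
#'   counter, so changing `per_class_n` does not reshuffle earlier curves.
#' @return A list of class `sim_config`.
#' @seealso [simulate_curve()], [simulate_dataset()]
#' @export
sim_config <- function(n_cycles = 40L, per_class_n = 100L,
                       noise_sd = 0.01, seed = 1L) {
  n_cycles <- as.integer(n_cycles)
  per_class_n <- as.integer(per_class_n)
  if (is.na(n_cycles) || n_cycles < 10L) stop("`n_cycles` must be >= 10", call. = FALSE)
  if (is.na(per_class_n) || per_class_n < 1L) stop("`per_class_n` must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    n_cycles = n_cycles, per_class_n = per_class_n,
    noise_sd = noise_sd, seed = as.integer(seed),
    ranges = list(
      baseline  = c(0.02, 0.10),
      amplitude = c(0.60, 1.00),
      x0_A = c(18, 32), x0_B = c(30, 38), x0_E = c(15, 25),
      k = c(0.8, 1.8), s = c(0.7, 1.4),
      plateau_frac = 0.9,
      step_height = c(0.10, 0.30), step_cycles = c(1L, 3L),
      hook_peak_offset = c(4, 8), hook_decay = c(0.015, 0.035)
    )
  ), class = "sim_config")
}

# derive a per-curve seed from (root seed, class index, counter); constants
# small enough that the product stays exact in double arithmetic
.curve_seed <- function(seed, class_idx, counter) {
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 69069 +
                class_idx * 7919 + counter * 131) %% 2147483629) + 1L
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.runif_range <- function(r) runif(1, r[1], r[2])

#' Simulate one amplification curve of a given morphology class
#'
#' @param label one of the six class labels, see [curve_classes()].
#' @param config a [sim_config()].
#' @param rng_state integer substream counter; together with `config$seed`
#'   and `label` it fully determines the curve.
#' @param params optional named list pinning generator parameters that would
#'   otherwise be drawn (`baseline`, `amplitude`, `x0`, `k`, `s`, `slope`,
#'   `step_height`, `step_cycles`, `hook_peak`, `hook_decay`). Used by tests
#'   and for ground-truth fixtures.
#' @return A [fluorescence_curve()].
#' @examples
#' cfg <- sim_config(noise_sd = 0)
#' simulate_curve("class_C", cfg, 1)$rfu[1:5]
#' @export
simulate_curve <- function(label, config = sim_config(), rng_state = 1L,
                           params = list()) {
  if (length(label) != 1L || !label %in% curve_classes())
    stop("unknown curve class: ", paste(label, collapse = ","), call. = FALSE)
  class_idx <- match(label, curve_classes())
  seed <- .curve_seed(config$seed, class_idx, rng_state)
  r <- config$ranges
  x <- seq_len(config$n_cycles)

  .with_seed(seed, {
    draw <- function(name, range) {
      if (!is.null(params[[name]])) params[[name]] else .runif_range(range)
    }
    b <- draw("baseline", r$baseline)
    A <- draw("amplitude", r$amplitude)
    clean <- switch(label,
      class_A = {
        x0 <- draw("x0", r$x0_A)
        k <- draw("k", r$k); s <- draw("s", r$s)
        b + A / (1 + exp(-(x - x0) / k))^s
      },
      class_B = {
        # defining property: the plateau is NOT reached by the last cycle
        # (amplified fraction <= plateau_frac there); resample within the
        # stated ranges until it holds
        nmax <- config$n_cycles
        repeat {
          x0 <- draw("x0", r$x0_B)
          k <- draw("k", r$k); s <- draw("s", r$s)
          frac_end <- 1 / (1 + exp(-(nmax - x0) / k))^s
          if (frac_end <= r$plateau_frac ||
              (!is.null(params$x0) && !is.null(params$k) && !is.null(params$s)))
            break
        }
        b + A / (1 + exp(-(x - x0) / k))^s
      },
      class_C = rep(b, length(x)),
      class_D = {
        h <- draw("step_height", r$step_height)
        j <- if (!is.null(params$step_cycles)) params$step_cycles
             else sample(r$step_cycles[1]:r$step_cycles[2], 1)
        out <- rep(b, length(x))
        out[(length(x) - j + 1):length(x)] <- b + h
        out
      },
      class_E = {
        x0 <- draw("x0", r$x0_E)
        k <- draw("k", r$k); s <- draw("s", r$s)
        xp <- if (!is.null(params$hook_peak)) params$hook_peak
              else x0 + .runif_range(r$hook_peak_offset)
        d <- draw("hook_decay", r$hook_decay)
        g <- 1 / (1 + exp(-(x - x0) / k))^s
        decay <- ifelse(x <= xp, 1, 1 - d * (x - xp))
        b + A * g * decay
      },
      class_F = {
        slope <- if (!is.null(params$slope)) params$slope
                 else A / (config$n_cycles - 1)
        b + slope * (x - 1)
      }
    )
    rfu <- clean + rnorm(length(x), 0, config$noise_sd)
    rfu <- pmax(rfu, 0)
    fluorescence_curve(rfu, x,
                       well_id = sprintf("%s_%03d", label, rng_state))
  })
}

#' Simulate the labelled six-class corpus
#'
#' Generates `per_class_n` curves for each of the six classes (defaults give
#' the 600-curve training corpus) and shuffles their order with the root
#' seed. Identical configurations produce bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @return A `curve_dataset`: list with `rfu` (n x n_cycles numeric matrix),
#'   `label` (factor over the six classes), `well_id`, and the `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(per_class_n = 2))
#' table(ds$label)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  labels <- curve_classes()
  n <- config$per_class_n * length(labels)
  rfu <- matrix(NA_real_, n, config$n_cycles)
  lab <- character(n)
  wid <- character(n)
  row <- 1L
  for (cl in labels) {
    for (i in seq_len(config$per_class_n)) {
      cur <- simulate_curve(cl, config, rng_state = i)
      rfu[row, ] <- cur$rfu
      lab[row] <- cl
      wid[row] <- cur$well_id
      row <- row + 1L
    }
  }
  ord <- .with_seed(config$seed, sample.int(n))
  structure(list(rfu = rfu[ord, , drop = FALSE],
                 label = factor(lab[ord], levels = labels),
                 well_id = wid[ord],
                 config = config),
            class = "curve_dataset")
}

#' @export
print.curve_dataset <- function(x, ...) {
  cat(sprintf("<curve_dataset> %d curves x %d cycles\n",
              nrow(x$rfu), ncol(x$rfu)))
  print(table(x$label))
  invisible(x)
}

#' Extract one curve from a dataset
#' @param ds a `curve_dataset`.
#' @param i row index.
#' @return A [fluorescence_curve()].
#' @export
dataset_curve <- function(ds, i) {
  fluorescence_curve(ds$rfu[i, ], well_id = ds$well_id[i])
}

#' Serialize / read a labelled dataset (CSV, one row per sample)
#'
#' Layout: header `label,c1,...,c<n>`; every row is the label followed by the
#' per-cycle fluorescence values (41 fields for 40 cycles). `read_dataset()`
#' checks the field count of every row and names the offending row on error.
#'
#' @param ds a `curve_dataset`.
#' @param path file path.
#' @return `read_dataset()` returns a `curve_dataset` (its `config` records
#'   only `n_cycles`; seed and ranges are not stored in the file).
#' @export
write_dataset <- function(ds, path) {
  df <- data.frame(label = as.character(ds$label), ds$rfu)
  names(df) <- c("label", paste0("c", seq_len(ncol(ds$rfu))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param n_cycles expected number of feature columns (default 40).
#' @export
read_dataset <- function(path, n_cycles = 40L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("parse error: file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  want <- n_cycles + 1L
  lens <- lengths(fields)
  bad <- which(lens != want)
  if (length(bad))
    stop(sprintf("parse error: row %d has %d fields, expected %d (label + %d cycles)",
                 bad[1], lens[bad[1]], want, n_cycles), call. = FALSE)
  header <- fields[[1]]
  if (header[1] != "label")
    stop("parse error: row 1: first column must be 'label'", call. = FALSE)
  body <- fields[-1]
  lab <- vapply(body, `[[`, "", 1L)
  unknown <- which(!lab %in% curve_classes())
  if (length(unknown))
    stop(sprintf("parse error: row %d has unknown label '%s'",
                 unknown[1] + 1L, lab[unknown[1]]), call. = FALSE)
  num <- matrix(NA_real_, length(body), n_cycles)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v))
      stop(sprintf("parse error: row %d has a non-numeric value", i + 1L),
           call. = FALSE)
    num[i, ] <- v
  }
  structure(list(rfu = num,
                 label = factor(lab, levels = curve_classes()),
                 well_id = sprintf("row_%04d", seq_along(body)),
                 config = list(n_cycles = n_cycles)),
            class = "curve_dataset")
}
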