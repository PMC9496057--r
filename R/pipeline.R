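#' Abnormal-cause lookup
#'
#' Maps an abnormal morphology class to the experimental cause reported to
#' the operator: an end-of-run jump (class_D) points to template
#' cross-contamination or low concentration; a rise-then-decline hook
#' (class_E) to severe evaporation or probe degradation; an upward drift
#' line (class_F) to slight evaporation.
#'
#' @param label an abnormal class label (`class_D`, `class_E`, `class_F`).
#' @return the cause string.
#' @export
anomaly_cause <- function(label) {
  causes <- c(
    class_D = "suspected cross-contamination of the template or low sample concentration",
    class_E = "severe evaporation of samples or probe degradation",
    class_F = "slight sample evaporation")
  label <- as.character(label)
  if (length(label) != 1L || !label %in% names(causes))
    stop("anomaly_cause is defined only for abnormal classes (class_D/E/F), got: ",
         paste(label, collapse = ","), call. = FALSE)
  unname(causes[label])
}

#' Risk level from a positive-result count
#'
#' Bins an instrument's cumulative positive count into four risk levels for
#' map display: level = 1 + number of thresholds strictly exceeded, so it is
#' monotone non-decreasing in the count and covers 1..4.
#'
#' @param positive_count non-negative integer count of positive results.
#' @param thresholds three strictly ascending integer cut points
#'   (default 10, 50, 100).
#' @return integer risk level in 1..4.
#' @examples
#' risk_level(0)    # 1
#' risk_level(101)  # 4
#' @export
risk_level <- function(positive_count, thresholds = c(10L, 50L, 100L)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop("`thresholds` must be 3 strictly ascending values", call. = FALSE)
  if (any(positive_count < 0) || any(positive_count != floor(positive_count)))
    stop("`positive_count` must be a non-negative integer", call. = FALSE)
  vapply(positive_count,
         function(n) 1L + sum(n > thresholds), integer(1))
}

#' End-to-end analysis of a batch of raw curves
#'
#' Implements the per-well flow: normalize the trace, classify it, then
#' branch on the verdict group -- positives get a 5PL fit and an SDM Ct,
#' abnormals get a cause string, negatives pass through. A failure on one
#' well (e.g. an uncallable positive) is recorded in that well's status and
#' never aborts the run.
#'
#' @param curves list of [fluorescence_curve()] objects (or a
#'   `curve_dataset`).
#' @param model a `curve_model` from [train_final()].
#' @param normalizer the training-set `curve_normalizer`.
#' @param metadata optional named list stored in the report (template name,
#'   instrument id, ...).
#' @param min_range passed to [call_ct()].
#' @return A `run_report`: list with `results` (one `curve_call` per well,
#'   in input order), `counts` (positive/negative/abnormal), and `metadata`.
#'   Each `curve_call` has `well_id`, `label`, `group`, `ct` (positives),
#'   `cause` (abnormals) and `status`.
#' @export
analyze_run <- function(curves, model, normalizer, metadata = list(),
                        min_range = 0.05) {
  if (inherits(curves, "curve_dataset"))
    curves <- lapply(seq_len(nrow(curves$rfu)), dataset_curve, ds = curves)
  results <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    cur <- curves[[i]]
    wid <- if (!is.null(cur$well_id)) cur$well_id else sprintf("well_%02d", i)
    res <- tryCatch({
      cls <- predict_curve(model, normalizer, cur)
      out <- list(well_id = wid, label = cls$label, group = cls$group,
                  ct = NA_real_, cause = NA_character_, status = "ok")
      if (cls$group == "positive") {
        cc <- call_ct(cur, min_range = min_range)
        out$ct <- cc$ct
        out$status <- cc$status
      } else if (cls$group == "abnormal") {
        out$cause <- anomaly_cause(cls$label)
      }
      out
    }, error = function(e) {
      list(well_id = wid, label = NA_character_, group = NA_character_,
           ct = NA_real_, cause = NA_character_,
           status = paste0("error: ", conditionMessage(e)))
    })
    results[[i]] <- structure(res, class = "curve_call")
  }
  groups <- vapply(results, function(r)
    if (is.na(r$group)) "failed" else r$group, "")
  counts <- c(positive = sum(groups == "positive"),
              negative = sum(groups == "negative"),
              abnormal = sum(groups == "abnormal"))
  structure(list(results = results, counts = counts, metadata = metadata),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d wells (positive %d, negative %d, abnormal %d)\n",
              length(x$results), x$counts["positive"], x$counts["negative"],
              x$counts["abnormal"]))
  for (r in x$results) {
    extra <- if (!is.na(r$ct)) sprintf("Ct %.2f", round_ct(r$ct))
             else if (!is.na(r$cause)) r$cause
             else r$status
    cat(sprintf("  %-12s %-8s %-9s %s\n", r$well_id, r$label, r$group, extra))
  }
  invisible(x)
}

#' Pearson agreement between reference and algorithm Ct values
#'
#' Method-agreement check against a reference instrument: the
#' product-moment correlation of paired Ct values and its two-sided p-value
#' from the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. The p-value is informational; no accept/reject threshold is
#' applied.
#'
#' @param reference numeric vector of reference-instrument Ct values.
#' @param algorithm numeric vector of this package's Ct values (same
#'   length, >= 3 pairs, both with nonzero variance).
#' @return list with `r`, `p` and `n`.
#' @export
pearson_validate <- function(reference, algorithm) {
  x <- as.numeric(reference)
  y <- as.numeric(algorithm)
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (!all(is.finite(c(x, y)))) stop("Ct values must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one of the columns", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Published Ct comparison pairs
#'
#' The eight HBV dilution-series samples measured both on a commercial
#' real-time instrument (reference) and by this package's fitting algorithm,
#' as printed in the platform's validation table; used for the Pearson
#' agreement check.
#'
#' @return data.frame with `sample`, `reference_ct`, `algorithm_ct`.
#' @export
ct_reference_pairs <- function() {
  data.frame(
    sample = LETTERS[1:8],
    reference_ct = c(35.99, 30.12, 25.07, 34.97, 32.41, 35.21, 34.59, 35.92),
    algorithm_ct = c(35.70, 29.71, 24.52, 34.53, 31.61, 34.50, 33.96, 35.25)
  )
}

#' Read a multi-well cycle-by-well CSV
#'
#' Layout: header `cycle,<well1>,<well2>,...`, one row per cycle; the cycle
#' column must run 1..n.
#'
#' @param path CSV file path.
#' @return list of [fluorescence_curve()] objects, one per well column.
#' @export
read_wells_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "cycle")
    stop("parse error: expected header 'cycle,<well>,...'", call. = FALSE)
  lapply(names(df)[-1], function(w)
    fluorescence_curve(df[[w]], df$cycle, well_id = w))
}

#' Render a run report to JSON or HTML
#'
#' JSON is a lossless serialization of the report (round-trips through
#' [parse_report()]); HTML is a human-readable per-well table with Ct values
#' formatted to two decimals and an inline SVG sparkline of each trace when
#' the raw curves are supplied.
#'
#' @param report a `run_report` from [analyze_run()].
#' @param path output file path.
#' @param format `"json"` or `"html"`.
#' @param curves optional list of the raw [fluorescence_curve()]s (HTML
#'   plots only).
#' @return the path, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "html"),
                          curves = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(report, "run_report"))
  if (format == "json") {
    payload <- list(
      metadata = report$metadata,
      counts = as.list(report$counts),
      results = lapply(report$results, function(r)
        list(well_id = r$well_id, label = r$label, group = r$group,
             ct = r$ct, cause = r$cause, status = r$status))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    rows <- vapply(report$results, function(r) {
      ct_txt <- if (!is.na(r$ct)) sprintf("%.2f", round_ct(r$ct)) else ""
      cause_txt <- if (!is.na(r$cause)) r$cause else ""
      sprintf("<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              r$well_id, r$label, r$group, ct_txt, cause_txt, r$status)
    }, "")
    spark <- ""
    if (!is.null(curves)) {
      spark <- paste(vapply(curves, function(cu) {
        y <- cu$rfu
        ymax <- max(y, 1e-12)
        pts <- paste(sprintf("%.1f,%.1f", 4 * seq_along(y),
                             40 - 36 * y / ymax), collapse = " ")
        sprintf("<div><b>%s</b> <svg width='%d' height='44'><polyline points='%s' fill='none' stroke='black'/></svg></div>",
                if (!is.null(cu$well_id)) cu$well_id else "", 4 * length(y) + 8, pts)
      }, ""), collapse = "\n")
    }
    html <- paste0(
      "<!DOCTYPE html><html><head><meta charset='utf-8'><title>qPCR run report</title></head><body>",
      "<h1>qPCR run report</h1>",
      sprintf("<p>wells: %d | positive: %d | negative: %d | abnormal: %d</p>",
              length(report$results), report$counts["positive"],
              report$counts["negative"], report$counts["abnormal"]),
      "<table border='1'><tr><th>well</th><th>class</th><th>group</th>",
      "<th>Ct</th><th>cause</th><th>status</th></tr>",
      paste(rows, collapse = "\n"),
      "</table>", spark, "</body></html>")
    writeLines(html, path)
  }
  invisible(path)
}

#' @rdname render_report
#' @export
parse_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  null_na <- function(v, as_num = FALSE) {
    if (is.null(v)) { if (as_num) NA_real_ else NA_character_ }
    else if (as_num) as.numeric(v) else as.character(v)
  }
  results <- lapply(payload$results, function(r)
    structure(list(well_id = null_na(r$well_id),
                   label = null_na(r$label),
                   group = null_na(r$group),
                   ct = null_na(r$ct, as_num = TRUE),
                   cause = null_na(r$cause),
                   status = null_na(r$status)),
              class = "curve_call"))
  counts <- vapply(payload$counts, as.integer, 0L)
  structure(list(results = results,
                 counts = counts[c("positive", "negative", "abnormal")],
                 metadata = payload$metadata),
            class = "run_report")
}
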