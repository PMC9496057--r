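# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small (180-curve) corpus: fast stand-in for the default 600-curve one
small_corpus <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_dataset(sim_config(per_class_n = 30, seed = 7))
  }
  .fixtures$small
}

# SVC + normalizer trained on the small corpus (fixed hyperparameters)
trained_small <- function() {
  if (is.null(.fixtures$model)) {
    ds <- small_corpus()
    norm <- normalize_fit(ds)
    model <- train_final("svc", list(C = 1, kernel = "linear", gamma = NA),
                         normalize_apply(norm, ds$rfu), ds$label)
    .fixtures$model <- list(model = model, normalizer = norm)
  }
  .fixtures$model
}

# noiseless single-curve fixtures with pinned generator parameters
noiseless_curve <- function(label, rng_state = 1L, params = list()) {
  simulate_curve(label, sim_config(noise_sd = 0), rng_state, params = params)
}

# independent macro-metric oracle: explicit per-class tallies from labels
macro_metrics_oracle <- function(truth, pred, levels) {
  per <- lapply(levels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(precision = mean(per[, "prec"]), recall = mean(per[, "rec"]),
       f1 = mean(per[, "f1"]), accuracy = mean(truth == pred))
}

# dense-grid oracle for the second-derivative maximum (step 1e-3 cycles)
sdm_grid_oracle <- function(params, lo = 1, hi = 40, step = 1e-3) {
  g <- seq(lo, hi, by = step)
  g[which.max(fivepl_d2(params, g))]
}

# wrap known 5PL parameters as a converged fit object for ct_from_fit()
as_fit <- function(params, n_cycles = 40) {
  structure(list(params = params, residual_norm = 0, iterations = 0L,
                 converged = TRUE, damping_used = FALSE,
                 n_cycles = n_cycles),
            class = "fivepl_fit")
}
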