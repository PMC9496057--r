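---
title: "Amplification-curve classification and Ct calling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplification-curve classification and Ct calling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrcall)
```

## The problem

A point-of-care qPCR instrument reads one fluorescence value per well at the
end of each thermal cycle, typically over 40 cycles. Interpreting a run means
answering three questions per well: is the curve a genuine amplification
(positive), a flat negative, or an artefact; if positive, at which fractional
cycle (Ct) did amplification become detectable; and if it is an artefact,
what likely went wrong at the bench. `pcrcall` implements that analysis core:
a six-class curve classifier, a five-parameter-logistic (5PL) fitter with a
second-derivative-maximum (SDM) Ct, and a cause lookup for the abnormal
classes, plus the harnesses used to select and validate the classifier.

The six morphology classes and their verdicts:

| class | shape | verdict | downstream action |
|---|---|---|---|
| A | sigmoid, plateau reached | positive | Ct calculation |
| B | late-onset sigmoid, plateau not reached | positive | Ct calculation |
| C | flat line | negative | none |
| D | baseline with an end-of-run jump | abnormal | cause warning |
| E | rises then declines ("hook") | abnormal | cause warning |
| F | upward drift line | abnormal | cause warning |

## The synthetic corpus: what it emulates and what it does not

Real labelled amplification curves are scarce, so the training corpus is
simulated: 100 curves per class, 600 in total, each a 40-cycle trace on a
normalized full scale of 1 fluorescence unit. Each class is the simplest
parametric family matching its morphology:

* **A/B** — the same 5PL sigmoid used by the fitter, with midpoint
  `x0 ~ U(18, 32)` for A and `x0 ~ U(30, 38)` for B, slope scale
  `k ~ U(0.8, 1.8)` cycles and asymmetry `s ~ U(0.7, 1.4)`. Class B's
  defining property — the plateau is not reached by the final cycle — is
  enforced by resampling `(x0, k, s)` within those ranges until the amplified
  fraction at cycle 40 is at most 0.9. Without that constraint a B curve with
  an early `x0` and small `k` is indistinguishable from an A curve, which
  contradicts the class definitions.
* **C** — constant baseline.
* **D** — baseline plus a step of 10–30% of full scale in the last 1–3
  cycles.
* **E** — a sigmoid whose amplified part is multiplied by a linear decay
  beyond its peak (decay rate 0.015–0.035 per cycle starting 4–8 cycles
  after the midpoint), giving exactly one interior maximum.
* **F** — a linear ramp across all cycles.

Baselines are `U(0.02, 0.10)` and amplitudes `U(0.6, 1.0)` of full scale, so
classes overlap in level but not in shape. Noise is i.i.d. additive Gaussian
(sd 0.01 of full scale, clipped at 0) — real instruments show smooth traces
with small jitter of about this size. One root seed drives everything;
per-curve substreams are derived by counter, so enlarging the corpus never
reshuffles existing curves, and identical configurations serialize to
identical bytes.

What the generator does **not** model: optics and thermal physics, melting
curves, baseline drift correction, multi-channel crosstalk, or the empirical
distribution of real artefacts. A green classifier test therefore
establishes that the pipeline separates these *stated* morphologies at the
stated noise level — not that it would reach the same accuracy on clinical
data. This is the same caveat the original platform carries: its classifier
was likewise trained on simulated curves.

## Normalization and the 2-D projection

Features (per-cycle readings) are brought to a common scale by per-feature
z-scoring fitted on the training split only; zero-variance features keep
scale 1 so they map to 0. Min–max scaling would also satisfy the
"same order of magnitude" requirement; z-scoring was chosen because the
downstream models are distance- and kernel-based, and is recorded here as
the package's documented choice.

`pca_project()` gives the 2-D principal-component view used to eyeball class
separation (component signs fixed so the largest-magnitude loading is
positive, making plots reproducible). Two caveats discovered while
quantifying "good discrimination": pairs that differ across many cycles
(sigmoid vs flat, late-onset vs hook, ...) separate by more than 4 times the
mean within-class scatter, but pairs that differ only locally do not —
classes C and D differ in at most 3 of 40 coordinates, which the top two
variance directions barely see, so their centroids nearly coincide in 2-D
even though the full 40-dimensional features (what the classifier consumes)
separate them cleanly. The separation property test therefore asserts the
4-fold ratio for the nine morphologically global contrasts only.

## Classifier selection

Five families are compared — SVC, ridge multinomial logistic regression
(LRC), k-nearest neighbours, a CART decision tree, and LDA — on a stratified
7:3 split with exhaustive grid search scored by stratified 5-fold
cross-validated accuracy; ties go to the earlier grid point. The SVC grid is
C ∈ {0.1, 0.5, 1, 10} × kernel ∈ {RBF, linear} × γ ∈ {0.1, 0.5, 1, "scale"},
which contains the original platform's published optimum (C = 0.5, RBF,
γ = 1). Because no SVM, CART or kNN implementation is available in the
target environment, the SVC is implemented in-package (an SMO dual solver
with maximal-violating-pair working-set selection, one-vs-one multiclass;
verified during development against an independent reference implementation
and continuously against its own KKT conditions), and kNN/CART are small
deterministic R implementations. LRC maps the conventional `C`
regularization to glmnet's ridge `lambda = 1/(nC)`.

On the regenerated corpus the grid-searched SVC reaches held-out accuracy
≈ 1.0 (the original platform reports 0.99 on its own simulated corpus), and
the family ranking puts SVC at the top. Two honest differences from the
original report, both consequences of the corpus being a re-simulation
rather than that platform's data: the selected grid point is typically a
linear-kernel SVC
rather than C = 0.5/RBF/γ = 1 (several grid points are statistically tied
near-perfect), and before the class-B plateau constraint is enforced the
A/B boundary produces exactly the published failure mode — a few A curves
predicted as B — at accuracy ≈ 0.97.

Metrics are macro-averaged precision/recall/F1 plus accuracy (the corpus is
balanced, so macro ≈ micro), with the confusion matrix in the
rows-are-truth convention; accuracy is identically its trace over its total.
Whether the published scores are CV or held-out-test scores is ambiguous in
the source; this package reports held-out-test metrics.

## 5PL fitting and the SDM Ct

Positive curves are fitted to

$$F(x) = F_b + \frac{F_{max} - F_b}{\left(1 + e^{-(x - x_0)/k}\right)^s}$$

by Gauss–Newton iteration on the analytic Jacobian. The parameterization
(baseline, plateau, midpoint location, cycle-scale slope, dimensionless
asymmetry) is the package's documented choice; the source names only the
model family. Initialization: baseline from cycles 1–5, plateau from the
trace maximum, `x0` from the interpolated half-height crossing, `k = s = 1`.
Undamped Gauss–Newton steps are attempted first (the named method);
Levenberg-style diagonal damping engages only when a step fails or increases
the SSR, so accepted iterations never increase the SSR. Convergence: step
infinity-norm or relative SSR change below `1e-8`, capped at 200 iterations;
`k, s` are kept positive by projection. A trace whose dynamic range is below
`min_range` (default 0.05 in normalized units — raise for raw instrument
counts) is rejected as not amplifying before fitting.

Ct is the abscissa of the maximum of the fitted curve's second derivative,
located by a 0.01-cycle grid over the measured domain and polished by Newton
steps on the (finite-differenced) third derivative. The search is
deliberately confined to the measured cycles: a maximum on the domain
boundary means no interior inflection exists and yields a
"positive-but-uncallable" status rather than an extrapolated Ct. In the
symmetric limit `s = 1` the position is known in closed form,
`x0 − k·log(2 + √3)` ≈ `x0 − 1.317k`, which anchors the numeric tests; the
SDM Ct is invariant to affine rescaling of the fluorescence axis since
`F_b`/`F_max` absorb it. Reported Cts are rounded to two decimals, half-up,
at the reporting layer only.

Degenerate late curves (class B, plateau unreached) are fitted as-is: the
fit is accepted if it converges and the second-derivative maximum is
interior; otherwise the well is positive-but-uncallable.

## Pipeline, causes, risk levels, validation

`analyze_run()` applies normalize → classify → branch per well, strictly by
predicted class with no secondary heuristic, and captures any per-well
failure in that well's status so one bad well never aborts a run. Abnormal
classes map to fixed cause strings (D: suspected template cross-contamination
or low sample concentration; E: severe evaporation or probe degradation; F:
slight evaporation). `risk_level()` bins an instrument's positive count into
four levels (1 + number of thresholds strictly exceeded); the 10/50/100
defaults are configuration, chosen as round clinic-scale counts since the
source gives no numbers. `pearson_validate()` computes the product-moment
correlation and its two-sided t-transform p-value for paired reference vs
algorithm Cts; recomputing it from the eight published comparison pairs
(`ct_reference_pairs()`) gives r = 0.9990, p = 2.7e-9, consistent with the
printed r = 0.99 read as truncated; the p-value is reported but never used
as a gate.

## Numerical conventions and limitations

* Tie-breaks are deterministic everywhere: grid order in grid search, first
  maximum in kNN/one-vs-one voting, earlier feature/lower threshold in CART.
* All randomness flows from explicit integer seeds; end-to-end reruns are
  byte-identical.
* The raw instrument export used for the original cross-instrument check is
  not redistributable; the corresponding test runs the same ingestion and
  fitting path on synthetic wells constructed to have known SDM Cts (and is
  labelled synthetic). Equality with the published sample-A value on the
  true export is therefore not established here.
* No baseline-drift correction or absolute quantification (standard curves)
  is attempted; both are out of scope for this analysis core.
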