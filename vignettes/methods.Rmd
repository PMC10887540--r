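---
title: "Models and methods behind cheesemlp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cheesemlp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheesemlp)
```

# The modeling problem

Herb-fortified kombucha fresh cheese is characterized by sixteen quality
responses measured over cold storage: five compositional percentages (dry
matter, fat, ash, proteins in dry matter, total proteins), water activity
and pH, four antioxidant-capacity assays (total phenols in mg GAE/g; DPPH,
ABTS and FRAP in µM Trolox equivalents/g), and five microbial counts in
log CFU/g. The experimental design is a 2 × 3 × 4 factorial: herb (sage or
wild thyme) × sample type (unfortified control KC, ground herb KG,
supercritical-fluid extract KSFE) × storage day (0, 10, 20, 30).

The package models all sixteen responses jointly with a single-hidden-layer
perceptron

$$y = f_1\!\left(W_2\, f_2(W_1^{\top} x + B_1) + B_2\right),$$

where $x$ is the 6-vector `[day, herb_salvia, herb_thyme, sample_KC,
sample_KG, sample_KSFE]`, $f_2$ is the hidden activation (tanh by default)
and $f_1$ the output activation (logistic by default). Both herb dummies
and all three sample dummies are kept — no reference level is dropped —
because the published trained network has six inputs in exactly this order;
the resulting collinearity is accepted, and its main consequence (the
herb/sample attribution ambiguity discussed below) is documented rather
than hidden.

## Activation assignment

The published architecture summary labels the activations "hidden: tanh,
output: logistic", and the bundled fixture follows that: $f_2 = \tanh$,
$f_1 = \text{logistic}$. The `exponential` tag implements the negative
exponential unit $e^{-v}$ of classical MLP toolkits; `identity` turns the
network into a plain affine map, which the tests use as a closed-form
limit.

# Training

`mlp_train()` minimizes the summed squared error
$\mathrm{SOS} = \sum_i \lVert y_i - \hat y_i\rVert^2$ with BFGS
(`stats::optim`) and analytic back-propagated gradients. Weights are
initialized uniformly in $[-0.5, 0.5]$ from a caller-supplied seed, making
every run reproducible; the default budget is 1,000 iterations with a
relative tolerance of $10^{-8}$. Because a logistic output cannot attain 0
or 1, regression targets are min-max scaled into $[0.05, 0.95]$ by default
(`fit_standardizer(..., "minmax")`); targets outside the attainable range
are rejected before optimization starts. Inputs enter the encoder
unscaled; z-scoring the day column is a separate, invertible step so that
the published fixture (whose original scaling convention is unknown) and
newly trained networks can use different conventions.

`architecture_search()` scans hidden-layer sizes (default 5–10) and
activation pairs with a configurable number of seeded random restarts, and
selects by mean validation r² (ties: smaller hidden layer, then lower test
SSE) on a fixed 70/15/15 train/test/validation split. The original study
screened on the order of 10⁵ random configurations; the package defaults
to desk-scale restart budgets (2–20) because, on the smooth synthetic
surfaces below, the search saturates validation r² ≥ 0.95 already with two
restarts per candidate.

Training on data generated by a known network recovers the *function* to
numerical precision (SOS below 10⁻⁶ on 200 noiseless points from a 6-4-3
generator, maximum prediction error below 10⁻³); the *weights* themselves
are not identifiable (hidden units can be permuted and sign-flipped), so
tests assert function recovery, never weight recovery.

# Yoon's connection-weight sensitivity

For input $i$ and output $j$, with hidden index $k$:

$$RI_{ij} = 100 \cdot
  \frac{\sum_k w_{ik} w_{kj}}{\sum_{i'} \left|\sum_k w_{i'k} w_{kj}\right|}\ \%$$

Biases are excluded: only input–hidden–output connection chains carry
attributable signal. Under this normalization each output's absolute
importances sum to exactly 100 % and each value keeps the sign of its
weight-product sum. A literal variant that divides by the *signed* sum is
available (`denominator = "signed"`) for comparison; its values sum to
+100 % per output but individual magnitudes are unbounded, which makes it
unsuitable for reporting.

Applied to the bundled published network, this computation reproduces the
published relative-importance percentages — e.g. day→dry matter +64.98 %,
day→FRAP −64.46 %, sage→water activity +18.78 % — to within 0.01
percentage points for eleven of the twelve headline pairs;
`reproduce_published_sensitivity()` performs the comparison. The twelfth
(day→aerobic mesophilic count) recomputes to −65.98 % against a reported
−66.98 %: a constant 1.00-point discrepancy that no variant of the formula
(bias-inclusive, signed denominator) removes, while the same transcription
matches every other reported pair — consistent with a single-digit
transcription slip in the reported figure. The package reports the
computed value.

Two caveats a user should know:

* **Attribution, not causation, and only in the non-saturated regime.**
  Connection-weight products approximate sensitivities when the hidden
  units operate near their linear range. Long unregularized training drives
  tanh units into saturation, where the products can cancel and misattribute
  even a perfectly fitted effect; the package's tests show clean recovery
  with early stopping (≈50 BFGS iterations on the synthetic study) and
  degradation beyond a few hundred. The published workflow likewise stopped
  training early.
* **Dummy-variable ambiguity.** Because `herb_salvia + herb_thyme = 1`, an
  effect of sage is representable as an opposite effect of thyme plus a
  bias shift. The identifiable quantity is the herb *contrast*
  $RI_{\text{salvia}} - RI_{\text{thyme}}$ (similarly for sample types);
  individual dummy attributions should be read with that in mind.

# Goodness-of-fit suite

For observed $x_{\exp}$ and predicted $x_{\text{pre}}$ over $N$
observations with $n$ model parameters:
$\mathrm{SSE} = \sum (x_{\exp} - x_{\text{pre}})^2$;
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/N}$;
$\chi^2 = \mathrm{SSE}/(N - n)$;
$\mathrm{MBE} = \tfrac1N \sum (x_{\text{pre}} - x_{\exp})$;
$\mathrm{MPE} = \tfrac{100}{N} \sum (x_{\text{pre}} - x_{\exp})/x_{\exp}$
(signed); AARD is MPE's absolute-value counterpart; and
$r^2 = 1 - \mathrm{SSE}/\mathrm{SST}$. AARD and $r^2$ are implemented with
their conventional definitions (the reporting layout they appear in does
not define them). MPE and AARD are undefined when an observation is exactly
zero; that metric is reported as `NA` and the others still computed.

On the parameter count $n$: `fit_metrics()` accepts any $0 \le n < N$, and
`n_parameters()` gives a network's free-parameter count, but
`run_pipeline()` passes $n = 0$ by default. A 6-10-16 network has 246 free
parameters against 24 design cells, so $\mathrm{SSE}/(N-n)$ with the full
parameter count is undefined at the study's own scale; $n = 0$ (the plain
mean squared error) is the only default that is always well defined, and
callers with enough data can override it.

# Chemometrics

Correlations are Pearson $r$ with two-sided p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$; no multiplicity correction is applied, since
the convention in this literature is to report raw $p \le 0.05$. PCA is
performed on the correlation matrix by default (the responses carry
incommensurate units). Per-variable **signed contributions** to each
component are reported as
$\text{sign}(\ell_{vc}) \cdot 100\,\ell_{vc}^2 / \sum_v \ell_{vc}^2$, so
absolute contributions sum to 100 % per component while the sign records
the direction of influence — the form in which such results are narrated in
this field. Clustering defaults to complete-linkage on Euclidean distances
over standardized responses (the original report names neither choice; both
are configurable), with merge-list JSON and Newick export.

# Multi-objective optimization

The design space is tiny — 2 herbs × 3 sample types × a day grid (default
step 1 day, 186 candidates) — so the reference method is **exhaustive
enumeration**: evaluate the network at every candidate, orient each
configured objective to "maximize" (minimized responses are negated;
`target` responses score $-|y - y^\ast|$), and filter to the exact
non-dominated set. The **genetic algorithm** (default population 100,
generation cap 500, tournament selection on dominance count, uniform
crossover, 15 % per-gene mutation, early exit after 25 generations without
archive change) exists for the continuous-day extension and for
methodological comparison; it maintains an archive of all evaluated
candidates pruned to its non-dominated subset, and requires an explicit
seed. On the default grid its front provably cannot contain a point
dominated by the exhaustive front, and the tests check exactly that, plus
argmax agreement in the single-objective case.

Default directions maximize the antioxidant responses and lactic acid
bacteria and minimize the four undesirable counts and water activity;
compositional responses are ignored unless the user supplies targets. The
original optimization ran over all sixteen responses simultaneously but
does not state its direction vector, so every choice here is explicit and
overridable. For the bundled published network, optimization operates on
model scale (logistic units): the output standardization used to train it
was never published, so its predictions cannot be mapped to physical units,
and the published optimal-sample values are treated as qualitative context
only. For networks trained in-package the fitted standardizers are passed
in and candidates are scored in physical units.

# Synthetic study generator

`synthetic_config()` defines an additive ground truth per response —
baseline + slope·day + quad·day² + herb offset + sample offset — plus
Gaussian replicate noise, over the full factorial grid. The default table
mirrors the qualitative storage-trend structure of fortified fresh cheese:
storage day the dominant driver (positive for dry matter, total phenols,
ABTS; negative for fat, pH, DPPH, FRAP and all microbial counts), sage
depressing dry matter/fat/proteins and raising ash and water activity,
thyme mirrored, extract fortification strongest on the
antioxidant/antimicrobial side. Magnitudes are the package's own choices of
realistic assay scales (e.g. dry matter ~50 % rising 0.15 %/day, water
activity ~0.95 falling 6·10⁻⁴/day, counts falling 0.035–0.06 log CFU/g per
day) with noise of roughly 2–5 % of each response's design range;
replicates default to 1 and the tests use 5–20.

What the generator deliberately does **not** emulate: interactions between
factors (the truth is purely additive), non-Gaussian or
heteroscedastic assay error, autocorrelation across storage days of the
same batch, and detection limits in the microbial counts (values are merely
clipped at 0, and water activity at 1). Passing tests therefore demonstrate
that the pipeline recovers the structure it assumes — monotone trends,
additive offsets, dominant-input signs — not that the published study's
specific numbers would be recovered from its unpublished raw data.

# Numerical choices and degenerate inputs

* Standardizers reject constant columns by name; inverse transforms restore
  originals to ≤ 10⁻¹⁰ relative error (asserted in tests).
* The 70/15/15 split takes the floor of the test and validation shares and
  gives the remainder to training (24 cells → 18/3/3); splits are seeded
  and serializable.
* Sensitivity errors out, naming the output, if an output's weight-product
  denominator is exactly zero (a dead output row).
* PCA drops constant columns with a warning before correlation-based
  decomposition; rank deficiency simply yields trailing zero eigenvalues.
* Dominance ties: a candidate equal to another on every objective is not
  dominated; duplicated optimal candidates are all retained.
* Non-finite training loss aborts with the evaluation index; targets
  outside the output activation's attainable range are rejected before
  optimization.

# Problem sizes used by the test suite

The suite trains networks on the synthetic study at 24 cells × 5–10
replicates (120–240 rows), runs the architecture search over H ∈ [5, 10]
with 2 restarts, checks the metric suite against an independent scalar
implementation on 1,000 random vector pairs, and exercises both optimizers
on the 186-candidate grid with a GA population of 100 and a 60–100
generation cap. These sizes were chosen so the full suite documents the
methods at interactive timescales; all of them are parameters, not limits.

# Known limitations

* The bundled fixture's input/output standardization is unknown, so its
  forward predictions live on model scale; only sensitivity analysis (scale
  invariant) and qualitative optimization are meaningful for it.
* Yoon attribution inherits the caveats above (saturation, dummy
  collinearity); Garson's algorithm and permutation importance are not
  implemented.
* The GA is a compact seeded implementation aimed at discrete/continuous
  day domains of this design space, not a general NSGA-II replacement: no
  crowding-distance selection, no constraint handling beyond the box/category
  domain.
* One published relative-importance value (day→aerobic count) differs from
  the recomputation by 1.00 percentage point, as discussed above.
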