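---
title: "Data-derived fuzzy-logic modeling of signaling plasticity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-derived fuzzy-logic modeling of signaling plasticity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzlink)
```

## The problem

Signaling networks assembled from the literature assume a fixed wiring, but
tumor cells rearrange their signaling — to acquire drug resistance, or because
the reported interactions were never active in that cell line to begin with.
Given multi-day time courses of phosphorylated and total protein levels under
several kinase-inhibitor treatments, fuzzlink fits a small data-derived model
to every node of a prior-knowledge network, simulates the network, and asks
*when* each model stops explaining its node: a model that fails from the
earliest training window on points at a statically wrong topology, while a
model that explains early data but fails once late time points are included
flags a candidate time-defined rearrangement.

## The node model (gFIS)

Each non-input node is modeled as a static map from its regulators' scaled
phospho-signals to its own. The map is a first-order Takagi–Sugeno fuzzy
inference system reduced to two rules:

* every input has two Gaussian fuzzy sets, *low* (center 0) and *high*
  (center 1), both with width 0.4247 — the conventional default for
  [0, 1]-scaled inputs; membership is `exp(-(x - c)^2 / (2 * w^2))`;
* rule 1 combines the low sets of all inputs, rule 2 the high sets
  (the product t-norm joins multi-input premises; the single-input form
  generalizes smoothly and the product keeps the map differentiable);
* each rule carries a free linear consequent `f_r(x) = sum_j p_rj x_j + q_r`;
  the output is the firing-strength-weighted mean of the two consequents.

Consequent coefficients may be negative, so inhibition is representable with
the same structure. The parameter accounting behind this reduction (per
`parameter_budget()`): a full grid partition of a two-input model needs 4
rules and 20 parameters; restricting rules to analogous set combinations
leaves 2 rules and 14 parameters; fixing the premises leaves the
`2 * (n_inputs + 1)` consequent parameters — 6 for two inputs, 4 for one —
below the 7–9 time points available per condition.

Inputs are deliberately **not** clipped to [0, 1] at evaluation time:
memberships are defined on the whole real line and simulated upstream signals
may transiently leave the unit interval; the training penalty (below)
discourages this.

## Preprocessing

`preprocess_dataset()` divides each phospho measurement by the matched total
measurement (protein loss over multi-day courses otherwise masquerades as
de-phosphorylation) and then scales every (analyte, condition) series by its
own maximum. Scaling is per analyte, not pooled across analytes within a
condition: pooled scaling would let the brightest analyte dominate every
fit. All-zero series pass through with a warning; a zero total is an error
naming the offending record. Missing time points are dropped, not imputed —
the models are static maps, so irregular sampling is harmless.

## Training

`fit_gfis()` minimizes RMSE over the training rows **plus** an
interpolation penalty: the model is evaluated on `n_interp = 20` equidistant
points per input axis spanning the observed input range (full Cartesian grid
for multi-input models, normalized by the number of grid points), and every
value above 1 or below 0 contributes its squared offset; the penalty is the
root mean square of those offsets. Without it, fits can be exact at the data
points yet wild between them, which wrecks downstream propagation.

The optimizer is multi-start Nelder–Mead. The first restart is a
deterministic warm start — the closed-form least-squares consequents under
the default premises (for the free-premise setups of the sensitivity
analysis, premises start at their defaults). The warm start matters:
without it, the free-premise setups systematically under-adapt (a
local-optimum artifact), which would understate their flexibility relative
to the convex fixed-premise fit. The remaining restarts draw all parameters
uniformly from [-2, 2] (premise centers/widths from ranges around their
defaults); restart `i` uses seed `seed + i - 1`, so fits are bit-reproducible
and the best objective is monotone in the number of restarts. Defaults:
20 restarts; the per-module studies use 5–6 because the fixed-premise
objective is convex in the consequents (the restarts only guard the penalty
term).

Because several parameter vectors can encode nearly the same map, all
recovery claims in the test suite are about predicted outputs, never about
parameter equality.

`bootstrap_sensitivity()` pins the penalty grid to the *original* data's
input range (`grid_range`): a duplicate-heavy resample spans a narrower input
range, and without the pin the consequents can blow up and extrapolate wildly
at the original data points.

## Multi-treatment models and network simulation

`assemble_mtfis()` stacks the per-condition consequent pairs of a node behind
the shared fixed premise — `2 x n_conditions` rules, no new parameters. The
naive condition switch is implemented as an exact 0/1 indicator that selects
the active condition's block (semantically identical to Boolean-shaped
trapezoidal switch membership functions, but numerically exact), so
evaluation under a condition reproduces the source per-condition model to
machine precision. Only single-treatment evaluations are supported.

`simulate_network()` propagates synchronously: at each observed time point,
input nodes (in-degree 0) take their measured value and every other node is
evaluated in topological order on its parents' *simulated* values. There is
no state between time points. Parent order is lexicographic and recorded, so
coefficients are unambiguous across runs. Cyclic topologies are rejected;
unmeasured topology nodes are excluded with a warning.

Node errors are computed against the model's own training window: evaluating
a 48 h model on 96 h data would conflate the two error components
(training-window misfit vs extrapolation) that the error-evolution analysis
is designed to separate.

## Error evolution and classification

`evolve_network()` retrains and simulates on nested windows (default 48, 72,
96 h). `classify_nodes()` labels each (node, condition) from the earliest-
and latest-window RMSE against a threshold of 0.2 — the error level below
which fits visibly track these data. Errors exactly at the threshold count as
high (below the threshold is the accurate regime). Intermediate windows are
reported but do not drive the label; the window-count normalization inside
the RMSE is the plain per-window point count, a deliberately simple choice —
comparing models trained to different numbers of points has no rigorous
normalization here, and this is a known limitation.

## Synthetic data

The experimental MFI data the method was developed on are not distributable,
so `generate_scaled()` emulates their structure: 10 analytes on the
0–96 h, 9-point grid under 4 conditions, input-node trajectories as smooth
trend-plus-sinusoid curves in [0, 1], downstream nodes generated from known
gFIS ground truths in topological order, additive Gaussian measurement noise
(default sigma 0.02) truncated to [0, 1], and a final per-series max-scaling
(the same last step as the preprocessing pipeline, so generated data satisfy
the scaled-data contract and `generate_raw()` round-trips through
`preprocess_dataset()` exactly). Ground-truth consequents are rescaled during
construction so every noiseless series peaks at exactly 1 while remaining
exactly generated by the recorded models.

Two generator choices deserve emphasis:

* **Input trajectories complete at least one full oscillation** over the
  window (frequency 1.2–2.2 cycles, mild trend). This is an identifiability
  requirement, not a cosmetic one: late-time rearrangements are only
  detectable if late-time input values revisit the input range explored
  early, otherwise the fitted map can bend freely in the unvisited region
  and absorb the event.
* **Noise draws and scale factors are event-independent** (stage-specific
  seeds; with an event, scale factors come from the matching no-event
  baseline), so the pre-switch portion of an event dataset matches the
  no-event dataset point for point.

What the generator does **not** emulate: bead-count artifacts, inter-plate
effects, heteroscedastic MFI noise, feedback loops (the topology is acyclic
by assumption), and biological variation between replicates. Passing tests
on these data show the pipeline recovers what it assumes; they do not certify
performance on real Luminex data.

## Rearrangement detection: power

With 9 time points and a switch at 48 h, only two points (72, 96 h) carry the
signal. If the displacement of those points is `d`, a fit that splits each
conflict in half reaches RMSE about `d / 3`, so the fixed 0.2 threshold needs
`d` around 0.6 — a displacement of 0.3, for instance, is undetectable under
these conditions. The `invert` event type therefore generates the
strongest-contrast rearrangement: the post-switch generating model is a gFIS
with identical affine consequents fitted to the opposite-extreme targets,
displacing every post-switch point by at least 0.5. The detection study
(`study_rearrangement_detection()`) uses a compact 4-node topology, two
conditions with the event in the treated condition only (mirroring
drug-specific rearrangements), noise sigma 0.02, and 50 replicates — sizes
chosen to exercise the full train/simulate/classify loop per replicate.

Static mis-wiring is harder. For generic smooth series on a 9-point grid the
two-rule family almost always *absorbs* an unrelated regulator: any two
smooth time courses trace a near-functional scatter at this sampling density,
and 4 free parameters suffice to track it below 0.2. (This also matches the
observation that on real, rougher data static mismatches only just exceed
the threshold.) `study_static_miswiring()` therefore demonstrates the one
geometry in which mis-wiring is identifiable from smooth series: a Lissajous
pair — two oscillations with a 1:2 frequency ratio — where neither series is
a function of the other. The mis-wired node then shows RMSE well above 0.2 at
every window and is labeled `static_mismatch`.

## Validation studies

* `study_parameter_recovery()`: noiseless datasets from the bundled MAPK
  topology; a fit of a single-regulator node must reach training RMSE below
  1e-3. 100 replicates.
* `study_loo_selfconsistency()`: leave-one-out cross-validation on noiseless
  node data; held-out predictions should correlate near-perfectly with the
  reference model's.
* `study_bootstrap_flexibility()`: 100 row-wise resamples (pairs drawn
  jointly, with replacement, original size) per model setup on a noisy
  single-regulator fixture; noise sigma 0.05 was chosen as representative of
  bead-assay replicate variability on scaled values. The per-point standard
  deviation of the bootstrapped simulations, averaged over points
  (`mean_sigma`), measures flexibility. Expected picture: the
  constant-consequent setup is the least flexible, and the fixed-premise and
  free-premise linear setups are comparable (the package's acceptance test
  reads "comparable" as within 25% of the larger) — fixing the premises
  costs little flexibility because the consequents carry most of the
  information. All three setups are fitted with the same warm-started
  multi-start Nelder–Mead optimizer, so the comparison reflects the model
  families, not optimizer identity.

## Numerical and degenerate-input choices

* Objective ties across restarts: the lowest restart index wins.
* Free-premise widths pass through `abs()` with a floor of 1e-3 during
  optimization, keeping every visited parameter vector a valid model.
* All-zero series scale to themselves (with a warning); constant inputs
  produce a degenerate one-point interpolation grid, which is handled.
* `Inf` as a training window means "all time points" and serializes as
  `null` in model bundles; bundles store doubles at 17 significant digits,
  so a reloaded network simulates bit-identically.
* Topology files are two-column TSV (`regulator<TAB>target`); interaction
  sign is not encoded because the consequents learn it.

## Known limitations

* Static maps per time point: no state is carried between time points, so
  transient-vs-sustained dynamics are out of reach by construction.
* Acyclic topologies only; feedback requires a different update scheme.
* Detection power at 9 points is modest (see above); the 0.2 threshold is a
  calibrated constant of the workflow, not an estimated quantity.
* Static-mismatch detection on smooth, low-noise series depends on the
  geometry of the involved trajectories; absorption by the flexible
  consequents is the norm, not the exception.
* Combination treatments (multiple drugs active at once) are rejected; the
  condition switch assumes exactly one active condition.
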