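---
title: "Population coding of actual and observed touch: models and methods"
author: "popcongruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding of actual and observed touch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcongruence)
```

## The scientific problem

Neurons in high-level sensory cortex respond both when a touch is felt and
when the same touch is merely observed on another person. The classical
"mirror neuron" reading is that single cells carry matched (congruent)
responses for self and other. The alternative, population-level reading is
that single neurons are heterogeneous and idiosyncratic, while the
*population* encodes basic-level tactile variables — which body part was
touched, and how — in latent subspaces that are reused (generalize) across
contexts such as actual versus observed touch.

This package implements the full analysis chain needed to adjudicate
between these readings on trial-aligned spike-count data from a factorial
touch paradigm:

* **Design.** Two tasks: a basic task crossing person (actual/observed)
  with body part (cheek/shoulder), touch fixed to rubs — 4 conditions; and
  a multidimensional task adding four touch types (pinch, press, rub, tap)
  — a 2 x 2 x 4 factorial, 16 conditions. A *sensory field* (format) is a
  person x body-part context: Ac, As, Oc, Os. Ten trials per condition per
  session; stimulation lasts 3 s.
* **Stages.** Per-neuron linear tuning with FDR correction; a
  discriminability index against the pre-stimulus baseline; split-half
  population-vector correlations; time-resolved diagonal-LDA decoding of
  touch type; exhaustive congruency-model selection (BIC and cvR2); and two
  population-generalization analyses (demixed subspaces, discrimination-axis
  transfer).
* **Ground truth.** A synthetic Poisson spike generator reproduces the task
  geometry with known per-neuron congruency models or known population-level
  compositional structure, so every stage has an acceptance surface with a
  known answer.

## Data model

A session is a `SpikeCountTensor`: a `units x trials x bins` array of spike
counts in uniform 10 ms bins, time measured in seconds relative to stimulus
onset with half-open bins `[left, right)`, plus per-trial condition labels
and per-unit metadata. Canonical condition order (actual before observed,
cheek before shoulder, touch types alphabetical) fixes every matrix layout.

The timeline follows the recorded protocol: baseline window `[-1, 0)` s,
analysis window `[0.5, 3.5]` s for 3 s stimulation (the 0.5 s offset absorbs
the experimenters' delay in delivering the stimulus), and tensors must cover
at least `[-1.5, 4]` s so that every published analysis window fits.
Requested windows are snapped *outward* to bin edges, deterministically.

Unit selection retains units with mean firing rate above 0.5 Hz and SNR
above 0.5. SNR is waveform-derived in recordings and therefore carried as
supplied metadata here, never recomputed; the synthetic generator draws it
from a gamma distribution (shape 4, scale 0.5, mean 2).

```{r}
pop <- generatePopulation("MSMT", nUnits = 12, nSessions = 1, seed = 1)
x <- pop$sessions[[1]]
x
table(selectUnits(x))
```

## The synthetic generator

Each simulated neuron has a baseline rate and a congruency model: an
assignment of the four sensory fields to "unresponsive" or to classes that
share a *selectivity pattern* (SP) — the vector of rate increments over the
four touch types. During the response window, a trial's expected rate is
`baseline + SP[touchType]` if its field is in a responsive class and
`baseline` otherwise; counts are Poisson per bin (a Gaussian-rate option
exists for closed-form checks). The response step is placed at the analysis
window onset (+0.5 s): the recorded protocol's stimulus-delivery delay and
the ~60 ms neural latency are absorbed into that offset, which keeps
expected analysis-window rates exactly `baseline + SP` and keeps
pre-stimulus decoding at chance.

Defaults mirror the recorded scale: 119 units x 8 sessions
(multidimensional), 126 x 6 (basic), 10 trials per condition, fresh units
each session (populations are re-recorded daily). Baselines are uniform on
1–10 Hz and SP increments uniform on 2–15 Hz; these effect sizes are
plausibility choices (per-condition effect sizes for the real neurons are
not published) and are deliberately strong enough that model recovery is
limited by trial counts, not by vanishing effects. The default model
mixture puts most mass on idiosyncratic/complex assignments with a 12%
(basic) or 5% (multidimensional) body-part-specific, mirror-like minority —
a qualitative echo of recorded heterogeneity, not a claim about the exact
published percentages.

The compositional generator instead builds population condition means as
`r(c) = baseline + W_body b(c) + W_touch t(c) + kappa W_int i(c) +
personGain W_person p(c)` with one-hot level codes and row-centered
loadings. Two deliberate choices: the body-by-touch interaction loadings
are drawn independently per person context, so the nonlinear interaction
never transfers across actual/observed (a shared interaction would
trivially generalize, which is not the phenomenon under study); and
`personSpecific = TRUE` redraws the body/touch loadings per person,
producing a population whose basic-level codes do *not* cross contexts —
the negative control for every generalization analysis.

What the generator does not emulate: correlated noise beyond the low-rank
mean structure, within-trial rate dynamics (onset transients, adaptation),
electrode drift, and unit-count attrition. Passing tests therefore show the
*analyses* are correct and calibrated, not that real cortex behaves this
way.

## Per-neuron tuning

Tuning fits `FR = sum_c beta_c X_c + beta_0` per unit. We operationalize
"modulation from baseline" by regressing baseline-subtracted rates on
condition indicators with a zero intercept reference, so each `beta_c` is
the mean modulation in condition `c`; the published contrast coding is not
stated, and this choice makes the coefficients exactly interpretable.
t-tests are two-sided (suppression counts as modulation). The FDR family is
the set of conditions within one unit, matching figures that report
per-condition responsive fractions; correction uses Benjamini–Hochberg at
q = 0.05. Session-level responsive fractions are summarized by a seeded
percentile bootstrap (1,000 resamples) across sessions.

## Population metrics

The discriminability index concatenates per-unit mean rates for the
analysis window (vector `A`) and baseline window (`B`) and reports
`DI = (mean(A) - mean(B)) / sqrt((var(A) + var(B)) / 2)`. The recorded
methods print exactly this univariate standardized difference while the
figure captions speak of a Mahalanobis distance; we implement the printed
formula as the default and provide a cross-validated Mahalanobis variant
(split-half mean differences whitened by pooled diagonal variance) as an
explicit alternative, asserting neither as "the" published computation.

Split-half correlation: per resample, each condition's trials are split in
half (ceil/floor for odd counts, the larger half alternating); Pearson
correlations between half-1 and half-2 mean population vectors give a
condition-by-condition matrix, symmetrized and averaged over 250 resamples.
The diagonal is the within-condition noise ceiling. Matched versus
mismatched body-part pairs are compared with a Welch t-test on
session-level values.

## Decoding

Touch types are decoded within one sensory field with diagonal LDA: class
means plus one pooled diagonal variance, equal priors (the design is
balanced), ties broken toward canonical class order. Variances are floored
at 1e-6 Hz^2 because all units are included — some are silent in a 300 ms
window. Accuracy is stratified leave-one-out, in 300 ms windows stepped at
10 ms from -0.5 s; the published end point is unstated, so the curve runs
until the window reaches stimulation offset + 0.5 s (start +3.2 s) by
default — a configuration choice, not a claim about the published curve.

## Congruency models

`enumerateModels()` builds every assignment of the four fields to
unresponsive-or-class, canonicalized so class ids are numbered by first
appearance (two assignments are the same model iff they induce the same
partition of responsive fields). Binary mode (basic task, 0/1 shared
coefficient) yields 2^4 = 16 models including the all-unresponsive one;
SP-sharing mode (multidimensional) yields 51 and excludes it — the
printed counts force this asymmetry, which is preserved deliberately.

Because the 0/1 coefficient scheme makes the all-responsive model collinear
with an intercept, all models are fit on baseline-subtracted rates with no
intercept: one shared-amplitude column per class (binary) or one column per
class x touch type (SP-sharing). On the balanced design all columns are
disjoint indicators, so every candidate is full rank.

Selection: Gaussian BIC on OLS residuals, `n log(RSS/n) + k log(n)`, and a
cvR2 from 10-fold condition-stratified cross-validation,
`1 - SS_res(held out) / SS_tot`; the published cvR2 protocol is unstated,
so the folds are seeded and recorded. Numerically zero residuals are
floored so exact fits tie and the tie breaks toward fewer parameters (a
noiseless neuron can be fit perfectly by any refinement of its true model);
such ties otherwise rank on rounding dust. BIC-best and cvR2-best are
reported separately, never merged. The eight-category grouping of the
51 models (invariant, body-part specific, person specific, single field,
three-fields-one-class, two-class other, idiosyncratic, unresponsive) is
this package's structural taxonomy: the published legend for the eight
modes is in supplementary material we do not reproduce.

## Subspace generalization

`marginalizedMeans()` is the exact balanced-design ANOVA identity: condition
means split into grand mean, two marginal factor effects and an interaction
that reconstruct the input to numerical precision, with orthogonal energy.
`fitDemixedAxes()` reduces each marginalization by SVD — a demixed-PCA-style
objective in which encoder and decoder coincide with the leading singular
vectors. The published analysis details live in supplementary material we
do not have; we therefore label results "dPCA-style" and expose component
counts (factor levels - 1; 3 for the interaction) in the interface. Latents
are the *marginalized* components projected on their own axes, so each
latent isolates its factor; projecting the full condition means instead
would let strong main effects leak into the interaction axes and fake
generalization. Test-context data are marginalized with the training
factors before projection, so a uniform context gain cannot masquerade as
factor structure. Transfer is summarized by the separation ratio
(test-level separation over training separation) and by the train–test
latent pattern correlation; for a one-component factor the pattern
correlation is forced to ±1, so the separation ratio is the informative
number there.

The axis-transfer analysis learns, per condition pair, a unit-norm
direction (difference of condition means whitened by pooled diagonal
variance — LDA under diagonal covariance; the published mapping family is
unstated). The normalized generalization index cross-validates the
denominator: the axis is learned on half the training trials, the training
separation is the signed difference of mean projections on the *held-out*
half, and the test separation uses the test pair's trials; the index is the
mean ratio over 25 half-splits. Signed ratios make a no-transfer situation
average to 0 rather than to a positive noise floor, and cross-validation
keeps pure-noise indices from being inflated by overfitting. Pairs whose
training separation is degenerate are excluded with an error rather than
silently returning an unstable ratio.

## Pipeline and reproducibility

`runAll()` chains simulate, unit selection and all stages, writing CSV/JSON
outputs plus a manifest with an MD5 hash per file; a config and seed fix
every output bit-exactly. A single global seed fans out to per-stage child
seeds through `deriveSeed()` (a polynomial hash of the stage name folded
into the seed modulo 2^31 - 1), so stages can be rerun in isolation.
Datasets round-trip through an HDF5 + CSV layout (`/counts`, `/bin_edges`,
`/unit_meta`, and a `session,trial,person,body_part,touch_type` table) with
validation errors that name the offending row or condition.

The test suite runs the generator at reduced problem sizes — typically
tens of units and one to four sessions, 120 units for model recovery —
chosen so the whole suite completes in about a minute while keeping
Monte-Carlo error well inside the asserted tolerances; the full recorded
scale (119 x 8) remains the package default for `runAll()`.

## Known limitations

* SNR must be supplied; the waveform-based definition is out of scope.
* The eight-category taxonomy and the dPCA/axis-mapping hyperparameters are
  this package's documented choices, not verified against the unavailable
  supplementary material.
* The Mahalanobis variant of the discriminability index uses diagonal
  covariance with a fixed floor; full covariance estimation at ~120 units
  and 10 trials per condition is not attempted.
* Generalization indices assume the train pair genuinely separates; with
  `personGain = 0` the person dimension carries no signal and person-pair
  transfer is undefined by design.
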