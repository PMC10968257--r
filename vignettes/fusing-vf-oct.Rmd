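---
title: "Fusing visual fields and OCT into interpretable AE-fused fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing visual fields and OCT into interpretable AE-fused fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedfuse)
```

## The problem

Glaucoma care tracks two very different measurements of the same disease.
Perimetry measures differential light sensitivity (DLS, in dB) at the 52
usable locations of the 24-2 grid; its summary index, mean deviation (MD),
trends downward as the field deteriorates, and the standard clinical
criterion calls a series *progressing* when the ordinary-least-squares MD
slope is worse than -0.5 dB/year. Optical coherence tomography measures
retinal nerve fiber layer (RNFL) thickness (um) at 256 angular positions on
a circle around the optic nerve head; it is far less noisy than perimetry
but saturates: below roughly 50 um of residual tissue the profile stops
tracking functional loss (the *floor effect*).

Perimetry is noisy enough that short follow-up windows produce many false
progression calls; OCT is quiet but indirect. This package fuses the two
modalities into a single 52-dimensional *AE-fused field* that can be read,
plotted and trend-analyzed exactly like an ordinary visual field.

## The model

An encoder $f_\theta$ maps the normalized input
$x = (v, r, a) \in \mathbb{R}^{309}$ (field, RNFL profile, age) to an
encoding $z = f_\theta(x) \in \mathbb{R}^{52}$; a decoder $g_\phi$ maps $z$
back to a reconstruction $x' = (v', r', a')$. Both are two-hidden-layer
multilayer perceptrons with GELU activations and layer normalization
(encoder 309-256-128-52, decoder mirrored). Training minimizes

$$L = (1 - \lambda)\, L_\mathrm{rec} + \lambda\, L_\mathrm{enc},
\qquad
L_\mathrm{rec} = \tfrac{1}{N}\sum_i \lVert x_i' - x_i \rVert^2,
\qquad
L_\mathrm{enc} = \tfrac{1}{N}\sum_i \lVert z_i - v_i \rVert^2 .$$

The encoding loss $L_\mathrm{enc}$ is what makes the fused data
interpretable: it penalizes the distance between the encoding and the
measured field, so each coordinate of $z$ remains a (structurally informed)
sensitivity estimate at a known grid location. The two terms are
adversarial: at $\lambda = 1$ training reduces to regressing $z$ onto $v$
and the fused field reproduces the measured field; at $\lambda = 0$ the
encoding is unconstrained and, although reconstruction is excellent, the
fused values drift off the DLS scale and cannot be read as a field (in
practice the slope scale collapses and trend analysis calls nothing
progressing). Intermediate $\lambda$ trades the two.

Both loss terms use one documented convention: the squared Euclidean norm of
the per-sample error vector (a sum over coordinates), averaged over the
batch. The norm in the loss definition above is already a sum over
coordinates, so $\lambda$ needs no rescaling between the 309-coordinate
reconstruction term and the 52-coordinate encoding term; we state the
convention because a per-coordinate-mean implementation would change the
effective $\lambda$ scale by a factor of about six.

### Normalization

All channels are mapped to $[0, 1]$ with *fixed clinical bounds* (DLS -1 to
40 dB, RNFL 0 to 250 um, age 0 to 110 years) rather than per-fold data
minima/maxima. Fixed bounds make the map identical across cross-validation
folds, preventing any leakage of validation statistics into training, and
make stored models portable between cohorts. Out-of-range values clip.

### Training protocol

Adam (learning rate 1e-3, batch 64), at most 500 epochs with early stopping
(patience 25) on the validation total loss; the returned model carries the
best-epoch parameters. All randomness flows through one integer seed, so a
fit is bit-reproducible. Model evaluation uses eye-grouped, severity-
stratified 10-fold cross-validation: folds partition *eyes* (never visits),
and eyes are dealt round-robin within severity bands (baseline MD $\ge -6$,
$-6$ to $-12$, $< -12$ dB — the common mild/moderate/severe convention), so
per-fold band counts deviate from proportionality by at most one eye.

### Choosing lambda

The mixing weight is selected by a grid search over $\lambda \in [0, 1]$
that trains per the cross-validation protocol and scores the aggregate F1
for progression detection at the two-year horizon; ties break toward the
smaller $\lambda$ (preferring reconstruction fidelity, hence more structural
information in the fused data). The package default is $\lambda = 0.6$. On
our synthetic cohorts the F1 surface between 0.1 and 0.6 is quite flat, and
a qualitative regime change happens only near the endpoints, consistent
with the adversarial-loss picture above; the monotone ordering of held-out
$L_\mathrm{enc}$ (decreasing in $\lambda$) and $L_\mathrm{rec}$ (increasing)
is asserted in the acceptance suite.

## The Bayesian linear-regression baseline

The comparator combines progression rates, not fields. For one eye and one
observation window, the functional rate is the OLS slope of MD with sampling
variance $\hat\sigma^2 / S_{xx}$; the structural prior converts the OLS
slope of mean RNFL thickness into dB/year through a conversion coefficient
$\kappa$ (dB per um), estimated once per training set by cross-sectionally
regressing MD on mean thickness over all training visits. The posterior rate
is the conjugate-normal precision-weighted average,

$$m_\mathrm{post} = \frac{m_l / v_l + m_p / v_p}{1 / v_l + 1 / v_p},
\qquad
v_\mathrm{post} = \frac{1}{1 / v_l + 1 / v_p},$$

so whichever measurement is steadier dominates. The prior variance is
$\kappa^2 \operatorname{var}(\text{structural slope})$ plus a first-order
term $\mathrm{se}(\kappa)^2 \, m_s^2$ propagating the uncertainty of
$\kappa$; the propagation term is configurable because different prior
constructions are defensible. With fewer than two OCT visits in a window the
prior is unavailable and the likelihood alone decides (flagged in the
output). A known pathology of this baseline is asserted as a property in the
test suite: for severe eyes whose RNFL sits at the floor, the structural
slope is near zero with tiny variance, so the posterior is pulled toward
stability and true progression is under-called.

## The progression benchmark

Each eye's follow-up is cut into overlapping segments with sliding windows
of 4-8 years (stride 1 year, configurable), which turns slow long-term
trajectories into many short-term episodes and keeps the linear trend model
locally adequate. The *ground truth* label of a segment is the OLS MD slope
of the **measured** field over the **full** window, thresholded strictly at
-0.5 dB/year; fused segments always inherit the label of their measured
twin. Classification then uses only the first 1-3 years of each segment
(0.5-year steps): measured MD slope (`vf`), fused-field MD slope (`fused`),
or the Bayesian posterior rate (`blr`), against the same threshold. Fused MD
is defined as the mean total deviation of the fused field against the same
normative values as the measured field, so both slopes share units and
threshold.

Counts accumulate per (method, window length, truncation time);
sensitivity, specificity and F1 use the standard confusion-matrix formulas,
with zero-denominator cases reported as NaN and excluded from aggregation
rather than imputed. Aggregation over the (window x fold) values at each
time reports mean +/- 1.96 SEM. Paired method comparisons use a Wilcoxon
signed-rank test, paired by (window length, fold) at a fixed truncation
time: exact (dynamic programming over the sign-flip distribution of midrank
sums, so tied differences are handled exactly) up to n = 25, and the normal
approximation with tie correction beyond. The minimum of four visits per
full window makes the label's residual variance estimable; two visits
inside a truncation are the minimum for a slope, and segments unclassifiable
at a given time are excluded from that time's counts (logged as NA).

## The synthetic cohort

No public paired VF/OCT longitudinal cohort exists, so the package ships a
simulator whose defaults emulate a tertiary glaucoma-clinic population:
baseline age 63.7 (SD 11.8) years, follow-up 7.7 (SD 1.7) years at roughly
0.8-year intervals, baseline MD -3.2 (SD 5.8) dB truncated above the -20 dB
exclusion floor, baseline mean RNFL thickness near 79 um, and a
stable/progressor slope mixture (75% near 0, 25% drawn below -0.5 dB/year)
with overall mean near -0.2 dB/year.

Each eye draws a defect archetype (superior arcuate, inferior arcuate,
nasal step, diffuse — an invented but clinically recognizable library,
shipped as unit-mean weight masks that users can extend). The latent field
declines linearly; half of the progression deepens the baseline pattern and
half is diffuse, so defects deepen *and* spread while latent MD stays
exactly linear at the drawn slope (which gives the pipeline its noise-free
oracle: truncated and full-window slopes coincide). RNFL sectors follow
regional field loss through a Garway-Heath-style map (six angular sectors,
temporal reference at 0 degrees, counter-clockwise for right eyes; shipped
as a data table) with gain `sf_gain` um/dB, clamped at the 50 um floor.
The gain has no published value and cross-sectional versus longitudinal
estimates disagree; the default of 1.5 um/dB with per-eye variability in
the healthy double-hump profile reproduces both the baseline thickness and
a plausible thickness slope, and is documented as a free calibration knob.

Measurement noise has three components, each motivated by the perimetry
literature: (1) independent pointwise noise (SD 2 dB at normal sensitivity)
that inflates linearly below 25 dB of latent sensitivity, mimicking the
well-known blow-up of test-retest variability in damaged regions; (2) a
per-test *global fluctuation* (SD 0.8 dB) shared by all locations — without
it, MD's test-retest SD would be an implausible 0.3 dB because 52
independent errors average out, whereas clinical MD varies by about 1 dB
between sessions; and (3) optional trial-lens-rim artifacts: a fixed 5 dB
depression of the peripheral ring of points in a configurable fraction of
visits, with no structural correlate. RNFL samples get independent Gaussian
noise (SD 2 um by default), so mean thickness is very quiet — the
structure-function asymmetry the fusion method assumes. Reliability indices
are drawn so a configurable fraction of visits fails the intake filters.

What the simulator does **not** emulate: the SITA staircase procedure and
its response-error model, device normative databases (a smooth synthetic
normative surface stands in), nonlinear or treatment-modified trajectories,
ganglion-cell-level physiology, and — importantly — the *irregularity* of
real artifacts. Simulated artifacts have a fixed footprint and depth, which
makes them a learnable pattern: with enough training data the encoder can
learn to pass them through into the encoding (doing so lowers both loss
terms), whereas real lens-rim artifacts vary in position and depth between
visits. Passing tests on this simulator therefore demonstrates the
machinery (losses, cross-validation, segmentation, metrics) and the
qualitative regimes of $\lambda$, not the clinical effect size of fusion on
real data; the benefit of fusion is largest precisely for the idiosyncratic
noise a generator cannot make fully realistic.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the progression criteria: a slope exactly
  at the threshold reads *stable*; reliability cut-offs exclude at the
  printed limits (a false-positive rate of exactly 15% is unreliable).
* OLS uses the closed form; with two points the fit is exact and the slope
  variance is reported as 0. A zero variance in the Bayesian update means
  certainty: that component is returned unchanged, and if both variances
  are zero the functional estimate wins (functional data is primary).
  Two infinite variances are an error.
* Normalization with `max == min` on any channel is rejected
  (`degenerate-channel`); out-of-range data clip after normalization.
* Training aborts with a diagnostic on non-finite losses; early stopping
  compares against the best validation loss with a 1e-9 margin.
* Visit-level filter order: reliability first, then the baseline-MD
  exclusion computed on the filtered series — "first test" is only
  meaningful among reliable tests. One reason code per excluded visit, with
  a documented precedence (incomplete metadata, VF reliability, OCT signal,
  missing RNFL samples, baseline MD).
* Left eyes are mirrored to right-eye orientation at read time; 54-point
  exports lose the two blind-spot columns on read. The 256-sample profile's
  angular origin (temporal, counter-clockwise for right eyes) is an internal
  convention — no device standard exists — and is stored in the cohort
  sidecar.

## Problem sizes

The shipped tests train on deliberately small cohorts (8-50 patients,
hidden layers down-scaled in the unit tests) and the acceptance suite uses
35-patient cohorts with 3-4 cross-validation folds and 150-500 epochs;
these sizes were chosen so the full suite runs on a laptop-class CPU in
minutes while every assertion still exercises the genuine training path.
The same functions scale to larger cohorts unchanged.

## Known limitations

* The fused field inherits whatever structure the encoder has learned;
  for inputs far outside the training distribution (e.g. post-surgical
  fields) it is extrapolation.
* MD here is the unweighted mean of total deviations; device MD weights by
  normative variance, so absolute values differ from printouts by fractions
  of a dB, though slopes are comparable.
* The conversion coefficient kappa is a population cross-sectional slope;
  eye-specific conversion would need hierarchical modelling, deliberately
  out of scope for this baseline.
* On synthetic cohorts whose artifacts are perfectly regular, the measured
  specificity advantage of fusion shrinks as training data grows (see the
  simulator section); conclusions about clinical effect sizes belong to
  clinical data.
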