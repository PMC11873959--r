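---
title: "Pairwise comparison learning for longitudinal image change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise comparison learning for longitudinal image change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The comparison model

Given two images $I_{t_1}, I_{t_2}$ of the same subject and optional
per-timepoint covariate vectors $M_{t_1}, M_{t_2}$, the model scores the
pair as

$$ r(I_{t_1}, I_{t_2}) \;=\; w^\top\!\big( (f(I_{t_1}) \oplus M_{t_1}) -
   (f(I_{t_2}) \oplus M_{t_2}) \big), $$

where $f$ is a convolutional feature extractor shared between the two
branches (a Siamese arrangement), $\oplus$ is concatenation, and $w$ is a
single linear layer **without a bias term**. Linearity in the feature
difference gives the score the three ranking properties — reflexivity
($r(a,a)=0$), antisymmetry ($r(a,b)=-r(b,a)$) and additive transitivity
($r(a,b)+r(b,c)=r(a,c)$) — exactly, up to floating-point rounding; the
test suite asserts them at $10^{-4}$ relative tolerance on random input
triples, in inference mode, for both random and trained weights. In
training mode batch-normalisation uses batch statistics, which breaks
per-call determinism, so all property tests run in inference mode; the
two branches are stacked into one forward batch so they always share
normalisation statistics.

Three tasks reuse this head:

* **ordering** — binary label "presented in chronological order";
  $\sigma(r)$ is the probability, trained with binary cross-entropy;
* **interval** — $r$ regresses $\Delta t$ with squared error;
* **score** — $r$ regresses the change $\Delta y$ in a scalar target,
  with metadata such as $(t, \text{sex}\cdot t)$ supplied so that the
  subtraction inside the model hands the head the interval and
  sex-by-interval directly and the image pathway only needs to carry
  target-specific signal.

The single-image regression baseline (SIRB) uses the same extractor
family with an ordinary biased linear head on one image at a time;
pairwise change is the difference of its two predictions.

## Architecture and defaults

The extractor has four blocks, each `conv (stride 1, same padding) →
BatchNorm → leaky ReLU → pooling (window 2)`; four blocks halve every
spatial dimension four times, so a $64^2$ image yields a $4\times4$
activation grid and a $128^3$ volume the $8\times8\times8$ grid used for
population peak maps. The final grid is **flattened**, not globally
pooled — this is what makes element-wise saliency attribution possible.
Defaults: channels $(8, 16, 32, 32)$, kernel 3, leaky-ReLU slope 0.01,
BatchNorm momentum 0.1 and variance floor $10^{-5}$. Average pooling is
the default for comparison models and max pooling for SIRB (each having
been reported as the stronger choice for its role). With these defaults
the 3D extractor has on the order of $5\times10^4$ parameters —
deliberately lightweight; channel counts are configuration, not
architecture.

Convolution weights are He-initialised. The head vector $w$ starts at
**zero**: the comparison then starts unbiased ($r=0$, order probability
0.5), and — more importantly for interpretation — feature positions that
never receive training signal (image regions whose features are constant
within every subject) keep weight exactly zero and therefore contribute
nothing to the score or to saliency maps. With a random head
initialisation, high-activation but uninformative regions (e.g. a static
bright structure) would enter the saliency map through their initial
random weights.

Inputs are min–max normalised to $[0,1]$ per image, a choice that is
robust across modalities and removes global intensity drift by
construction.

The network core (im2col convolution with an Rcpp gather kernel,
BatchNorm, pooling, full backpropagation, Adam) is implemented in the
package; its gradients are verified against central differences in the
test suite at $10^{-4}$ relative tolerance, through all four blocks, both
pooling types and the metadata pathway.

## Training

Adam with learning rate $10^{-3}$ and conventional moments
$\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$, no weight decay. Early
stopping halts training when the validation loss has not decreased for
10 consecutive epochs (the `patience` default), and the
best-validation-loss weights and normalisation statistics are restored;
ties select the earliest epoch. Validation AUC (ordering) or $R^2$
(regression) is logged per epoch and reported alongside; the minimum
validation loss is the selector.

For the ordering task, each unordered within-subject pair is emitted
once per epoch with a freshly randomised presentation order, keeping
labels balanced 1:1 in expectation while halving cost relative to
emitting both orders; a `both_orders` flag provides exact balance when
wanted (the bias-free head makes the two orders informationally
redundant, so either convention is sound).

An optional curriculum admits only pairs separated by more than a
threshold (e.g. 50 months in a brain-aging setting) at epoch 0, then
decays the threshold linearly to zero in steps every 2 epochs so that
all pairs pass after a 10-epoch warm-up. The decay shape is a design
choice: only the starting threshold, the step cadence, and the warm-up
horizon are externally specified, and a linear ramp is the simplest
schedule through those constraints. If the filter ever admits no pairs,
the threshold is relaxed step by step with a warning rather than
aborting.

## Saliency

Because features are flattened, Grad-CAM's per-channel importance
weights become element-wise: the saliency map is the gradient of the
comparison score with respect to the last-block activation grid,
multiplied element-wise with the activations, summed over channels,
rectified, and upsampled. For the linear head this gradient is exactly
$\pm w$ reshaped onto the grid, so the map is not an approximation but
an exact decomposition of the score.

Two decisions deserve explanation:

* **Predicted-class sign.** The differentiated scalar is the presigmoid
  $r$, taken with positive sign when $r \ge 0$ and negated otherwise —
  i.e. the score of the class actually predicted. Without this, a pair
  presented in anti-chronological order (negative $r$) has all its
  evidence contributing negatively, the ReLU clips everything, and the
  map degenerates to noise.
* **Per-branch vs pair maps.** `branch = "first"`/`"second"` maps
  ($\mathrm{ReLU}(\sum_c A_1 \odot G)$ and
  $\mathrm{ReLU}(-\sum_c A_2 \odot G)$) attribute one image with the
  other fixed and are the right overlay for figures. But each contains
  the *shared* content of the pair, with a sign that depends on the
  arbitrary sign structure of the learned channels, so one of the two
  is typically ReLU-clipped. The `"pair"` map sums the two signed maps
  *before* rectification; the shared content cancels exactly, the
  result decomposes $r$ into per-cell contributions, and it is invariant
  to presentation order. Quantitative analyses (peak hit rates,
  population maps) use the pair map.

ReLU is applied after channel summation, matching the original Grad-CAM
ordering; ties in the peak are broken at the lowest linear index.
Upsampling is separable linear interpolation with half-pixel centres
(no corner alignment); nearest-neighbour replication is available and is
used for binarised peak indicators so that their mass is conserved.

Per-case trust is quantified by the explainability score
$\tau = 1 - (y - \hat y)^2 / (y - \bar y)^2$ with $\bar y$ the
training-target mean — an $R^2$ without the sum, treated as an
Efron-style pseudo-score for the binary task (with $\hat y = \sigma(r)$).
$\tau$ is undefined when $y = \bar y$; such cases return `NA` and are
excluded from gated summaries. Reported maps use $\tau > 0.7$.
Population summaries binarise each included case's coarse map at its
peak, upsample, and average, using one pair per subject (the maximum
$|\Delta t|$ pair) so subjects with many timepoints are not
over-weighted.

As an independent check, an occlusion-sensitivity oracle slides a zero
patch over one branch on the same coarse grid and records $|r -
r_\text{base}|$. Its spatial resolution is bounded below by the
network's receptive field (about three coarse cells for the default
architecture), so agreement with Grad-CAM is asserted as the Grad-CAM
peak lying within the occlusion peak's one-cell neighbourhood, and — the
stricter check — inside the known sensitive region of constructed stub
models whose head weights are supported on a known block of cells.

## Statistical evaluation

* **AUC** is computed from midranks (ties get half credit), which makes
  the constant-score naive baseline exactly 0.5. The implementation is
  cross-checked against brute-force positive–negative pair counting and
  against an independent ROC package. Uncertainty comes from a
  percentile bootstrap: 1,000 resamples of the test set with
  replacement, resamples that lose a class redrawn. Percentile (rather
  than BCa) intervals match the plain resampling description of the
  procedure.
* **Regression** reports RMSE, MAE and $R^2$, against the naive
  baseline that always predicts zero (the mean of a balanced change
  target). Pearson correlations between predicted and true change use
  only chronologically ordered pairs, with the presigmoid logit as the
  prediction for ordering models.
* **Mixed-effects slope analysis.** Predicted changes anchored at each
  subject's first timepoint (change at $t=0$ is zero by construction)
  are modelled without intercepts as
  $\text{change} = \beta t + \gamma\,\text{group}\cdot t + b_s t +
  \varepsilon$, $b_s \sim N(0, \sigma_b^2)$, fitted by maximum
  likelihood via `lme4`. Individual variability is tested by a
  likelihood-ratio test against the fixed-effects-only reduction; since
  the variance is tested on its boundary, the null is the mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ and the p-value is half the
  $\chi^2_1$ tail (1 when the statistic is zero). The group effect is
  tested by a likelihood-ratio test between random-slope models with
  and without the group term ($\chi^2_1$), keeping random slopes under
  both hypotheses. Operating characteristics are checked by simulation:
  with 40 subjects, 5 anchored timepoints, $\beta = 1$,
  $\sigma_b = 0.15$, $\sigma_e = 0.3$ and $\gamma = 0.3$, a standard
  error calculation gives an effect-to-SE ratio near 6, so the
  configured effect size was chosen a priori to give essentially full
  power while the type-I rate is verified near the nominal 5% over 200
  null replicates.

## The synthetic cohort generator

Real longitudinal datasets (embryo time-lapse, wound assays, serial
brain MRI) are large, restricted, or both, so validation runs on
synthetic cohorts with exact ground truth. Each subject carries a
monotone change process with rate drawn from
$N(\mu + \delta\,\mathbb{1}[\text{treatment}], \sigma^2)$ (truncated at
zero); the default rendering is a soft-edged disk whose radius grows
linearly with the process state, and a "division" variant doubles blob
count at integer states (emulating cleavage) with per-blob radius
shrinking to conserve area. An optional second, spatially disjoint
process — a shrinking disk with its own subject-specific rate, drawn
independently of the change rate — emulates a concurrent confounded
dynamic such as ordinary aging alongside disease-specific change.

Three aspects of the two-process design matter for validity and were
set by analysis rather than convenience. First, the confound rate
varies between subjects: a confound whose image signal were an exact
function of elapsed time would be perfectly collinear with the supplied
time metadata, leaving the placement of head weight between the
confound region and the metadata undetermined — the disentanglement
claim would then rest on optimizer luck rather than on the model.
Second, the two regions sit on opposite diagonal corners, separated by
more than the extractor's receptive field (roughly 18 px for the
default architecture), because saliency cannot be expected to
distinguish structures closer together than the network's spatial
resolution. Third, the focal (score) process carries the larger mean
rate and substantial between-subject variability (0.3 ± 0.1 state
units per frame against 0.15 ± 0.05 for the confound): the
subject-varying component is precisely what forces the model to read
the score region at all, and with only a handful of training subjects
a weak focal signal can be matched in-sample by chance correlation
with the confound.

Nuisance variation is drawn independently per frame: rotation about the
grid centre (default maximum 5°), per-axis translation (2 px),
multiplicative intensity drift (10%) and additive Gaussian noise (SD
0.02 on a $[0,1]$ intensity scale). Because the shapes are isotropic,
rigid motion is applied analytically to shape centres, so the nuisance
is exact rather than resampled and carries no ordering information by
construction; a test checks the empirical correlation between nuisance
draws and frame index. Configurations whose shapes could leave the
field of view at a $+3$ SD rate are rejected with a sizing error at
construction time. Ground truth (per-subject rates, groups, per-frame
states, change and confound region masks) is returned in memory and
written as a JSON sidecar next to the image files (32-bit TIFF for 2D,
NIfTI for 3D) and CSV manifest.

What the generator does **not** emulate: photorealistic texture,
deformable anatomy, registration error beyond rigid jitter,
within-subject acquisition gaps, or label noise. Passing tests on these
cohorts therefore demonstrate that the implementation learns, localizes
and quantifies the kind of monotone, spatially localized change the
model class targets under realistic nuisance — not that it will match
any particular real dataset's accuracy.

## Problem sizes

The end-to-end checks use 10-subject cohorts of 12 frames at
$64\times64$, split 60/20/20 by subject, trained for 10–12 epochs with
batch size 32 — sizes at which the full pipeline (three trained models,
saliency analyses and the mixed-model simulations) completes in a few
minutes on one CPU while leaving wide margins to the thresholds being
tested. The mixed-model operating characteristics use 200 replicates
per condition.

## Known limitations

* 3D support is functional (the geometry code is dimension-generic) but
  the end-to-end training checks are 2D; volumes are assumed
  co-registered by the user, and registration is out of scope.
* Per-branch saliency maps are informative overlays but, unlike the
  pair map, can be ReLU-clipped depending on learned channel signs; the
  package defaults to the pair map for anything quantitative.
* The occlusion oracle's resolution is limited by the receptive field;
  it validates region-level, not cell-level, agreement.
* Only two-image comparisons are supported; sequence-level models and
  transformer extractors are out of scope.
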