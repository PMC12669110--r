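---
title: "Methods: OCT-based cardiovascular risk prediction with octcvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT-based cardiovascular risk prediction with octcvd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

octcvd implements a complete analysis for predicting five-year myocardial
infarction / stroke risk from macular optical coherence tomography (OCT):
quality filtering, matched case-control construction, self-supervised
representation learning with a variational autoencoder (VAE), multimodal
random-forest classification over seven data-channel combinations, and dual
(global + local) explainability built around latent-traversal vector fields.
Because clinical OCT cohorts with longitudinal cardiovascular outcomes cannot
be redistributed, the package ships a synthetic phantom generator that plants
a known choroidal-morphology signal; every pipeline stage is tested against
that recoverable ground truth.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic experiments do and do
not demonstrate.

## The synthetic OCT phantom

A phantom B-scan is a stack of horizontal tissue bands delimited by the 11
named retinal boundaries used in clinical OCT reading (ILM, RNFL, GCL, IPL,
INL, OPL, BMEIS, IB_OPR, IB_RPE, OB_RPE, and the lower choroidal boundary).
Each band has a mean thickness and reflectivity (`layer_specs()`); boundary
positions are the cumulative sums of sampled band thicknesses, displaced by a
shared undulation field — a sum of at most three low-frequency sinusoids with
random phase (`undulation_amp`, default 2 px) — which gives anatomy-like
curvature without requiring any segmentation machinery. Speckle is modelled
multiplicatively with a unit-mean gamma field whose standard deviation is
`speckle_level / quality`, the standard first-order OCT speckle model; each
scan draws its own quality factor, and the left eye has higher mean quality
than the right (`quality_mean_left = 1`, `quality_mean_right = 0.9`),
emulating acquisition-order differences reported for biobank protocols.

Band reflectivities are calibrated so that most tissue sits above the quality
index's upper threshold (0.45–0.95). This matters: with dim mid-layers, added
noise pushes pixels *up* through the threshold and the quality index would
reward noise. With the bright calibration, both speckle and additive noise
drain signal mass downward and the QI decreases monotonically with noise, as
it does on real scans.

Clinical metadata (age, sex, ethnicity, BMI, systolic/diastolic blood
pressure, HbA1c, alcohol status) are drawn from per-label Gaussian and
categorical distributions calibrated to a published matched cardiovascular
cohort; age and sex marginals are identical across labels *by construction*,
so matching is testable and the planted image signal is the only systematic
label difference. The disease signal itself is planted **only in choroidal
thickness**: CVD+ subjects have their mean choroidal band scaled by
`1 + choroid_effect`. The real effect size is not quantified in the source
literature, so `choroid_effect` is a free parameter (0 disables the signal;
the desk-scale study uses 0.35, deliberately strong so recovery is
unambiguous at small n). An optional RNFL/GCL thinning toggle exists but is
off by default, keeping the ground truth single-sourced. Both eyes share a
subject-level thickness latent with correlation 0.8 — same anatomy, imaged
twice, but not identical.

The choroid itself is not rendered as a uniform band: real choroid is
depth-stratified vascular tissue (choriocapillaris, Sattler and Haller
zones), and the phantom modulates choroidal reflectivity sinusoidally in
*fractional* band depth (`choroid_texture`, default amplitude 0.25). The
modulation is deterministic given the boundaries, so it is learnable, and
because it is anchored to fractional depth, a thickness change stretches
it — giving optical flow trackable structure throughout the band exactly as
vascular texture does in real scans. A uniform band would be invisible to
flow estimation everywhere except a thin ring at its moving boundary,
making the explainability stage blind to the planted signal by
construction.

When sampled thicknesses overflow the image height, the vitreous gap above
the ILM absorbs the excess (the retina sits higher in the frame); a stack
that cannot fit even then is a configuration error.

## Quality index and exclusion

The quality index follows the two published ingredients: an intensity ratio
(mean intensity of pixels above the saturation-free upper histogram mode,
relative to the overall mean — the top histogram bin is excluded as
saturation) and a tissue signal ratio (pixels above `tau_hi = 0.55` per pixel
below `tau_lo = 0.30`), with `qi = intensity_ratio * tissue_signal_ratio`.
The cited original algorithm is not public in full; the thresholds are
config-exposed and the package makes no claim of numeric agreement with it,
only of the same construction and the same monotone response to degradation.
Constant images are degenerate and score 0. QI is computed per B-scan; a
volume's QI is the median over its scans (the source study does not state
which level it scored, so both are available). `filter_lowest_fraction()`
excludes exactly `floor(fraction * n)` scans (default 20 %), breaking ties by
stable input order so the filter is deterministic.

## Cohort construction

The event window is half-open: an event qualifies if `0 < offset <= 5`
years, so pre-imaging events never count and an event exactly at the horizon
does. Comorbidity exclusions (diabetes, cardiomyopathy) are applied one
criterion at a time, each recorded as a step in a STROBE-style ledger with
conservation (`n_after = n_before - n_excluded`) and chaining enforced.

Matching fits a logistic propensity model of case status on age and sex,
then — within exact sex strata, in seeded random case order — greedily
assigns each case the `ratio = 3` nearest controls by propensity score
without replacement, subject to an age caliper (default 2 years). Greedy
nearest-neighbour without replacement is the simplest deterministic standard
variant; the case-order shuffle removes input-order bias while staying
reproducible. By default a case that cannot receive its full complement of
controls is an error that names the unmatched cases — there is no silent
partial matching. The pipeline instead uses the explicit `on_unmatched =
"drop"` mode: at a few hundred subjects, one or two extreme-age cases are
routinely unmatchable inside the caliper, and removing them (recorded in the
ledger, ids retained in the result) is exactly what matched designs do in
practice. Constant covariates (e.g. a single-sex stratum test fixture) are
dropped from the propensity model rather than breaking the model matrix.

## The VAE

Each eye gets its own VAE trained on that eye's B-scans. The encoder maps a
flattened scan to a diagonal Gaussian posterior (mean and log-variance of
dimension `latent_dim`, default 128); the decoder maps a latent draw back to
the image through a sigmoid output. Training minimizes

$$L = L_{MSE} + \beta \, L_{KL}, \qquad
L_{KL} = \sum_d \tfrac{1}{2}\left(\sigma_d^2 + \mu_d^2 - 1 -
\log \sigma_d^2\right),$$

where $L_{MSE}$ is the per-sample squared reconstruction error — the
pixel-wise squared difference summed over the image, averaged over the batch
— and $L_{KL}$ is the Gaussian KL divergence to the standard-normal prior in
its nonnegative form, summed over latent dimensions and averaged over the
batch: the sign and summation convention under which minimizing the loss is
equivalent to maximizing the evidence lower bound. The pixel *sum* (not
mean) in the reconstruction term is load-bearing: it keeps reconstruction
and KL on the scale at which $\beta \in [0.001, 0.01]$ is a meaningful
trade-off. With a per-pixel mean the KL term outweighs reconstruction by the
pixel count and the posterior collapses completely — every latent-mean
standard deviation shrinks to $\sim 10^{-3}$, the decoder ignores the
latents, and latent traversals decode to nothing, even while downstream
classifiers still pick up faint encoder-side signal.
$\beta$ follows a linear KL-annealing ramp from 0.001 at epoch 0 to 0.01 at
epoch 20, constant thereafter (the simplest monotone schedule matching both
endpoints; the plateau value is returned exactly, not up to rounding).
Annealing lets the model prioritize reconstruction before regularizing the
latent space.

The architecture is convolutional: the encoder stacks stride-2 3×3
convolutions with ReLU activations (six layers at the default channel plan,
automatically trimmed when the image is too small for the full stack); the
decoder mirrors it with nearest-neighbour 2× resizes followed by 3×3
convolutions with leaky-ReLU activations (slope 0.2) and a final sigmoid
conv to one channel. Convolutional layers matter beyond efficiency: their
latent directions decode to *spatially local* image changes, which is what
makes latent-traversal explanations localize. (A fully connected
variant remains available via `vae_config(arch = "dense")`; its latent
directions are global eigen-image-like patterns, and measured on planted
phantoms its traversals spread over the whole scan — fine for
classification, useless for localization.) The conv forward/backward passes
are implemented in compiled code (each 3×3 kernel tap is one BLAS GEMM on a
column-shifted view of the padded channels-first feature map), with
hand-derived gradients verified against finite differences in the test
suite; Adam with learning rate $10^{-3}$. Log-variances are clamped to
$[-10, 10]$ for numerical stability (gradient masked at the clamp).
Training uses reparameterized sampling; **inference uses the posterior mean
with no sampling**, so every downstream feature is deterministic. Images
are split 6:2:2 train/validation/test by seeded permutation; validation
losses are computed at the posterior mean. One loss-breakdown row is logged
per epoch and `total = mse + beta * kl` holds to machine precision on every
row.

A volume's per-eye representation is the mean of the per-scan posterior means
over **all** B-scans (modes for a central slice or an explicit subset exist;
using the whole stack avoids discarding most of the volume, a criticism of
earlier work). Warm-starting from previously trained weights is supported
via `init_weights`.

## Classification

Seven feature tables are assembled from the same subjects: left-eye latents
(LE), right-eye latents (RE), both (BE), metadata only (MTDT), and the three
image+metadata combinations, with columns always ordered `[zl | zr |
metadata]` and named `zl000…`, `zr000…` after the eye and latent index. The
eight clinical variables are encoded to exactly one numeric column each —
categoricals as integer codes with missing alcohol status kept as its own
level, continuous passed raw (forests are scale-invariant), missing
continuous values set to 0 with an appended missingness indicator. Integer
coding rather than one-hot keeps the metadata block at 8 columns so the
combined BE-MTDT table has exactly 128 + 128 + 8 columns at the default
latent size.

Feature selection is recursive feature elimination on impurity (Gini)
importance, dropping 10 % of the remaining columns per round to a target of
10 features (5 for the right-eye-only mode). Model selection is a seeded
grid search over forest hyperparameters scored by mean AUROC under
five-fold cross-validation, refit on the full training data. Subjects are
split 5:2:3 train/validation/test, stratified by label so both classes are
present everywhere at small n; the grid search cross-validates over
train+validation and the held-out test set is locked by an order-invariant
hash recorded at split time — every later evaluation asserts it, so the test
set provably never moves between experiments.

Evaluation reports accuracy, sensitivity and specificity at probability
threshold 0.5, AUROC via the midrank statistic (ties count one half;
equivalent to the all-pairs probability comparison), confusion counts, and
95 % bootstrap confidence intervals over test subjects. Classifier pairs are
compared by McNemar's test on discordant correctness,
$\chi^2 = (b - c)^2/(b + c)$ with 1 degree of freedom and no continuity
correction by default (correction and a contingency-table variant are
config-switchable; the source study does not state which $\chi^2$ it used,
so both are available).

## Explainability

*Global.* Feature importance is the forest's mean Gini information gain,
normalized to sum to one; channel (modality) importance aggregates it into
percentage shares for left-eye latents, right-eye latents and metadata.

*Local.* The most important latent dimension $z_{max}$ (ties: lowest index)
is perturbed multiplicatively by $\sigma_{max}$, the standard deviation of
that dimension's posterior means over the training population; all other
dimensions stay fixed. The base and perturbed latent vectors are decoded and
the displacement field between the two reconstructions is estimated with a
Lucas–Kanade solver: central-difference spatial gradients (averaged over
the two frames), 5×5 windows, and a structure-tensor minimum-eigenvalue
gate at $10^{-4}$ below which pixels are masked invalid. `lucas_kanade()`
itself is single-level; because traversal displacements span several
pixels, `vector_field_explanation()` defaults to a three-level
coarse-to-fine pyramid (2× box-filter downsampling, bilinear warping of the
second frame by the upsampled coarse flow, then single-level refinement),
which tracks shifts of at least six pixels accurately. Flow between the
*original image* and the perturbed
reconstruction is config-selectable but not the default, because
reconstruction error would contaminate the field; comparing the two
reconstructions isolates the effect of the traversal. An additive
perturbation mode exists for sensitivity analysis.

The magnitude map is summarized per tissue band using the phantom's
ground-truth boundary maps: mean magnitude, area fraction, and the
enrichment of top-decile-magnitude pixels relative to the band's area
fraction. On planted-signal cohorts the choroidal band should carry the
signal — that is the recoverable target the generator provides. An
occlusion-sensitivity comparator (mean-intensity patch, configurable size
and stride, probability-drop saliency averaged over overlapping patches and
min-max normalized) cross-checks the vector-field localization with an
entirely different mechanism.

## Pipeline, seeding and reproducibility

`run_pipeline()` executes simulate → quality filter → cohort rules →
matching → per-eye VAE training → seven-mode classification → explanation.
A single run seed is fanned out to per-stage seeds by hashing the stage name
(`stage_seed()`), so a stage rerun in isolation reproduces its output. The
run manifest records the config hash, all stage seeds, the locked test-set
hash and a hash of the metrics table; two runs with identical config and
seed are bit-identical. The VAE is trained self-supervised on all
quality-retained volumes (optionally capped per eye by a seeded subsample,
`vae_max_volumes`), independent of labels; latents are then extracted for
the matched subjects only.

## Desk-scale study conditions

`study_config()` fixes the conditions used by the end-to-end tests and the
acceptance script: 60 cases and 360 controls, 16 B-scans per eye at 64×64 px,
`choroid_effect = 0.35`, speckle 0.2; a conv VAE with 32 latent dimensions
and channel plan 8/16/32/64/64/64, trained 48 epochs with the 0.001→0.01
ramp over the first 20 (the plateau epochs supply most of the
disentanglement pressure) on a seeded subsample of 80 volumes per eye; 20 %
quality exclusion, 1:3 matching with a 3-year caliper (slightly wider than
the 2-year default — the desk-scale control pool is thousands of times
smaller than a biobank's); RFE to 10 features (5 for RE) and 800-tree
forests; 1000 bootstrap replicates. The sizes were chosen so a full run
takes minutes on a single CPU while the matched cohort stays above 200
subjects. The latent dimension is reduced from 128 to 32 in proportion to
the reduced image complexity; the default configuration object retains the
full-scale values.

## What the synthetic experiments do and do not show

Passing tests on phantoms demonstrate that the pipeline *recovers a planted
choroidal signal*: at least one latent dimension tracks ground-truth
choroidal thickness, image-derived classifiers beat metadata-only ones, and
the vector-field explanation concentrates in the choroidal band. They do
**not** show that real OCT carries such a signal at any particular effect
size — the phantoms omit vascular texture, attenuation and shadowing,
motion artifacts, pathology other than the planted effect, and real
metadata-image correlations (phantom metadata are independent of the images
by design, which is why the metadata-only classifier hovers at chance on
synthetic cohorts). Published performance figures from real cohorts are not
reproducible from this package and are not targets of its tests.

A quantitative caveat on localization: on planted-signal cohorts the
choroidal band carries the largest absolute share of top-decile flow pixels
(about 0.31 at an area fraction of about 0.26), and the highest enrichment
*ratios* land on the thin RPE-complex bands directly adjacent to the
choroid — the same "choroid plus adjacent RPE" pattern reported for real
cohorts. The traversal axis is not perfectly disentangled at the annealed
KL weights used here (β ≤ 0.01): it retains a global-position component,
and because the RPE bands are the brightest edges in the scan, that
residual registers there most strongly. Strong in-band exclusivity of the
top-decile flow (say, a 2× enrichment of a quarter-of-the-image band, i.e.
more than half of all top-decile pixels inside it) is not reached at desk
scale; users interpreting per-band summaries should read the share and the
ratio together.

## Known limitations

Dense (not convolutional) VAE layers; single-level optical flow; the QI is a
faithful reconstruction of the described ingredients, not the original
implementation; phantom realism as above; matching assumes an ample control
pool and will (by design) refuse, or explicitly drop, unmatchable cases.
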