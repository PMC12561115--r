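---
title: "Reconstruction-based anomaly detection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based anomaly detection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection principle

`anomrecon` implements the reconstruction route to unsupervised anomaly
detection. A generative backend `decode(z)` represents the baseline
distribution of images; a test image is reconstructed by searching the latent
space for the decoded image closest to it in pixel MSE. Everything rests on a
single asymmetry: content inside the backend's expressible family is
recovered almost exactly, content outside it (the anomaly) cannot be
rendered at any latent, so its pixels stay as residual. The residual's size
is the detection score and its location the localization. Encoder-based
inversion is deliberately avoided — an encoder trained to be accurate
everywhere would partially reproduce anomalies and erase the signal.

The assumptions, made explicit:

1. the backend generalizes across the baseline family (otherwise baseline
   images also score high — false positives);
2. the anomaly is not expressible by the backend (otherwise it is
   reconstructed — false negatives);
3. the optimizer actually finds a near-optimal latent (otherwise optimization
   failures masquerade as anomalies).

The synthetic benchmark is constructed so that 1 and 2 hold by construction,
which is precisely what lets it certify 3.

## The phantom backend

The bundled reference backend is an analytic renderer, not a trained
network: a soft-edged body ellipse plus three organ ellipses at fixed
anatomical stations (a bright liver-like organ left, a dark fluid-filled
organ right, a bright bone-like organ low and central). The image is

$$I(p) = \mathrm{clamp}\Big(bg + \sum_e (I_e - I_{below(e)})\,
  \sigma\big(\tfrac{1 - q_e(p)}{s}\big),\ 0,\ 255\Big),$$

with $q_e$ the ellipse quadratic form, $\sigma$ the logistic function and
$s$ the edge softness (default 0.08 in units of $q$, i.e. an edge a couple
of pixels wide at the default 64 × 64 size). Each latent coordinate lies in
$[0,1]$ and maps affinely onto a parameter box (centres, semi-axes,
intensities); the prior is uniform over the unit box. The boxes place each
organ in its own region, which keeps the parametrization identifiable —
interchangeable organs would make latent recovery a permutation problem the
optimizer cannot resolve.

What the phantom emulates: smooth anatomy with population variation,
organ-level intensity contrast, a body silhouette against air background, a
family that provably cannot express needles, peripheral fluid rims or global
intensity transforms. What it does not emulate: texture and noise, fine
anatomical detail, inter-slice variation, the perceptual failure modes of a
trained GAN (mode dropping, precision–recall trade-offs). Passing the
synthetic end-to-end benchmark therefore demonstrates that the *pipeline
machinery* — projection, scoring, subsampling, localization — behaves as
designed when its assumptions hold; it says nothing about whether a given
trained generator satisfies those assumptions on clinical data.

## Projection: the optimizer and why it is preconditioned

Projection minimizes pixel MSE on the [0, 255] scale by gradient descent
through `decode`, starting from the mean of 500 prior draws plus seeded
Gaussian jitter (SD 0.05 latent units). A plain scalar learning rate fails
here, by a wide margin: intensity coordinates move thousands of pixels at
once while an ellipse centre only moves its edge ring, so the loss curvature
across coordinates spans roughly three orders of magnitude. Any scalar step
stable for the stiff coordinates is uselessly small for the others, and a
step-size sweep never brought self-reconstruction below MSE ≈ 10² at 500
steps. The descent is therefore preconditioned with the Gauss–Newton
diagonal of the loss, $c_j = \tfrac{2}{N}\sum_p (\partial I_p / \partial
z_j)^2$, estimated by central finite differences of `decode` (step 1e-3,
refreshed every 25 steps, damped by 1e-4) so it works for *any* backend
satisfying the decode contract. The update uses only the current point — no
momentum, no gradient history — so the trajectory is a deterministic
function of backend, target and seed, and identical calls are bitwise
reproducible. The step schedule warms up linearly over the first 5 % of
steps and then decays with a half-cosine; the returned fit is the best
latent over all visited steps, which is robust to late-step oscillation.
Non-finite loss aborts with an error naming the step.

Under these settings self-reconstruction of in-prior phantoms reaches
machine-zero MSE within roughly 25–100 steps, which is why the package and
its tests use 200-step projections (500 in the convergence tests) rather
than a longer default.

## Scoring

MSE is the mean of squared per-pixel differences over the included pixels.
WD is defined as the 1-D Wasserstein-1 distance between the empirical
distributions of included pixel intensities — the quantile-function
formulation, which for equal pixel counts equals the mean absolute
difference of the two sorted intensity sequences. This is the definition
consistent with the metric's motivating property, spatial invariance:
scrambling pixel positions changes MSE but not WD, so WD forgives small
anatomical misregistration while still seeing intensity mass that appears
or disappears. Scores are computed on real-valued intensities; quantization
to 8 bits happens only at PNG write (round-half-up), avoiding
double-quantization bias.

Patch scoring tiles the image with `d × d` patches (stride defaults to `d`,
non-overlapping; overlapping strides are configurable), scores each patch
with the chosen metric, and takes the arg-max with a deterministic
tie-break: smallest row origin, then smallest column origin. When a body
mask is supplied, a patch is scored only if at least 50 % of its pixels are
inside the mask (configurable) — patches straddling the background would
otherwise win on silhouette mismatch alone. Coordinates are 0-based,
row-major, top-left origin; patches are half-open `[r, r+d) × [c, c+d)`.

## Body masks

Scoring can be restricted to the anatomy to remove the influence of
background and table. The recipe — Otsu threshold, morphological closing
with a 5-pixel disc, largest connected component, hole filling — is a
pragmatic stated default (all parameters configurable), implemented over
EBImage. There is no canonical body-mask algorithm at this image scale; any
recipe that covers the anatomy and excludes background serves, and the mask
is deliberately derived from the *original* image only, never the
reconstruction.

## Fréchet-distance contextualization

Backend fidelity is summarized by the squared Fréchet distance between
Gaussians fitted to image features. The matrix square root is computed by
eigendecomposition of the symmetrized product
$\Sigma_1^{1/2}\Sigma_2\Sigma_1^{1/2}$; eigenvalues above −1e-8 are clamped
to zero (beyond that tolerance a numerical-domain error is raised), the
result is clamped at zero, and covariance uses the n−1 denominator. Raw FD
values are not interpretable alone, so the protocol contextualizes them:
repeatedly halve the dataset at random (five repetitions by default) and
compare the baseline half-vs-half FD against halves where one side received
uniform Gaussian pixel noise (default SD 25 intensity units) or Gaussian
blur (default SD 2 pixels) — magnitudes chosen to be visually obvious
corruptions at 8-bit scale, and recorded in every report. Per-repeat seeds
are derived so that the halving stream is identical across conditions; a
zero-strength manipulation reproduces the baseline condition exactly.

Pretrained-network feature extractors are out of scope at desk scale; the
deterministic "radiomics-lite" extractor stands in: intensity mean, SD,
skewness, excess kurtosis, 256-bin histogram entropy (bits), the nine
deciles, foreground fraction (pixels above 10 % of the intensity scale) and
gradient-magnitude mean and SD — 17 features in total, all defined directly
on [0, 255] intensities. Degenerate inputs have defined values: a constant
image has zero SD, entropy and gradient features, and its skewness and
kurtosis are defined as 0. Any extractor with a fixed output length can be
plugged in through the same contract.

## Evaluation and statistics

AUROC uses the rank (Mann–Whitney) formulation with ties counted ½,
anomalous as the positive class. Class imbalance is handled by repeated
without-replacement subsampling of the baseline scores to the anomaly-set
size (50 repeats by default), reporting mean and sample SD. Localization
reports the proportion of images whose top-scoring patch overlaps the
ground-truth anomaly mask by at least one pixel (configurable), across
projection seeds 0–4; the one-pixel rule mirrors the convention that a
strong needle artifact counts as localizing the needle, and the synthetic
needle masks include the artifact streaks for the same reason.

The permutation test uses the difference of group means as its statistic —
the minimal choice for comparing mean AUROCs or proportions. When the
number of distinct label assignments is at most 10,000 the test enumerates
them exactly (the p-value then includes the observed split and can reach
1/total); otherwise it uses seeded Monte Carlo with the add-one estimator
$(1 + \#\mathrm{extreme})/(1 + B)$, which never returns exactly zero.
Floating-point ties in the permuted statistic are compared with a relative
tolerance of 1e-9. Power is estimated by simulating datasets from normal
distributions with the specified group means and SDs, running the
permutation test on each, and reporting the rejection fraction at the
chosen level; the direction of the one-sided alternative follows the sign
of the specified mean difference.

Across-repeat and across-seed SDs are sample SDs (n−1) throughout;
`summarize_dataset_mean()` reports both the sample and population
conventions because published summaries do not always state theirs.
Printed-precision comparisons round half-up.

## Problem sizes

The bundled benchmark uses 64 × 64 phantoms: 40 baseline-test images plus
40 images per anomaly class (needle, fluid rim, inverted), 200-step
projections, patch sizes {4, 8, 16} (the largest, 16, is a quarter of the
image side), AUROC over 50 subsamples, localization over seeds 0–4. Unit
tests use 32 × 32 phantoms and 100-step projections. Power analyses use
1000 simulated datasets with 1000-iteration permutation tests. These sizes
were chosen so that every stage's behaviour (convergence, separation,
calibration) is already unambiguous at this scale.

## Known limitations

- The phantom certifies the pipeline, not any particular trained generator;
  with a real backend, assumptions 1–2 must be re-established (e.g. with
  the FD contextualization protocol and reconstruction spot checks).
- WD's spatial invariance cuts both ways: an anomaly that only *rearranges*
  intensities (e.g. mirroring) is invisible to WD and needs MSE.
- The body-mask recipe assumes a single connected subject brighter than the
  background; it will mis-segment multi-object or inverted-polarity images
  unless given an explicit threshold.
- The DICOM reader intentionally covers single-frame little-endian
  grayscale only; multi-frame, color and compressed transfer syntaxes are
  rejected rather than guessed at.
- Projection cost scales linearly in steps × latent dimension (the
  preconditioner adds 2·dim decodes per refresh); very high-dimensional
  backends will want an analytic `decode_gradient` method, as the phantom
  provides.
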