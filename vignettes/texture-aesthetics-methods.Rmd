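---
title: "Modelling aesthetic perception of visual textures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aesthetic perception of visual textures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textureAesthetics)
```

## The problem

When people look at a visual texture — woven cloth, bark, brushed metal —
they form fast affective impressions (warm or cold, rough or smooth, dark
or light), slower aggregate judgments (harmonious, elegant, complex,
natural), and finally an overall liking. `textureAesthetics` implements a
complete computational pipeline for studying how such semantic-differential
ratings relate to low-level image structure:

1. a four-family **texture feature bank** (HSV colour statistics, gray-level
   co-occurrence statistics, Tamura descriptors, wavelet sub-band energies);
2. unsupervised **feature selection** by the Laplacian Score on a
   k-nearest-neighbour heat-kernel graph;
3. a **hierarchical feed-forward perception model** with three layers —
   affective `G(1..3)`, judgment `T(1..4)`, emotional `Q` — fitted by
   cross-validated forward selection over a term library with
   least-squares coefficients, plus the published reference equations for
   the eight antonym pairs;
4. a **synthetic-data module** that generates parametric textures and
   simulates the rating experiment from a planted hierarchy, so every stage
   is testable without the original stimuli or participants.

## The feature bank

All extraction starts from a `TextureImage` with pixel values on $[0,1]$
and at least $32 \times 32$ pixels (the study's stimuli were
$480 \times 480$; any size above the minimum is accepted).

**Colour (6 features).** The image is converted to HSV with all channels on
$[0,1]$ (hue = angle/360); the features are the means and population
standard deviations of H, S and V. Grayscale images are treated as
zero-saturation colour images.

**Co-occurrence (64 features).** Gray levels are quantized into 8 uniform
bins on $[0,1]$ (the quantization depth is configurable; 8 is the common
toolkit default and keeps the $8\times8$ matrices well populated). For each
offset in distances $d \in \{2,4,6,8\}$ crossed with orientations
$\theta \in \{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$ — 16 matrices — the
joint distribution $p(i,j)$ of gray-level pairs is formed symmetrically
(transpose counts added, then normalized; Haralick's statistics assume a
symmetric normalized matrix) and summarized by contrast, correlation,
energy and homogeneity. $45^\circ$ means the up-right diagonal offset
$(\Delta\text{row}, \Delta\text{col}) = (-d, +d)$, the dominant convention
in image-processing toolkits. For a constant texture both marginal standard
deviations vanish and correlation is *defined* as 1 — a constant texture is
perfectly predictable from itself — which avoids NaN contagion downstream.

**Tamura (3 features).** Coarseness follows the classical best-scale
procedure: window averages $A_k$ over $2^k \times 2^k$ neighbourhoods
($k \le k_{max} = 5$), horizontal/vertical differences between averages
separated by $2^{k-1}$, a per-pixel argmax scale, and the mean of
$2^{k^*}$ over the valid interior. Ties, and the all-zero-difference case
of a constant image, resolve to the finest scale ("fine unless evidence of
coarse"), so a constant image scores exactly 2. Scales whose neighbour
windows fit nowhere in the image are dropped from the per-pixel comparison;
this keeps images with sides in $[2^{k_{max}}, 2^{k_{max}+1})$ usable, and
only sides below $2^{k_{max}}$ are rejected. Contrast is
$\sigma / \alpha_4^{1/4}$ with $\alpha_4$ the kurtosis (0 for a constant
image). Directionality histograms Prewitt gradient orientations (16 bins
over $[0,\pi)$, gradient-magnitude threshold 0.1 on the $[0,1]$ intensity
scale) and measures the concentration of the histogram around its peaks;
an ideal single-orientation edge scores 1, a threshold-failing (flat)
image 0. The original formulation leaves all of these parameters open;
the defaults above follow the common re-implementations and every one is
an explicit argument.

**Wavelet (36 features).** A decimated 2-D Daubechies-4 transform with
half-sample symmetric extension is applied to 4 levels; each of the 12
high-frequency sub-bands contributes its per-coefficient $L^1$ and $L^2$
norms and the Shannon entropy of the normalized coefficient energies.
Per-coefficient (rather than raw-sum) norms make the features comparable
across resolutions. The transform was validated coefficient-for-coefficient
against an independent reference implementation; frozen values guard it in
the test suite. Note that a decimated transform is not shift-invariant:
sub-band energies of the same texture can change by tens of percent under
odd pixel shifts. That is a property of the descriptor, not a bug, and the
translation-stability test therefore shifts by a multiple of
$2^{\text{levels}}$.

The full bank is $6 + 64 + 3 + 36 = 109$ features. (The component counts
are documented family by family; all 109 are always emitted — none are
silently dropped to match any externally quoted total.) Any non-finite
value aborts extraction naming the offending feature.

## Feature selection

Features are min–max scaled to $[-1,1]$ per column (constant columns map
to 0; the scaling parameters are stored for reuse on new textures) before
graph construction, so Euclidean distances are commensurate. The affinity
graph connects each texture to its $k = 5$ nearest neighbours (distance
ties at the k-th neighbour are all kept, so duplicated samples stay
connected), symmetrises by union, and weights edges with
$S_{ij} = \exp(-\|x_i-x_j\|^2/t)$, where $t$ defaults to the mean squared
distance over the graph's edges — a standard self-tuning choice.

The Laplacian Score of feature $r$ is
$L_r = \tilde f_r^T L \tilde f_r \,/\, \tilde f_r^T D \tilde f_r$ with the
degree-weighted mean removed. Constant features receive a sentinel (`NA`)
and always rank last. The importance direction is configurable; the
default treats **higher scores as more important**, matching the published
feature table in this application area, where the retained features carry
the largest scores. The default working subset is the top 10.

## The perception model

Each property model is an intercept plus weighted terms over its layer's
inputs: 10 selected features for the affective layer, those plus the 3
affective properties for the judgment layer (13 inputs), and everything
below for like-dislike (17 inputs). The acyclicity of the hierarchy is
enforced by the class validity.

The **reference model** transcribes the eight published equations
verbatim, including the rough-smooth slope of $-1.31\times10^{-13}$, which
makes that property effectively constant at its intercept $-1.73$; it is
kept exactly as printed. The dark-light equation is the only non-linear
one (one product, one square). The reference equations expect features
scaled to $[-1,1]$; the original scaling parameters were never published,
so the reference model carries no scaling metadata and callers must supply
features already on that scale.

The **fitter** replaces a proprietary symbolic-regression product with a
documented procedure that matches the published account of its outcome
(weighted combinations of library terms with least-squares coefficients):

* a deterministic term library — variables, squares, pairwise products,
  and optional unary transforms (`sqrt`, `log`, `exp`, `sin`, `cos`,
  `tan`, applied only where domain-valid; division is excluded by default
  because it invites singularities and the published models use none);
* greedy forward selection maximizing mean cross-validated $R^2$
  (5 folds, seeded), stopping at `minGain` ($10^{-3}$) or `maxTerms` (8);
* an **F-to-enter guard**: the winning candidate must also pass a
  Bonferroni-corrected partial F-test on the training fit
  ($\alpha = 0.05/\text{library size}$). The guard exists because the best
  of many candidates capitalizes on CV noise: with a pure-noise response
  the best mean CV gain among even a handful of candidates exceeds
  $10^{-3}$ in most runs, while the familywise F-guard keeps the model at
  intercept-only about 95% of the time. Genuine terms have F-statistics
  orders of magnitude above the threshold;
* a **swap pass** when forward steps stall (exchange one chosen term for
  one candidate when training $R^2$ improves by `minGain`), which lets the
  search escape basins where no single addition helps without growing the
  model;
* **backward pruning** (drop terms whose removal costs less than `minGain`
  of training $R^2$) so proxy terms picked en route on correlated features
  do not survive;
* final coefficients by OLS on all training data, with rank-deficient
  terms dropped with a warning.

Preprocessing before fitting is per-variable z-scoring with $|z|>3$ sample
removal (a documented stand-in for an unspecified "outliers removed"
step; there is no smoothing because textures are unordered), then the
min–max scaling above. The hierarchy is fitted the way the original
experiment was analysed: judgment models see the *observed* affective
ratings and the like-dislike model the observed values of both lower
layers; predictions are only cascaded at prediction time, where observed
values can override any layer.

Evaluation reports $R^2 = 1 - SS_{res}/SS_{tot}$, Pearson's $r$, RMSE, the
**basic complexity** (number of non-intercept terms — the interpretability
measure) and an **enhanced complexity** (weighted expression-tree size:
variable/constant 1, add 1, multiply 2, power 2, unary transform 3) that
approximates symbolic-regression size metrics and is reported for
orientation only. Because CV-based $R^2$ can mean "held-out-fold" or
"refit-training" depending on convention, fitted models carry both
(`cvR2` and `trainR2` in the fit metadata).

## The synthetic-data module

`generateTexture()` produces gratings, checkerboards, Gaussian-filtered
noise and HSV colour patchworks — controllable coarseness, contrast,
orientation and colour. These are deliberately simple stand-ins for
photographic texture databases: they do not model natural-image statistics,
global illumination, or semantic content, so passing tests demonstrate the
pipeline's correctness, not that the published human results replicate on
real stimuli.

`simulateRatings()` implements the experiment design: 20 raters × 5
repetitions per texture (100 raw ratings), each raw rating = planted
cascade value + per-rater additive bias (Gaussian, sd 2) + per-rating
noise (Gaussian, sd 5), clipped to $[-100,100]$ as a bounded scrollbar
would, then averaged. Rater effects are additive only — the simplest
structure consistent with averaging. The published study gives no
distributional description of its ratings; these noise levels are design
choices of the simulator, not estimates.

`plantHierarchy()` draws sparse linear hierarchies: 5 feature terms per
affective model, 3 feature + 2 lower-layer terms per upper model, feature
coefficient magnitudes uniform on $[8,20]$, lower-layer magnitudes on
$[0.2,0.6]$, intercepts on $[-10,10]$. Two considerations fix these
defaults. First, with features on $[-1,1]$ they keep cascade values
several standard deviations inside the rating range, so clipping is rare
(a clipped texture bends the otherwise-linear relation and would
contaminate exact-recovery tests). Second, coefficient recovery in a
layered linear model is subtle: an affective property is itself a linear
function of the features, so a judgment model's data cannot fully
distinguish $\gamma \cdot G$ from $\gamma$ times G's feature expansion.
Recovery is therefore assessed on the **feature-space reduced form**
(`reducedFormCoefficients()`), which is invariant to that substitution and
is the object the model class actually identifies.

`makeBenchmarkDataset()` chains everything: parametric textures spanning
all four kinds, extraction, scaling, Laplacian-Score ranking, selection of
the top 10 **mutually distinguishable** features (features whose absolute
correlation with an already-kept feature exceeds 0.95 are skipped — the
bank contains near-duplicates, e.g. co-occurrence contrasts at adjacent
distances correlate above 0.99, and a hierarchy planted on one of two
nearly collinear columns is not identifiable from data), a planted
hierarchy, and the simulated experiment.

## Problem sizes and recovery studies

The test suite runs its recovery studies at these sizes, chosen so that
each study completes in seconds while leaving the statistical conclusions
unambiguous:

* zero-noise end-to-end benchmark: 60 textures of $128\times128$ pixels;
* noisy recovery: 50 repetitions of 150 textures with independently drawn
  uniform $[-1,1]$ feature matrices (a well-conditioned design, so failures
  indicate fitter defects rather than accidental collinearity), rating
  noise sd 5, rater bias sd 2, the full 20 × 5 averaging design.

Recovery studies configure the fitter with a linear-only library (the
planted truth is linear; a separate unit test covers interaction-term
recovery), `maxTerms = 12` headroom so the search may wander through
substitutions and prune back, and the F-guard disabled — on noise-free
data every true term should enter regardless of the size of its marginal
evidence, and under the averaged design the effective noise
(sd $5/\sqrt{100} = 0.5$) leaves true-term evidence far above any
plausible threshold. For the zero-noise study the stopping tolerance is
tightened to $10^{-9}$ because exact recovery requires the tolerance to
sit below the smallest planted contribution.

Under these conditions the zero-noise benchmark recovers the planted
reduced form to machine precision and the noisy study recovers it within
10% (infinity-norm relative to each property's coefficient scale) in well
over 90% of repetitions.

## Numerical conventions and degenerate inputs

* Quantization assigns intensity 1.0 to the top bin (closed upper edge).
* A GLCM offset with no valid pixel pair is an error, not an empty matrix.
* Wavelet detail coefficients below $10^{-12}\times$ the input scale are
  flushed to zero so that analytically-zero sub-bands (constant regions)
  report exact zeros for $L^1$, $L^2$ and entropy.
* An all-zero sub-band has entropy 0 by convention; entropy is bounded by
  $\log_2 N$.
* Constant observed vectors make $R^2$ and $r$ undefined; they are
  reported as `NA` while RMSE is still computed.
* Model JSON stores numbers at full precision; save/load round trips are
  lossless and byte-reproducible for a fixed config and seed.

## Known limitations

* The synthetic textures are far simpler than photographic stimuli; real
  feature distributions are heavier-tailed and more collinear.
* The published study's headline goodness-of-fit table was computed on a
  proprietary 151-image set with human ratings and cannot be recomputed
  here; the package reproduces the printed equations, their structural
  properties and the pipeline mechanics, and validates the statistical
  machinery on synthetic ground truth instead.
* The decimated wavelet transform is phase-sensitive; studies requiring
  shift-invariant energies should average features over small shifts.
* The fitter's term library is quadratic in the number of inputs; with
  many more than the default 17 inputs the forward search cost grows
  accordingly.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
bench <- makeBenchmarkDataset(nTextures = 30, seed = 1, size = 64)
fit <- fitHierarchy(bench$selected, bench$ratings,
                    fitConfig(squares = FALSE, products = FALSE, seed = 2))
evaluateHierarchy(fit, bench$selected, bench$ratings)

# the published equations, and a prediction with observed lower layers
h <- referenceModel()
predictCascade(h, rep(0, 10))
predictCascade(h, rep(0, 10), overrides = list(G = c(0, 0, 0)))
```
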