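---
title: "Counterfactual attribution ratios for two-stage retinal image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual attribution ratios for two-stage retinal image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusCAR)
```

## The model

fundusCAR implements a two-stage screening classifier for retinal fundus
images together with the attribution machinery that makes the second stage
interpretable.

**Stage 1 (findings).** For each abnormal finding $f$ (hemorrhage, hard
exudate, drusen, ...), a branch of the encoder produces a spatial feature
map $g_f(x) \in \mathbb{R}^{C \times H' \times W'}$; global average pooling
gives $\bar z_f \in \mathbb{R}^C$, and a linear head scores the finding:
$\hat y_f = \sigma(w_f^\top \bar z_f + b_f)$.

**Stage 2 (diseases).** Each disease head is a linear classifier over the
concatenation of all pooled finding features:
$\hat y_d = \sigma\!\left(\sum_f v_{d,f}^\top \bar z_f + c_d\right)$.
Because the map from finding features to disease logits is linear, the
contribution of each finding block can be isolated exactly — this is the
property the whole attribution framework rests on.

## Counterfactual attribution

The pooled feature of finding $f$ decomposes about the head's unit weight
direction $\hat w_f = w_f / \lVert w_f \rVert$ as
$\bar z_f = p\,\hat w_f + \bar z_{f,\perp}$, with
$p = \hat w_f^\top \bar z_f$.  For a unit-norm head
$p = \sigma^{-1}(\hat y_f) - b_f$: moving $p$ moves the finding score and
nothing else that the finding head can see.

The *counterfactual latent* replaces $p$ so that the finding score becomes
a small $\epsilon \in (0, 1/100)$ — the feature vector the image would
have had, had the finding been confidently absent — leaving the orthogonal
component untouched.  Writing $\mathcal{O}(d;x)$ for the disease odds
$\hat y_d / (1 - \hat y_d)$ and $\mathcal{C}(f,d;x)$ for the odds after
substituting the counterfactual latent, the instance-level attribution
ratio is

$$R_{I\text{-}CAR}(f,d;x) = \frac{\mathcal{O}(d;x)}{\mathcal{C}(f,d;x)}
 = \exp\!\big((\sigma^{-1}(\hat y_f) - \sigma^{-1}(\epsilon))\,
              v_{d,f}^\top \hat w_f\big),$$

and replacing $\hat y_f$ by $1 - \epsilon$ gives the instance-free CAR

$$R_{CAR}(f,d) = \exp\!\big((\sigma^{-1}(1-\epsilon) -
  \sigma^{-1}(\epsilon))\, v_{d,f}^\top \hat w_f\big)
 = \exp\!\big(-2\,\sigma^{-1}(\epsilon)\, v_{d,f}^\top \hat w_f\big),$$

an odds-ratio-scale quantity directly comparable to the pooled odds ratio
of expert annotations (`pooledContingency()` / `oddsRatio()`).  The
attribution activation map
$A(f,d;x) = (v_{d,f}^\top \hat w_f)\,(w_f^\top g_f(x))$ localizes the
contribution spatially; its spatial mean equals
$(v_{d,f}^\top \hat w_f)(\sigma^{-1}(\hat y_f) - b_f)$ by linearity of
pooling, an identity the test suite checks on random instances.

Because overriding a finding score only moves $p$, a reader's interactive
adjustment (`interactiveAdjust()`) re-evaluates every disease head without
an encoder pass and agrees exactly with full recomputation.

### Conventions and numerical choices

* **Weight norm.** The decomposition identities are exact for unit-norm
  finding heads, so `modelBundle()` rescales $w_f$ to unit norm by default
  (bias kept; scores change only by a logit rescaling, leaving rank
  order and AUROC untouched).  With `normalize = FALSE` the engine divides
  the coupling by $\lVert w_f \rVert$ internally, so the odds identities
  hold for any norm; `coupling()` always reports the unit-direction form
  $v_{d,f}^\top \hat w_f$.
* **Epsilon.** Default $\epsilon = 0.005$, the midpoint of the permitted
  interval.  `selectEpsilon()` also supports the benign-percentile policy
  (nearest-rank 5th percentile of finding predictions on benign cases),
  clipped into $(0, 1/100)$ with a warning.  The same $\epsilon$ is used
  in the counterfactual latent and in the "present surely" arm
  ($1 - \epsilon$).
* **Clipping.** Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$
  before logits; clamping emits a message.
* **Display rule.** The interactive report lists at most 3 findings whose
  instance-level I-CAR exceeds the natural constant $e$.  The threshold is
  applied to I-CAR (instance-level reading is what a per-image display
  needs); applying it to the instance-free CAR instead would make the
  listing image-independent.

## Label fusion

Training targets come from three independent readers per image.  Readers
are modeled as conditionally independent given the truth, each with a
per-label sensitivity and specificity (a binary Dawid–Skene model).
`naiveBayesPosterior()` computes $\Pr(Y = 1 \mid \hat y_{1..A})$;
`emEstimate()` alternates that E-step with posterior-weighted M-step
estimates of prevalence and reader profiles until the largest parameter
change falls below `tol` (default $10^{-6}$).  Choices:

* initialization from majority-vote pseudo-labels — deterministic, avoids
  label switching in practice; if EM still lands in the mirrored solution
  (average sensitivity + specificity below 1) it is re-anchored by
  flipping the latent class, and the fit is flagged;
* each label is fit independently (labels are treated as independent);
* profiles are estimated per reader id across all images that reader read;
* the observed-data log-likelihood trajectory is returned and is
  non-decreasing, which the tests assert.

Ordinal panels (DR below referable DR; BRVO below CRVO; dry below wet
AMD) are first recoded by `severityRecode()`: a reader marking severity
$s$ asserts every label of severity at most $s$.  Evaluation reference
labels use the conservative `referenceStandard()` rule — majority
positive, unanimous negative, lone positive excluded — which applies only
to validation/test reference sets, not to training targets.

## Training the heads

Only the linear heads are trained (`trainFindingHeads()`,
`trainDiseaseHeads()`); the encoder stays frozen.  The objective is mean
binary cross-entropy (soft targets from label fusion enter directly) plus
$\lambda \lVert w \rVert^2$ with $\lambda = 5\times10^{-4}$.  The
optimizer is deterministic full-batch gradient descent with a
backtracking line search, converging when the relative loss change drops
below $10^{-7}$; the recorded loss checkpoints are non-increasing by
construction.  Predictors are standardized internally and the penalty
applied on the standardized scale with an unpenalized intercept (the
glmnet convention), then folded back to raw-scale coefficients —
otherwise a fixed $\lambda$ would mean nothing against arbitrary feature
scales.  `balancedBatches()` provides the class-balanced sampler (equal
expected positives and negatives per batch) for users who want
mini-batch training at realistic prevalences.

## The synthetic study

`toyGeneratorSpec()` fixes the study conditions: 64 px fundus-like discs,
$F = 3$ findings with distinct lesion blob signatures (dark-red
hemorrhage blobs, yellow hard-exudate dots, pale drusen deposits),
$D = 2$ diseases linked to findings through a logistic model with
coefficients $\pm 3$ on truly-driving pairs, $C = 8$ feature channels,
Gaussian feature noise 0.3, finding prevalences 0.3/0.25/0.2, and a
three-reader panel with sensitivities (0.9, 0.8, 0.7) and specificities
(0.95, 0.9, 0.85).  Signature intensities are chosen so every color plane
stays inside $[0,1]$ on the shaded disc: out-of-gamut clipping would mix
lesion colors nonlinearly and leak one finding's signal into another's
detection channel.  All generators are pure functions of (spec, seed).

The toy encoder replaces the large pretrained trunk that a production
system would use.  It is fixed, not trained: a mean-pooling pyramid
(preserving color planes), then one branch per finding consisting of that
lesion's *linear spectral-unmixing filter* — the pseudo-inverse row that
responds to its own lesion color and nulls the others — followed by
frozen normalization calibrated on probe images (per-location background
subtraction and a global scale, the role batch normalization plays in a
trained network) and a bank of amplitude-band detection channels
(band edges 0.5–8 on the normalized scale; disjoint bands keep the
within-block features well conditioned).  This hand-designed
specialization stands in for what per-finding training achieves in a real
system: each feature block carries information about its own finding
only, which is what makes the disease head's block decomposition — and
hence the CAR grid — identifiable.

**What passing tests do and do not show.**  The generator exercises every
code path: lesion rendering, encoding, fusion, head training, attribution,
evaluation.  It does *not* emulate photorealistic fundus texture, camera
variation, ungradable images, reader correlation, or findings whose color
signatures are not linearly separable — so end-to-end results here
demonstrate correctness of the machinery, not clinical performance.  At
the default desk scale (2000 images, 1600 train / 400 held out, probe
calibration on 300 images) the test suite verifies per-finding held-out
AUROC of at least 0.95 and 100% agreement between CAR signs and generator
coefficient signs on the $|\beta| = 3$ pairs.

## Evaluation utilities

`auroc()` is the Mann–Whitney pair statistic (ties count one half),
`clopperPearson()` the exact Beta-quantile binomial interval, and
`chooseOperatingPoint()` scans score midpoints for the maximizer of the
harmonic mean of sensitivity and specificity (ties broken toward higher
specificity, the screening convention) or returns the largest threshold
meeting a target sensitivity — the rule for rare-positive labels.
Exact binomial intervals are provided for sensitivity and specificity;
applying them to AUROC is not supported, since AUROC is not a binomial
proportion.  `cosineBranchAnalysis()` reproduces the branch-point
diagnostic for shared-encoder architectures: mean pairwise cosine
distance between findings' pooled features per layer, with the suggested
branch point just before the distance first rises by more than a
configurable margin (default 0).

## Known limitations

* CAR magnitudes inherit the calibration of the heads: with nearly
  separable toy data the finding logits, and hence $\log R_{CAR}$, are
  large.  Signs and orderings are the meaningful quantities at desk scale.
* Couplings on truly-null finding-disease pairs are fit noise along
  nearly flat likelihood directions; with $n = 2000$ and
  $\lambda = 5\times10^{-4}$ their $|\log R_{CAR}|$ is not reliably below
  the matched pairs' minimum, so the package reports the ordering
  (`groundTruthCar()$nullBelowMatched`) but the tests do not assert it.
* The EM fusion assumes conditional independence of readers; correlated
  readers (e.g. shared training) bias the recovered profiles.
* `preprocessImage()` centers content by its crop bounding box; no fovea
  detector is included, and laterality is accepted only as metadata.
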