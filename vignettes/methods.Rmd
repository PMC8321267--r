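---
title: "Methods: adversarial domain translation for macroscopic lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial domain translation for macroscopic lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dermoscopes reveal subsurface skin structure under polarized, contact
illumination; the resulting image collections are large and well annotated.
Macroscopic images — lesions photographed with an ordinary or phone camera —
are what a mobile triage tool actually sees, but few annotated sets exist.
The two modalities differ systematically: dermoscopic images carry pigment
networks, diffuse borders, and acquisition artifacts (dark circular corners
from the scope's field of view, immersion gel, ruler markings), while
macroscopic images show specular glare, warmer ambient skin tones and
apparent depth. `derm2macro` implements a pipeline that learns an unpaired
translation between the two domains and uses the translated dermoscopic
images as augmentation for a macroscopic lesion segmenter, together with
the evaluation stack needed to judge both stages.

## The translator

Two mapping functions are trained jointly: G : X → Y (dermoscopic →
macroscopic) and F : Y → X, with patch discriminators D_X and D_Y. The
domain binding of the symbols is a package convention (the roles are
otherwise symmetric): G's outputs are the "TransMacro" images, F's the
"TransDermo" images.

The objective is

L(G, F, D_X, D_Y) = L_GAN(F, D_X, Y, X) + L_GAN(G, D_Y, X, Y) + λ · L_cyc(G, F)

with λ = 10. The adversarial term is sigmoid cross-entropy of the
discriminator's patch map against an array of ones; the cycle term is the
mean absolute error of both reconstruction directions (an image translated
to the other domain and back should be comparable to the original). An
optional identity-mapping L1 term is available with weight 0 by default:
descriptions of an extra per-pair L1 generator term are ambiguous for
unpaired data, so the closest standard construction (the identity loss)
is exposed but disabled.

Architecture follows the residual style-transfer generator: an encoder of a
reflection-padded 7×7 stride-1 convolution and two 3×3 stride-2
convolutions (instance norm + ReLU each), a transformer of twelve residual
blocks by default (configurable), and a decoder of two 3×3 stride-2
transposed convolutions plus a reflection-padded 7×7 output convolution
with tanh. Discriminators are PatchGANs: five 4×4 stride-2 convolutions
with instance norm and leaky ReLU (slope 0.2) between layers and a sigmoid
patch map, so a 64-px input yields a 2×2 grid of patch probabilities.

Training follows the standard unpaired-translation protocol: batch size 1,
Adam (learning rate 2·10⁻⁴, β₁ = 0.5), weights initialised from a Gaussian
with mean 0 and standard deviation 0.02 (the convention of the original
translation protocol), and a 50-image history pool for discriminator
updates, whose loss (real-vs-ones + pooled-fake-vs-zeros) is halved. No
learning-rate decay is applied: decay schedules matter over hundreds of
epochs, and the package's default runs are far shorter. Stopping is either
the epoch cap or a programmatic stand-in for "generator loss
stabilisation": the relative spread of the generator loss over a 10-epoch
window falling below 2%. Reflection padding before the 7×7 convolutions
and instance-norm epsilon 10⁻⁵ follow the cited generator design.

## The segmenter

The segmenter is a reduced mobile encoder–decoder: a MobileNetV2-style
inverted-residual backbone whose stage widths are all scaled by a width
multiplier α (default 0.35, minimum width 4), an atrous spatial pyramid at
output stride 16 with dilation rates 6/12/18, low-level (stride-4) feature
fusion, and a 1×1 convolution head whose logits are bilinearly upsampled
and passed through a sigmoid — the appropriate head for binary
segmentation. Normalisation is instance norm throughout (the package
trains with very small effective batches, where batch statistics are
unreliable).

Training uses the soft Dice loss, `1 − (2Σpt + s)/(Σp + Σt + s)` with
smoothing constant s = 1, batch size 4, an internal 90/10
train/validation partition, and Adam with a triangular cyclic learning
rate. The cited cyclic-LR method prescribes no bounds; the package
defaults to (10⁻⁴, 3·10⁻³) with a half-cycle of 4 epochs. Lower bounds
such as (10⁻⁵, 10⁻³) were found to underfit badly at desk scale (32
images, 64 px, 20 epochs reach only ~0.63 validation Dice versus ~0.90
with the defaults), and the bound is exposed in the configuration for
larger runs. The best-validation-Dice checkpoint is returned, not the
final epoch.

Classic augmentation applies flips and transposition identically to image
and mask (the bookkeeping is asserted by tests rather than any
equivariance of the network, which would not hold), and brightness,
contrast, saturation, hue rotation about the gray axis, and Gaussian noise
to the image only, so masks stay binary. The binarisation threshold for
prediction is 0.5 by default and exposed, since no canonical value is
established.

## Evaluation

**Fréchet distance.** Image sets are embedded, a Gaussian (μ, Σ) is fitted
per set (sample covariance, denominator n − 1), and the distance is
`||μ_a − μ_b||² + Tr(Σ_a + Σ_b − 2(Σ_a Σ_b)^{1/2})`. The matrix square
root uses the symmetrised `Σ_a^{1/2} Σ_b Σ_a^{1/2}` form via
eigendecomposition with negative eigenvalues clamped to zero — rank
deficiency is the normal case when few images are embedded — plus an
optional diagonal jitter (default 10⁻¹²; kept tiny so analytic cases are
reproduced to near machine precision, which a fixed 10⁻⁶ jitter would
spoil). The default embedder is a fixed-seed random linear projection of
the 16×16-downsampled image to 64 dimensions: deterministic, dependency
free, and — being linear in pixels — directly sensitive to the cues the
synthetic domains differ in (corner darkness, glare, skin tone). An
adapter for a pretrained deep embedder can be supplied as any function
mapping an image to a fixed-length vector; absolute distances are embedder
specific, which is why comparisons are always made within one embedder and
summarised by the **Variation Ratio** `VR = (reference − value)/reference`
(reported at two decimals, rounded half away from zero). Positive VR means
translation moved the distributions closer.

**Segmentation metrics.** Per image: JA = TP/(TP+FP+FN),
DI = 2TP/(2TP+FP+FN) (identically 2·JA/(1+JA)), accuracy, sensitivity,
specificity; aggregates are per-image means (a pooled-pixel mode is
available — the choice between the two is not canonical, and the per-image
mean matches the thresholded Jaccard's inherently per-image definition).
TJA zeroes each per-image JA below 0.65 before averaging. Conventions the
reference material never encounters are fixed and documented: an image
where both masks are empty scores JA = DI = SE = 1; SP = 1 when no true
negatives are possible. Normalized FP/FN rates divide per-image error
pixels by the ground-truth foreground area (a total-pixel normalizer is
available; the published normalizer is unstated, and foreground-relative
rates are the interpretation under which the published values are
plausible for lesions occupying a minority of the frame). Overlays use the
bit-exact color table yellow = TP, red = FP, green = FN, black = TN.

## The synthetic domains

The generator exists so that every downstream stage is testable without
restricted clinical data. Lesions are star-convex radial functions
r(θ) = radius + Σᵢ aᵢ cos((i+1)θ + φᵢ) — the simplest family with
irregular, diffuse-looking borders — rasterised with a 1-px anti-aliasing
band, filled with a pigment-like dark color and a thresholded
smoothed-noise mesh evoking pigment networks. Dermoscopic renders may add
dark circular corners (field-of-view vignette to luminance < 0.1), a local
gel-blur patch and ruler ticks; macroscopic renders use a warmer skin
tone and may add additive Gaussian glare blobs (clipped at 1, peak
luminance > 0.9) and a signed depth-shading gradient across the lesion.
The two artifact families never cross domains, which makes the domain gap
learnable at smoke scale: with per-domain artifact probabilities of 1 the
domains are linearly separable under the toy embedder. Artifact prevalence
in real collections is not quantified anywhere, so the default
probabilities (0.7 dark corners, 0.2 gel/ruler; 0.7 glare, 0.5 depth) are
free choices meant to look like "most but not all images carry the
modality's artifacts". What the generator does **not** emulate: hair,
vasculature, multi-class disease appearance, camera noise, resolution
differences, or color calibration of real devices — so passing smoke tests
demonstrates the machinery learns and evaluates correctly, not clinical
performance.

## Problem sizes and numerical choices

Default experiment scales are desk scale by design: 32–64 px images, 8–32
images per domain, tens of epochs; every knob scales to the reference
setting (512 px, α = 0.35, up to 1000 epochs) by configuration. The smoke
properties asserted by the acceptance tests use: translator — 16 images
per domain at 32 px, base width 8, 2 residual blocks, 30 epochs, 5 seeds
(the translated set must approach the macroscopic domain, VR > 0, in at
least 4); segmenter — 32 high-contrast lesions at 64 px, 20 epochs
(validation Dice must improve and exceed 0.8); pipeline — two runs of the
full two-arm experiment must produce byte-identical reports. All
randomness flows from one root seed through named substreams
(`derive_seed`), so stages are reproducible yet decoupled; R's default
generator is used throughout and no global RNG state leaks out of library
calls. Degenerate inputs are errors, not silent recoveries: empty domains,
missing masks, non-finite losses (aborted with a stage-tagged diagnostic),
images outside the declared value range, crop boxes out of bounds, and
lesion specs whose foreground leaves (0.5%, 65%) of the frame.

## Known limitations

The conv engine is plain R over BLAS matmuls: fine for smoke scale,
roughly two orders of magnitude from framework speed at 512 px. Batch size
1 training (translator) and per-sample gradient accumulation (segmenter)
are exact but unvectorised across a batch. The toy embedder is linear, so
FID values are not comparable to deep-embedder FIDs in magnitude — only
ratios (VR) are meaningful across embedders. Mask transport through
translation assumes style-level translation (geometry preserved), which
holds architecturally (no spatial resampling in the generators) but is not
re-verified per image.
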