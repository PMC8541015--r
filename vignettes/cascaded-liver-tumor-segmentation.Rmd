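---
title: "Coarse-to-fine liver and tumor CT segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine liver and tumor CT segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeseg)
```

## The problem

Contrast-enhanced abdominal CT is the standard modality for liver-lesion
assessment. Segmenting the liver and its tumors is hard for two compounding
reasons: extreme class imbalance (tumor pixels are often well under 1% of a
slice) and the variable morphology of lesions — single large masses, small
subtle foci, or many scattered nodules. `cascadeseg` implements a two-stage,
coarse-to-fine convolutional pipeline for this task, together with the
preprocessing, loss, metrics, synthetic phantoms and command-line tooling
needed to exercise it end to end on a single CPU.

## The model

**Stage 1 (coarse).** A U-Net: a contracting path of paired 3x3
convolutions with rectification and 2x2 max pooling (channels double at each
descent), an expanding path of 2x2 transposed convolutions (channels halve)
with skip concatenation and paired 3x3 convolutions, and a final 1x1
convolution to three class logits. With the default depth of 4 and base
width 64 the network has exactly 23 convolutional layers. All 3x3
convolutions use "same" padding so a 512x512 slice yields a 512x512 map;
softmax over the three mutually exclusive classes (background, liver, tumor)
gives the coarse probability map.

**Fusion.** The summed foreground probability (liver + tumor) is added
elementwise to the min-max-normalised input slice, keeping a single channel.
This is the simplest additive fusion consistent with a one-channel second
stage; concatenation as a second channel is the obvious alternative and was
deliberately not taken so both stages consume the same input format.

**Stage 2 (fine).** The fused map is presented at three resolutions (native,
1/2, 1/4 — 512/256/128 at full scale). Each branch applies a 3x3 stem
convolution, an *ADense block*, and multi-layered channel attention; branch
features are bilinearly up-sampled to native resolution, summed, and a final
convolution plus softmax emits the refined map.

The **ADense block** applies dense connectivity to the dilated convolutions
of atrous spatial pyramid pooling: layer *i* receives the block input
concatenated with all previous layer outputs (so its input width is
`C + (i-1) * growth_rate`), applies a 3x3 convolution at dilation
`dilation_rates[i]`, and the final concatenation is projected back to `C`
channels by a 1x1 convolution. Default rates are (1, 3, 6, 12): strictly
increasing for multi-scale context, and all far below 24, beyond which a
dilated kernel samples too sparsely to be useful. The stacked receptive
radius is 1+3+6+12 = 22 pixels, which the test suite verifies on impulse
inputs.

**Multi-layered channel attention.** Three convolutions of kernel size 1, 3
and 5 form three branches. Each branch's features are pooled globally (max
and average) into channel descriptors; both descriptors pass through one
shared K-length 1-D convolution across the channel axis (K = 3 by default,
the smallest odd kernel that mixes neighbouring channels), are summed, and a
sigmoid produces per-channel weights in (0, 1) that rescale the branch.
The three calibrated branches are summed. The sharing scope of the 1-D
kernel is not dictated by the architecture description; this implementation
uses one kernel per attention module, shared across both pooling paths and
all three branches — the most parsimonious reading.

**Activation placement.** Rectification follows every convolution that
produces features: the stem, each dense dilated layer, the block's 1x1
projection, and the attention branch convolutions (the 1-D channel
convolution feeds a sigmoid instead, and the final classifier convolution is
linear before the softmax). The architecture description leaves these
placements open; with a purely linear projection-plus-attention tail the
fine stage optimises markedly worse in desk-scale experiments, so the
standard convention — rectify every internal convolution — was adopted.

## The loss

Class-weighted cross-entropy
`L = -(1/N) * sum_i sum_c w_c * 1[y_i = c] * log p_ic`, with per-class
weights from the *adaptive* rule `w_c = 1 / ln(t + P_c)` where `P_c` is the
class's pixel proportion in the training masks and `t = 1.02`; weights are
clipped to the closed interval [1, 50]. An absent class hits the upper
clamp (1/ln 1.02 ~ 50.5 -> 50); a saturated class gets 1/ln 2.02 ~ 1.42.
Weights are computed once from the training split before training — they
adapt to the dataset's imbalance, not to each batch (a per-batch variant
would make the objective nonstationary). `N` counts pixels in the batch, the
natural logarithm is used throughout, and a floor of 1e-12 inside the
logarithm keeps degenerate predictions finite.

## Training protocol

The package defaults mirror the reference protocol: 300 epochs per stage,
Adam with a constant learning rate of 1e-4, and `alpha = 0.33`. Training is
sequential: the coarse net is trained, then frozen; its probability maps are
fused with the inputs once, and the fine net is trained on those fused
multi-resolution inputs. `alpha` only enters the optional joint fine-tuning
phase, whose objective is `alpha * L_coarse + (1 - alpha) * L_fine`; the
fused prior is treated there as a constant input of the fine stage, so no
gradient crosses the stage boundary. This is one concrete reading of a
loosely specified coupling constant; it is constant during training (the
"initialised" phrasing may hint at scheduling, which is not implemented).

All tensor operations (dilated/transposed convolution, pooling, bilinear
resampling) are compiled kernels driven from R, with im2col + GEMM
convolutions; both networks' backward passes are verified against central
finite differences in the test suite.

## Preprocessing

Raw scanner values convert to Hounsfield units via
`HU = pixel * slope + intercept`. Slices are windowed to (-200, +250) HU —
a standard liver window that retains parenchyma and hypodense lesions while
clipping air and bone; the reference description does not state its window,
so this default is configurable. Gaussian denoising uses sigma = 1 pixel,
kernel truncated at radius 3*sigma, with half-sample reflective borders
(chosen so the smoothing operator is doubly stochastic and preserves the
global mean exactly). All-background slices are removed from training sets;
slices export to 8-bit PNG with the window mapped linearly to [0, 255], and
label masks store raw values {0, 1, 2} so round-trips are bit-exact. NIfTI
volumes are sliced along the last (axial) storage axis without
reorientation.

## Tumor-pattern stratification

Evaluation stratifies cases into three morphological patterns: *multiple*
if the tumor pixels form two or more 8-connected components (this rule takes
precedence), otherwise *large* when the tumor-to-liver pixel ratio exceeds
10% and *small* otherwise. The denominator counts the whole liver region
(labels 1 and 2 together), since lesions lie inside the liver; a ratio of
exactly 10% counts as small ("greater than" is strict). Patterns are
assigned per slice. Liver metrics likewise evaluate the filled region
(labels 1 and 2), matching how liver masks are scored in the LiTS
literature; tumor metrics use label 2 alone.

## Metrics

Per case and class: Dice `2TP/(2TP+FP+FN)`, volumetric overlap error
`1 - TP/(TP+FP+FN)`, and relative volume difference. The literal ratio form
`FP/(TP+FN)` is non-negative by construction, yet signed (negative) values
are the norm in reported liver-segmentation tables; both forms are computed,
and the signed form `(TP+FP)/(TP+FN) - 1` is used in summaries. When both
masks are empty the case is scored as perfect agreement (Dice 1, VOE 0,
RVD 0). Aggregation is an unweighted mean over cases within each group.

## The synthetic phantom

Real abdominal CT with expert labels cannot ship with a package, so the
generator emulates the structural essentials of a labelled axial slice: a
noisy-edged elliptical "liver" (semi-axes 24-36% of the side, low-order
angular wobble), zero or more darker circular "lesions" strictly inside it
with at least a 2-pixel gap between lesions, elliptical background clutter,
and Gaussian noise. Default tissue values follow portal-venous contrast
ordering: liver 60 +/- 10 HU, lesions 30 +/- 8 HU, background -100 HU,
noise 15 HU; raw voxels are stored as `(HU - intercept)/slope` with
slope 1 / intercept -1024 so the full conversion path is exercised. Pattern
generation draws lesion areas from ratio ranges (large 13-22%, small 2-7%,
multiple: 2-4 lesions of 1.2-3.5% each) and re-draws a slice if pixelation
pushes the realized pattern off the requested one, so manifests always agree
with the classifier.

What passing on phantoms does **not** show: robustness to real CT texture,
vessels and other organs of similar intensity, partial-volume effects at
lesion rims, inter-scanner intensity shifts, or 3-D context. The phantom
establishes that the pipeline's mechanics — imbalance-weighted learning,
cascade fusion, multi-resolution refinement, pattern stratification — work
end to end; claims about clinical data require the real LiTS volumes, which
users can feed through the same NIfTI/PNG interfaces.

## Desk-scale experiment sizes

CPU experiments in the tests use the reduced `cpu-test` profile: coarse
depth 3 / base width 8, fine width 16 / growth 8 at 64x64, Adam at 1e-3,
around 10 epochs per stage, 200 phantoms (160 train / 40 held out) for the
main run and 5 seeded repeats of 50 multiple-lesion phantoms for the
cascade-versus-coarse comparison. These sizes were chosen once as the
smallest configuration at which the phantom task is learned cleanly; the
package defaults remain the full-scale protocol above.

## Numerical choices and degenerate inputs

* Argmax ties in prediction resolve to the lowest class index
  (background before liver before tumor).
* Softmax subtracts the per-pixel maximum before exponentiation.
* A constant slice min-max-normalises to all zeros.
* `sigma = 0` disables smoothing exactly; negative sigma is an error.
* Window bounds must satisfy `low < high`; windowing is idempotent.
* Masks reject any value outside {0, 1, 2}; a mask with tumor pixels but no
  liver pixels is a degenerate input and raises an error in pattern
  classification.
* Adaptive weights require `t > 1` so the logarithm is positive for every
  possible proportion.

## Known limitations

* 2-D, slice-wise only; no 3-D context or isotropic resampling.
* No data augmentation, no post-processing (largest-component filtering,
  CRFs), no test-time augmentation.
* CPU training at full 512x512 scale with default widths is impractical;
  the full-scale configuration exists for completeness and for users with
  patience or smaller volumes, while the reduced profile is the supported
  desk-scale path.
* The joint fine-tuning objective does not propagate gradients through the
  fusion step; the stages remain separately optimised modules.
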