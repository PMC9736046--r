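---
title: "Collaborative-patch multi-feature networks for retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative-patch multi-feature networks for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vesselseg)
```

## The problem

Retinal vessel morphology carries diagnostic signal for diabetic
retinopathy, glaucoma and other ocular disease, and pixel-level vessel
segmentation of fundus photographs is the step that makes it quantifiable.
Two things make the task hard: capillaries are one or two pixels wide at
typical fundus resolutions and sit at low contrast against the background,
and the images themselves (584×565 for DRIVE-style data) are large enough
that whole-image training either downsamples away the thin structures or
exhausts memory. Patch-based training sidesteps the memory problem but
introduces another: a patch boundary severs every vessel that crosses it,
so the network never sees the neighbourhood context that says whether a
faint streak at the border is a vessel continuing from outside or noise.

`vesselseg` implements a segmentation method built around two ideas:

1. **A two-stage multi-feature network.** A pre-segmentation U-Net produces
   a rough vessel map of the target patch; a main-segmentation U-Net --
   equipped with adaptive coordinate attention after each encoder stage and
   a gated windowed self-attention block at the bottleneck -- refines it. A
   shallow, Sobel-initialized edge branch supplies an explicit vessel-edge
   probability to the main encoder.
2. **Collaborative patches.** Each small \(s \times s\) target patch is
   extracted together with five large \(l \times l\) patches that all
   contain the target region (centre placement plus the four corners).
   Features extracted from the large patches re-inject the neighbourhood
   information the small patch lost at its borders, both between the two
   network stages (the *associated-information fusion* step) and at the
   final head (the *correction* step).

## The attention modules

**Adaptive coordinate attention (ACA).** For a feature map
\(T \in \mathbb{R}^{C\times H\times W}\), each channel is encoded along each
axis by 1-D pooling, with *both* average and maximum pooling:

\[
k^{a}_{c}(w) = \tfrac1H \sum_i T_c(i, w), \qquad
k^{m}_{c}(w) = \max_i T_c(i, w),
\]

and the analogous pair over the width. Average pooling blurs one-pixel
capillaries into the background; the max branch keeps them visible. The
average-pair and max-pair are each concatenated along the spatial axis and
passed through a shared 1×1 bottleneck transform \(F_1\) (reduction ratio
\(r\), hard-swish non-linearity), then recombined with two *learnable
scalars*:

\[ z = g_1 z^{a} + g_2 z^{m}, \]

split back into height and width parts, and mapped through per-direction
1×1 transforms with a sigmoid to gates \(f^h \in (0,1)^{C\times H}\),
\(f^w \in (0,1)^{C\times W}\). The output is the pure elementwise gating
\(y_c(i,j) = T_c(i,j)\, f^h_c(i)\, f^w_c(j)\), so attention can suppress or
keep whole rows/columns per channel -- a good match for elongated,
direction-coherent vessels. With \(g_1 = 1, g_2 = 0\) the module reduces
exactly to classical average-only coordinate attention (the `CA` baseline);
the package tests assert this reduction bit-for-bit.

*Choices made here:* \(g_1, g_2\) are per-module scalars initialized at 0.5
each (an equal mix that gradients can move either way); the bottleneck
non-linearity is hard-swish (configurable); no normalization is imposed on
\(g_1, g_2\).

**Gated self-attention (GSA).** Full-image self-attention is quadratic in
pixels and the relative position bias of windowed transformers is known to
train poorly on small datasets. The GSA block therefore (a) computes
attention inside \(M\times M\) windows only, and (b) multiplies the
relative-position bias \(B\) by a learnable scalar gate:

\[ \mathrm{Attention}(Q,K,V) = \mathrm{Softmax}\!\left(\frac{QK^t}{\sqrt d} + g_a B\right) V. \]

\(B\) is gathered from a learnable table indexed by relative displacement,
of shape \((2M-1)\times(2M-1)\) -- the standard relative-coordinate range
(a displacement of \(\pm(M-1)\) in each axis). Two transformer sub-blocks
are applied in sequence (LayerNorm → windowed attention → residual;
LayerNorm → 2-layer MLP → residual), the first with a regular partition and
the second after a cyclic shift of \(\lfloor M/2 \rfloor\), so information
crosses window borders. Token maps not divisible by \(M\) are zero-padded
and cropped back; no attention masking is applied to the wrapped tokens of
the shifted partition (at the bottleneck sizes used here the wrap spans at
most half a window, and the gate can learn to discount it). With
\(g_a \equiv 0\) the block is bias-free windowed attention; frozen at
\(g_a \equiv 1\) it is the Swin-style `SW` baseline -- both reductions are
asserted exactly in the tests. Defaults: \(M = 6\), one head per 32
channels, MLP expansion 4, \(g_a\) initialized at 1 ("bias on").

## The collaborative patch strategy

The geometry is one small patch \(S\) coinciding with the target region and
five large patches placed so the target sits at the centre and at each of
the four corners: offsets \(\{((l-s)/2, (l-s)/2), (0,0), (0,l-s), (l-s,0),
(l-s,l-s)\}\). Whatever side of the target the relevant neighbourhood is
on, at least one large patch covers it. Near image borders the large
patches are completed by reflective padding of width \(l-s\) (reflection
avoids fabricating dark borders that mimic vessels), so the containment
invariant -- the small patch equals the sub-array of every large patch at
its recorded offset, bitwise -- holds everywhere; it is property-tested on
1,000 random geometries including all border cases. Defaults: \(s = 72\)
(the patch size used for DRIVE/STARE-scale images), \(l = 2s\).

**Context networks and the compute profile.** The large patches carry
*coarse* context -- which vessels approach the target region and from
where -- not fine detail. They are therefore downsampled ×4 (block mean)
and processed by dedicated lightweight context encoder–decoders (channel
ladder 6→12→24 by default) rather than by the full-resolution
sub-networks. This is the package's resolution of a real tension: had the
five large patches passed through the same full-resolution networks as the
small patch, the collaborative forward would cost roughly twenty times the
single-patch forward and the strategy's low-compute rationale would
collapse. With coarse, narrow context networks the static count (see
`count_flops_params()`) puts the collaborative forward within 5% of the
single-patch forward and under 2% of one whole-image forward at 584×565 --
the compute relationship the strategy is designed around. The cost is that
context features are not weight-shared with the main path; the package
treats that as the better trade.

**Fusion and correction.** The five context pre-segmentation features pass
through a shared 3×3 convolution, are *cut* to the target region (the cut
operator is pure indexing at the feature scale; offsets divide exactly by
the downsampling factor by construction, validated at model build), then
concatenated, channel-gated (global-pool attention), compressed by a 1×1
convolution and upsampled -- this fused feature \(f_{plt}\) joins the raw
patch, the small-patch pre-segmentation feature and the edge map as the
main network's input. Cutting *before* concatenation aligns the fused
feature spatially with the small patch, which is what lets it join the
small-patch input at all. The correction step repeats the pattern on the
context networks' second-stage features: shared 3×3 convolution, an
auxiliary large-patch segmentation head per patch, cut → concat → channel
attention → \(f_{mlt}\), and the final head is a 3×3 + 1×1 convolution pair
over \([f_{ms}, f_{mlt}]\) with a sigmoid. With the collaborative path
disabled, \(f_{plt}\) and \(f_{mlt}\) are zeros of the same shape, so the
ablation changes no contract.

## Preprocessing and supervision

Images are reduced to the green channel by default (the highest-contrast
channel for vessels in fundus photography; luminance is the alternative),
then CLAHE (clip 2.0, 8×8 tile grid) and gamma correction (γ = 1.2) -- the
constants are conventional for fundus work and exposed in the
configuration. Training-time augmentation applies an identical geometric
transform (right-angle rotations, both flips) to image and masks, plus
random erase of a 2–8%-area rectangle on the image only. Arbitrary-angle
rotation is deliberately excluded by default: masks would need resampling
and the label bits would no longer be exact.

The loss is BCE + soft Dice (equal mix) with deep supervision:
\(\lambda_{main} = 1\) on the final head, \(\lambda_{pre} = 0.4\) on the
pre-segmentation heads, \(\lambda_{large} = 0.2\) on each auxiliary
large-patch head, and \(\lambda_{edge} = 0.2\) on the edge head, whose
target is the morphological gradient (3×3 dilation minus erosion) of the
vessel mask -- the simplest label-derived edge. The optimiser is Adam with
the stepwise schedule `lr = lr0 * 0.8^(epoch %/% decay_every)` (defaults
lr0 = 0.0025, decay every 20 epochs; the STARE-style alternative is 0.002
every 8) and L2 weight decay 7e-6.

**Patch sampling policy.** Training patches are drawn from a stride-\(s\)
grid restricted to target regions with at least 50% field-of-view coverage,
plus random origins inside the FOV bounding box. This matters: the region
outside the FOV disc is dark *and labelled background*, while vessels
inside the FOV are dark *and labelled vessel*. A sampling scheme dominated
by corner patches feeds the network mostly the first pattern and training
collapses to the all-background solution; FOV-aware sampling restores the
signal. Evaluation is unaffected -- metrics are always computed over all
FOV pixels.

## Evaluation

All metrics are restricted to FOV pixels: ACC, SE (sensitivity), SP
(specificity) and F1 from the confusion counts at a 0.5 threshold
(configurable), and AUC by the exact Mann–Whitney rank statistic with
average ranks on ties -- a deliberate choice over trapezoidal integration
of a thresholded ROC, which depends on the threshold grid. The AUC
implementation is cross-checked in the tests against an \(O(n^2)\)
pairwise-concordance oracle.

Whole-image inference tiles the image with stride \(s/2\) (50% overlap) and
averages overlapping small-patch probabilities; stitching an identity
network reproduces the input to within float-addition tolerance, which the
tests assert.

## The synthetic data generator

Real DRIVE/STARE images cannot ship with the package, so every test and the
acceptance script run on synthetic fundus-like records: recursive branching
vessel trees drawn as width-tapering random-walk curves radiating from an
optic-disc analogue, rasterized inside a circular FOV; the image is a
bright noisy background (mean 0.55, σ = 0.03) with vessels darker by a
configurable contrast (0.35), Gaussian-blurred (σ = 1) to soften
boundaries; dark-vessels-on-bright polarity matches the fundus green
channel. Ground truth, edge map and FOV are consistent with the image by
construction and the whole record is a deterministic function of the seed.
Default specs put the vessel fraction inside the FOV at 7–11%, within the
plausible fundus range, and the fixture suite includes a fine-calibre
subset (root width under 2 px) for small-vessel sensitivity.

What the generator does *not* emulate: optic disc and macula appearance,
lesions, illumination gradients, inter-image colour variation, annotation
noise. Passing the learning smoke test on this data shows the training
machinery works end to end -- sampling, loss, gradients, optimiser,
inference, metrics -- and that the network can learn thin curvilinear
structure at realistic class imbalance. It does not certify DRIVE/STARE
accuracy numbers; reproducing those requires the real datasets and
GPU-scale training, which are out of scope here.

## Problem sizes used by the tests and the acceptance script

The equation-level oracle checks run on ~100 random small instances per
operator; geometry exactness on 1,000 random cases. The learning smoke test
trains the smoke-scale model (patch 48/96, channel ladders 8→16→32 for both
full-resolution sub-networks and 4→8→16 for the context networks, one
attention head) for 30 epochs on the 12-image 192×192 fixture suite with
batch size 2 and three patch sets per image per epoch, then requires mean
test F1 above 0.6 on the four held-out images; typical runs land around
0.8 with AUC near 0.98. The ablation-direction comparison (collaborative
vs single-patch) runs three seeds at a further reduced scale (6 epochs, 6
training images) and is reported rather than hard-asserted, since at that
scale seed noise can exceed the effect. `scripts/acceptance.R` repeats the
pipeline at 24 epochs and writes all headline quantities as JSON. The
compute-profile check uses the full full-scale configuration (72/144
geometry, 32→64→128→256 main ladder) and is purely static arithmetic.

## Known limitations

* CPU-only: the bundled autodiff engine is minimal by design (dense arrays,
  im2col + BLAS convolutions). It trains the smoke-scale models in minutes
  but is not a vehicle for full DRIVE/STARE training.
* No attention masking in the shifted-window pass (see above).
* The context path is not weight-shared with the main path; the compute
  profile is the reason.
* GIF input is not supported (PNG/TIFF/PGM/PPM are); DICOM is out of scope.
* `estimate_fov()` is a deliberately simple intensity-threshold +
  largest-component + closing estimator. It gates evaluation pixels only
  and is no substitute for dataset-provided FOV masks when those exist.
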