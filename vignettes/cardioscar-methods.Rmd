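---
title: "Detecting regional LV scar from CTA with latent-space classifiers"
author: "cardioscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regional LV scar from CTA with latent-space classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Late gadolinium enhancement (LGE) MRI is the clinical gold standard for
imaging myocardial scar, but it is frequently contraindicated — implanted
devices, claustrophobia, availability. Contrast CT angiography (CTA) is far
more widely acquired, yet it has no validated scar-imaging protocol: scar is
at best faintly visible through texture and wall thinning. The question this
package addresses is whether a neural network can recover *regional* scar
information (septal wall versus lateral wall, per short-axis slice) from a
single-phase, clinically standard CTA — useful, for example, when planning
cardiac resynchronization therapy, where scar at the lateral pacing target
predicts poor response.

`cardioscar` implements the full chain needed to study this question:
the ground-truth generation path (MRI-to-CTA mesh registration, short-axis
slicing, region labeling), image preprocessing, the encoder–decoder
classification networks with their losses, the patient-stratified
cross-validation harness — and a synthetic phantom generator so that each
stage, and the pipeline end to end, can be exercised and tested without any
patient data.

## Ground-truth generation

### Three-step mesh registration

Scar is segmented on LGE MRI as a surface mesh; to label CTA slices it must
be carried into CTA space. Registration is rigid and proceeds in three
steps, each implemented with closed-form least squares or iterative closest
point (ICP):

1. **Major axis** (`alignMajorAxis`): the largest-variance direction of the
   endocardial vertex cloud is rotated onto the fixed mesh's, centroids
   aligned. Axis *sign* is taken from the apex/base-centre landmarks when
   present, otherwise the orientation with the smaller post-alignment
   surface distance is kept.
2. **RV junctions** (`alignRvJunctions`): a single rotation about the long
   axis, found in closed form (2-D Procrustes of the projected landmarks),
   aligns the labelled RV-junction points. Restricting this stage to one
   degree of freedom reflects its purpose — fixing axial roll — and the
   labelled correspondence resolves the 180° ambiguity.
3. **Endocardial ICP** (`registerEndocardium`): point-to-point ICP
   (nearest-neighbour correspondence + Kabsch fit), `maxIter = 100`,
   stopping when the RMS correspondence distance improves by less than
   `tol = 1e-4` mm. The per-iteration RMS is non-increasing; non-convergence
   is flagged in metadata rather than raised.

Transforms are strictly rigid (no scaling): the registration of same-heart
surfaces across modalities should not absorb size error into scale, and any
residual is part of the ground-truth uncertainty. Nearest neighbours use
blocked brute-force distance matrices — meshes here are a few thousand
vertices, where a k-d tree buys nothing.

### Short-axis slicing

`toHeartCoordinates` re-expresses the CTA volume and meshes in a heart
frame: apex at the origin, long axis along +z, septal direction (midpoint of
the RV-junction landmarks) along +x. `sampleShortAxis` then cuts 60 evenly
spaced planes (cell-centred: plane *i* at `apex + (i + 0.5)·L/n`, so a
single slice falls at the axis midpoint and no plane degenerates onto a
landmark), resampling each to 600 × 600 pixels by trilinear interpolation.
The in-plane field of view is a fixed 120 mm square (0.2 mm/px at 600 px);
only the pixel count is inherited from the reference pipeline, so the
physical extent is configurable. Masks are rasterized from the watertight
surface meshes by even-odd scanline filling of the plane/mesh cross-section:
a pixel is inside iff its 3-D centre is inside the closed surface. Slice
index 0 is the most apical.

### Region labeling and exclusion filters

The septal wall is defined *operationally*: myocardium within an adjacency
radius (Euclidean distance transform) of the RV mask; everything else —
anterior and inferior included — is "lateral". The adjacency radius defaults
to 12 px at 600 × 600 and scales with the grid. A region is labelled
scar-positive when scar covers **at least 10%** of that region's myocardial
pixels (inclusive comparison; the region's own pixel count is the
denominator). Three exclusion filters run in order:

1. `low_myocardium` — fewer than 50 myocardial pixels (kept at exactly 50):
   apical tip or above the base;
2. `no_rv` — empty RV mask: near the apex the septal region cannot be
   defined;
3. `self_intersection` — mask-topology failure standing in for the
   basal aortic-valve case: the myocardium must be one connected component
   whose single interior hole contains the endocardial mask.

The order puts the cheap size check first and lets apical solid-tip slices
(no lumen, no RV) fall under `no_rv`, matching the anatomical reading of
each filter. The topology check deliberately detects the *mask-level*
signature of the valve-plane self-intersection; there is no separate valve
detector.

## Image preprocessing

Each kept slice is zoomed by 0.6 (600 → 360 px; bilinear for the image,
nearest-neighbour for masks) and cropped to 256 × 256 centred on the
endocardial centroid. During training a uniform integer offset in ±20 px per
axis decentres the crop (static augmentation: offsets are drawn once per
sample, as when shards are written to disk); evaluation crops are centred.
If the crop would clip the RV, the window shifts minimally to include it;
an RV too large for any window falls back to the centred crop with a flag.
Intensities map linearly from a (−200, 800) HU-like window to [0, 1] — wide
enough to span background through contrast-filled blood pool; the window is
configurable since nothing in the reference pipeline pins it. Labels are
computed on the native grid *before* any geometric preprocessing and carried
through unchanged.

## Networks

Three variants share one skeleton (`buildNetwork`): a convolutional encoder
(five levels of 16–256 channels at full scale, each level a stride-2 3 × 3
convolution followed by a second stride-1 convolution — the usual two
convolution blocks per scale — with group normalisation and PReLU after
each), a variational bottleneck (the deepest feature map flattened, then
linear maps to μ and log σ², latent size 128), and a decoder plus fully
connected classification branches fed by the latent vector:

* **VAE-Scar** — the decoder reconstructs the input image (no skips); both
  septal and lateral branches classify from the latent.
* **U-Scar** — the decoder receives skip connections from the encoder and
  emits 3-channel segmentation logits (endocardium, epicardium, RV), forcing
  anatomical shape into the latent code.
* **U-Scar-Lat** — U-Scar with only the lateral branch.

Branches are blocks of (linear → group norm → PReLU → dropout 0.5) with
widths 1000, 1000, 256 and a 2-way softmax head. Training samples the latent
by reparameterisation (`z = μ + σ·ε`); evaluation uses `z = μ` and disables
dropout, so inference is deterministic. The decision threshold for
sensitivity/specificity is 0.5 on the positive-class softmax probability.

Numerical choices worth recording: σ is parameterised as log-variance,
clamped to ±15; group counts divide the channel count (reduced when
necessary); and the log-variance head bias is initialised at −6. The last
one matters: with a unit-scale σ at initialisation the reparameterisation
noise is an order of magnitude larger than the spread of μ across inputs,
and the classification branches simply learn to ignore the latent —
training collapses to the majority class. Starting near-deterministic lets
μ become informative before the KL term re-inflates σ.

The bottleneck is *flattened* rather than globally average-pooled, as in
the MONAI-style VAE segmentation networks this design follows. The pooled
alternative interacts badly with group normalisation: group norm
zero-centres each sample's feature map, so its spatial average carries
almost no between-sample information and the latent μ degenerates — an
effect that reproducibly stalled classification in desk-scale experiments.

The whole layer stack (convolution via C++ im2col/col2im and BLAS matrix
products, group-norm, PReLU, linear, dropout, Adam) is implemented in the
package; every layer's analytic gradient is checked against central finite
differences in the test suite.

## Losses

The training objective is a weighted sum with one weight per component:

$$L_{total} = W_x L_x + W_{kl} L_{kl} + W_s L_s(p_{septal}) + W_l L_l(p_{lateral})$$

* $L_x$: mean binary cross-entropy of the decoder output — against the
  normalised image (VAE-Scar) or the 3-channel segmentation (U-Scar).
  Cross-entropy is preferred over Dice here for tunability against the
  other terms.
* $L_{kl} = \tfrac12\sum_d (\mu_d^2 + \sigma_d^2 - 1 - \log\sigma_d^2)$,
  the divergence of the latent posterior from a unit Gaussian.
* $L_s, L_l$: focal losses
  $-\alpha\,(1-p)^{\gamma}\log p$ on the true-class softmax probability,
  with per-region weighting α (applied to positives, 1−α to negatives) and
  focusing γ. Class imbalance in scar cohorts is severe (≈11% septal, ≈18%
  lateral positive slices), hence the low default α = 0.05; γ defaults
  to 2. With γ = 0, α = 1 the focal loss reduces exactly to cross-entropy.

Defaults `W_x = 1, W_kl = 0.001, W_s = W_l = 1`; the small KL weight guards
against posterior collapse. Setting any weight to zero removes that
component exactly (the total is linear in each weight), and a positive
region weight without the matching branch is a contract error.

## Training and evaluation

Cross-validation is 5-fold, **grouped by patient** (no patient straddles
train/validation) and additionally stratified on patient-level scar status
so every fold sees positives. The optimiser is Adam (lr 1e−4, batch 16,
up to 200 epochs, early stopping on validation loss with patience 10 —
all configurable); data order, dropout, crop offsets and reparameterisation
noise are all derived from the run seed. Metrics: AUC as the Mann–Whitney
rank statistic with DeLong 95% confidence intervals (via pROC, cross-checked
in tests against brute-force pair counting), sensitivity/specificity at the
0.5 threshold, and accuracy averaged over active regions. Validation
predictions are pooled across folds before the ROC computation; per-fold
reports are retained.

## The synthetic phantom

`generatePhantomCase` builds what the data-generation chain would produce
from a real case: a stack of short-axis slices with an annular LV
(blood pool ≈ 400, myocardium ≈ 120, background ≈ −50, HU-like), an RV
crescent attached over a configurable arc centred on the septal direction,
additive Gaussian noise, and scar drawn as an angular sector of a region's
myocardium. Septal scar sits on the septum; lateral scar is centred in the
lateral free wall (normally distributed around 180° from the septum, SD
30°), mirroring how infarcts cluster within coronary territories — without
that anatomical clustering a small cohort presents each fold with
essentially unrepeated scar positions, and no learner (the networks or a
pixel-space linear probe) generalises across patients.
The scar sector's pixel count is chosen so the realised burden
matches the requested fraction exactly up to rounding, and scar carries the
two cues reported for CTA — an intensity shift and local wall thinning.
The stack tapers toward the apex so the minimum-myocardium and missing-RV
filters fire naturally on apical slices. `generateMeshPair` builds matching
watertight endocardial/epicardial/RV surfaces with landmarks, optionally
transformed and jittered, giving registration a known ground-truth
transform. All randomness flows from a single per-case seed.

What the phantom deliberately does **not** model: realistic CT noise
texture and beam hardening, contrast-timing variation, papillary muscles,
trabeculation, pericardium, through-plane anatomy changes, or HCM-like
morphology. Passing the end-to-end learning test therefore shows the
*pipeline and networks* work — data flow, labels, losses, optimisation,
leak-free validation — not that the real clinical discrimination problem is
solved at these accuracies; on real CTA the reported signal is far weaker.

`phantomCohort` draws per-patient geometry from the spec ranges and assigns
scar at patient-level prevalences matching the reference class balance
(≈11% septal, ≈18% lateral), with burden for positive patients uniform in
0.20–0.45 — comfortably above the 10% labeling threshold, so label noise
does not confound the learning check.

## Desk-scale study conditions

The end-to-end checks run at a reduced scale chosen once
(`deskNetworkConfig()` and friends): 40 synthetic patients of 8 slices
generated at 150 px (so the zoom/crop chain is exercised: 150 → 90 → 64
with ±5 px offsets), a U-Scar-Lat with encoder widths 4/8/16/32 (two conv
blocks per level), latent 32 and branches 32/16 with dropout 0.1, Adam at
lr 1.5e−3, batch 8, 30 epochs (no early stopping within the cap — the
classification branches converge after the decoder, so a validation-loss
stopping rule truncates them), 5-fold patient-stratified CV, and per-epoch
crop-offset augmentation of ±4 px.
Lateral prevalence is ≈18% at slice level and the scar intensity shift
(−80) is several multiples of the pixel noise.

Three desk-scale choices deserve comment because getting them wrong
silently breaks learning. First, the crop-offset jitter must be re-drawn
every epoch: frozen offsets let the network memorise training patients
(training AUC 1.0, patient-grouped validation at chance). Second, two
convolution blocks per encoder level matter even at these widths — the
single-block variant underfits the sector-darkness feature within the epoch
budget. Third, the focal focusing term is set to γ = 0 for this run (plain
class-weighted cross-entropy): with a few hundred clean, well-separated
synthetic samples the `(1−p)^γ` factor starves the gradient long before
convergence. The full-scale defaults keep γ = 2, where rare, hard positives
among thousands of noisy clinical slices are exactly the regime focal loss
is designed for. Under these conditions the pooled cross-validated lateral
AUC reliably exceeds 0.8, while training on permuted labels stays
statistically indistinguishable from chance — the leak check that matters
most with patient-grouped data.

## Known limitations

* The septal/lateral boundary is adjacency-based; alternative boundary
  definitions would shift fractions near the junctions.
* Rigid-only registration; cross-modality size mismatch lands in the
  ground-truth error budget.
* The self-intersection filter works on mask topology, not on the meshes.
* The NN stack is CPU-oriented R + BLAS; it is meant for method study and
  desk-scale experiments, not GPU-scale training.
* Real-data formats: DICOM support is a minimal explicit-VR little-endian
  single-frame CT reader; ASCII PLY for meshes.
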