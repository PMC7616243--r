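# cardioscar

Regional left-ventricle (LV) scar detection from routine, single-phase
cardiac CT angiography (CTA), using encoder–decoder neural networks whose
latent space feeds fully connected classification branches.

## Who this is for

MRI with late gadolinium enhancement is the gold standard for myocardial
scar imaging but is often contraindicated (devices, claustrophobia,
availability). CTA is acquired far more widely, yet scar is only faintly
expressed in it — as texture change and wall thinning. This package is for
researchers studying whether those faint cues can be learned: it implements
the complete data-generation and learning chain for per-slice septal/lateral
scar classification, and a synthetic phantom so the entire pipeline runs and
is testable without patient data.

## What it implements

**Ground-truth chain**

* Three-step rigid registration of MRI-derived surface meshes to CTA meshes
  (`registerMriToCta`): major-axis alignment → RV-junction roll correction →
  endocardial iterative closest point. The resulting transform carries the
  MRI scar mesh into CTA space.
* Heart-coordinate conversion and short-axis slicing
  (`toHeartCoordinates`, `sampleShortAxis`): 60 evenly spaced planes normal
  to the apex–base axis, resampled to 600 × 600 px; masks rasterized from
  the watertight meshes.
* Region labeling (`labelRegions`): the septal wall is myocardium adjacent
  to the RV (distance transform); the rest is lateral. A region is
  scar-positive when scar covers ≥ 10 % of its myocardial pixels.
  Exclusion filters drop slices with < 50 myocardial pixels, without RV, or
  with self-intersecting (non-annular) myocardium masks.

**Networks and training**

* `buildNetwork` constructs three variants: **VAE-Scar** (image-
  reconstructing variational autoencoder, septal + lateral branches),
  **U-Scar** (skip-connected decoder emitting endo/epi/RV segmentation)
  and **U-Scar-Lat** (lateral branch only). Latent size 128, group
  normalisation, PReLU, branch widths 1000/1000/256, dropout 0.5.
  The layer stack (conv via C++ im2col + BLAS, group norm, PReLU, linear,
  dropout, Adam) is implemented in the package and gradient-checked against
  finite differences.
* The loss (`totalLoss`) is the weighted sum
  `W_x·L_decoder + W_kl·L_KL + W_s·L_septal + W_l·L_lateral`,
  with per-region focal losses `−α(1−p)^γ log p` for class imbalance.
* `crossValidate` runs 5-fold cross-validation grouped by patient (and
  stratified on patient scar status); `evaluate` reports AUC with DeLong
  95 % CIs plus sensitivity/specificity at the 0.5 threshold.

**Synthetic phantom**

`generatePhantomCase` / `phantomCohort` build short-axis stacks with an
annular LV, attached RV crescent, apical taper, noise, and scar drawn as an
angular sector with exact burden control, intensity shift and wall thinning
— with per-slice ground-truth labels. `generateMeshPair` builds matching
watertight meshes with a known rigid transform for registration tests.

## Worked example

```r
library(cardioscar)

# one synthetic patient with a 30% lateral scar
spec <- phantomSpec(imageSize = 128, nSlices = 8,
                    scarPresent = c(septal = FALSE, lateral = TRUE),
                    scarBurden = c(septal = 0, lateral = 0.3), seed = 7)
case <- generatePhantomCase(spec)
labelCase(case)[1:4, c("slice_index", "excluded", "reason",
                       "lateral_scar", "lateral_fraction")]
#>   slice_index excluded reason lateral_scar lateral_fraction
#> 1           0     TRUE  no_rv           NA               NA
#> 2           1    FALSE   none         TRUE        0.2998296
#> 3           2    FALSE   none         TRUE        0.3007092
#> 4           3    FALSE   none         TRUE        0.2997543
```

The apical slice is excluded (no RV visible, so no septal region can be
defined); kept slices realise the requested 30 % burden to within rounding
and are labelled positive under the 10 % rule.

```r
# recover a known rigid transform by 3-step registration
gen <- rigidTransform(rotationAboutAxis(c(0.2, 0.3, 1), 12), c(5, -3, 2))
pair <- generateMeshPair(spec, gen)
t <- registerMriToCta(meshSet(endo = pair$moving@endo),
                      meshSet(endo = pair$fixed@endo))
meanSurfaceDistance(applyTransform(pair$moving@endo, t), pair$fixed@endo)
#> [1] 6.462002e-15
```

With noiseless meshes the composed transform recovers the generator to
machine precision; with 0.5 mm vertex jitter recovery stays below 1 mm mean
surface distance (see the test suite).

```r
evaluate(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
#> MetricsReport
#>   lateral  AUC 0.750 [0.057-1.000]  sens 0.50  spec 0.50  (n=4, pos=2)
#>   accuracy 50.0%
```

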