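---
title: "Majority-voting ensembles for 3D tooth segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-voting ensembles for 3D tooth segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(VoteSeg)
```

## The problem and the method

Automatic tooth segmentation on cone-beam CT (CBCT) is hard for a single
convolutional model: teeth share Hounsfield range with surrounding bone, and a
2D network sees only one plane, so axial models hallucinate root-shaped bone
clusters, coronal/sagittal models mistake sheet-like bone for teeth, and 3D
patch models err at patch borders. Because the error *modes* differ while the
true teeth are found by most models, a per-voxel majority vote across models
removes a large share of the false positives without losing the shared true
positives.

`VoteSeg` implements that ensemble pipeline as a toolkit:

1. **Multi-view decomposition** (`extractSlices`, `makeSlabs`,
   `tilePatches`): a volume becomes axial/coronal/sagittal 2D stacks, 2.5D
   three-channel axial slabs (slices $i-1,i,i+1$), or non-overlapping
   $64\times64\times128$ 3D patches. Every decomposition is lossless and
   invertible (`stackToVolume`, `assemblePatches`).
2. **Predictors** (`buildPredictor`, `trainPredictor`, `predictVolume`): a
   native U-Net (two ReLU convolutions per level, $2\times$ max pooling,
   nearest-upsampling + convolution with skip concatenation, dual-class
   softmax) trained with Adam on binary cross-entropy. Any external model
   producing aligned binary masks can substitute — voting and evaluation only
   consume masks.
3. **Voting** (`majorityVote`, `applyScheme`): voxel $v$ is foreground iff at
   least $k$ of $n$ voters mark it. Stock schemes: `2.5Dv` = vote of the three
   orthogonal 2D models ($k=2$), `3.5Dv4` = the 2D trio plus the 3D model
   ($k=3$), `3.5Dv5` = all five trained models ($k=3$), and `3.5Dv3` = a
   *nested* vote of {`2.5Dv`, `2.5Da`, `3D`} with $k=2$ whose first voter is
   itself a vote. Nesting is evaluated depth-first and is **not** equivalent
   to a flat five-voter vote; both are exercised in the tests.
4. **Morphology** (`erodeMask`, `dilateMask`, `openED`): binary
   erosion/dilation with a discrete spherical structuring element, composed
   as an opening ("E&D") to delete speckle-sized false positives.
5. **Evaluation** (`confusionPerSlice`, `aggregateSlices`, `makeFolds`,
   `pairedWilcoxon`, `kruskalWallisBonferroni`, `ksNormality`): slice-based
   confusion counts, the six metrics
   $\mathrm{DSC}=\frac{2TP}{FP+2TP+FN}$, accuracy, sensitivity, specificity,
   PPV, NPV, patient-level fourfold cross-validation folds, and the
   nonparametric comparisons.
6. **Phantoms** (`makePhantom`, `degradePrediction`,
   `simulatePredictionSet`): synthetic CBCT-like volumes and controllable
   noisy predictions so the whole pipeline is testable without patient data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `th1`, `th2`, `th3` (`computeMDBR`) | 3070 HU, 2500 HU, 0.4 | metal-like and enamel-like density thresholds and the heavy-burden cutoff of the metallic-dental-burden (MDB) screen |
| `sigma` (`gaussianSmooth`) | 1 voxel | 3D Gaussian denoising SD |
| structuring element | Euclidean ball, radius 2 (33 voxels) | the E&D element |
| vote threshold `k` | strict majority $\lfloor n/2\rfloor+1$ | minimum affirmative votes |
| `tau` (`binarize`) | 0.5 | probability threshold; ties go to foreground, equal to the two-class softmax argmax |
| U-Net spec | depth 4, 32 first features, Adam, BCE, lr $10^{-4}$, batch 12 (2D/2.5D) / 6 (3D), epochs 150/200, LR $\times0.95$ after 10 stalled epochs, early stop after 50 | reference configuration; reduced specs are used for desk-scale runs |

The MDB ratio is implemented as the ratio of voxel *counts* above `th1` and
`th2`. A literal ratio of the thresholds themselves would be the constant
1.228 and could never be compared against a cutoff of 0.4, so the count
reading is the only self-consistent one; the literal reading remains
available via `definition = "threshold_ratio"`. When no voxel exceeds `th2`
the ratio is defined as 0 — a scan without enamel-density voxels cannot carry
a metal-burden verdict, so it is conservatively not excluded.

Gaussian smoothing interprets `sigma` in voxels: CBCT grids are isotropic
(0.19 mm here), so voxel and millimetre parameterisations are proportional.
Boundaries are handled by reflective padding, which preserves local mean
intensity at the volume faces; zero padding would darken the borders and bias
the threshold-based ground-truth contouring that follows smoothing.

## Numerical and convention choices

* **Axis convention.** Arrays are indexed (x, y, z) with axial = fixed-z,
  coronal = fixed-y, sagittal = fixed-x. `hflip` reverses x (the left-right
  direction of an axial slice), giving the standard augmentation factor of 2.
* **2.5D edges.** Slab channels for out-of-range neighbours replicate the
  nearest existing slice, keeping channel semantics without inventing
  intensities.
* **Patching.** Volumes are zero-padded at the trailing end of each axis to
  the next multiple of the patch shape and cut into disjoint blocks (raster
  order, z fastest). Overlap-and-average inference is deliberately out of
  scope; patch-border artefacts are part of what voting is shown to fix.
* **Structuring element.** "Spherical, radius 2" is read as the Euclidean
  ball on the voxel lattice: offsets with $\lVert z\rVert_2\le2$, i.e. 33
  voxels (1+6+12+8+6 by squared norm). City-block and chessboard balls are
  available. Outside-grid voxels count as background for erosion, so objects
  touching the border erode — the standard convention.
* **Opening consequences.** Opening never adds foreground, so per-slice TP
  and FP are non-increasing: specificity and PPV can only rise, sensitivity
  and NPV can only fall. The tests assert exactly these directions.
* **Ties in voting.** `3.5Dv4` uses $k=3$ of 4: a 2–2 tie is negative.
  Conservative ties suit the false-positive-removal goal; `k` is
  configurable.
* **Undefined metrics.** Per slice, sensitivity is undefined without
  ground-truth positives, PPV without predicted positives, specificity/NPV
  without the respective negatives; undefined slices are excluded from that
  metric's aggregate. One rule is fixed: predicted foreground on a slice with
  empty ground truth gives DSC = 0 (the formula's $0/FP$), which is what
  penalises stray speckles on tooth-free slices. For slices empty in both,
  DSC scores 1 under the default policy (`dscEmpty = "one"`; no error is
  perfect agreement) or is dropped under `"exclude"` — both are implemented
  because either reading of "averaging the performance of every slice" is
  defensible, and aggregates report the number of contributing slices.
  Slices are pooled across volumes by default; per-patient averaging is a
  row-bind away since `aggregateSlices` consumes plain data frames.
* **Callback windows.** The plateau/early-stop counters treat the first
  epoch's validation loss as the baseline and count it toward the stall
  window: a frozen loss decays the learning rate at epochs 10, 20, … and
  stops training at epoch 50. `plateauSchedule` replays the arithmetic on
  any loss trajectory for auditing.
* **Wilcoxon exactness.** For $\le 25$ non-zero paired differences the
  two-sided p comes from the exact sign-flip permutation distribution of the
  positive-rank sum built by subset-sum convolution on doubled midranks, so
  ties in the absolute differences are handled exactly; larger samples use
  the tie-corrected normal approximation. The Kruskal–Wallis post hoc is
  Dunn's z on pooled ranks with Bonferroni adjustment (36 pairs for 9
  models), and the normality screen is the Lilliefors-corrected KS test
  since the reference normal has estimated parameters.
* **U-Net upsampling** is nearest-neighbour followed by a convolution.
  Inputs are intensity-normalised by clamping to $[-1000, 3100]$ HU and
  scaling to $[0,1]$. Binarisation at 0.5 equals softmax argmax with
  foreground ties.

## What the phantom emulates — and what it does not

`makePhantom` builds a 64³ voxel, 0.19 mm isotropic volume: an air
background, an elliptical soft-tissue head section (50 HU), a parabolic bone
arch (1200 HU) and six tooth units — a dentin root cylinder (2000 HU, radius
2.5 voxels, length 12) under an enamel crown ellipsoid (2800 HU, semi-axes
3.5/3.5/4.5) — plus additive Gaussian noise (SD 30 HU). The tooth
cross-sections are wide enough to survive a radius-2 opening, as real teeth
are at CBCT resolution; `addMetal` converts crown-adjacent voxels to 3100 HU
so MDB screening can be exercised with exact counts. The 64³ size keeps a
hundred-replicate simulation on one CPU in seconds while leaving dozens of
axial slices per volume.

`degradePrediction` corrupts the ground truth with the three error modes a
single model shows on real scans: Poisson-planted false-positive speckles
(radius-1 balls, i.e. 7 voxels — strictly smaller than the radius-2 opening
element, so E&D provably removes them, and placed at least one speckle radius
clear of the truth), partial false-negative dropout of tooth components, and
boundary jitter. `simulatePredictionSet` realises inter-voter correlation
$\rho$ by Poisson thinning: a shared error stream at rate $\rho\lambda$ is
applied to every voter plus private streams at $(1-\rho)\lambda$, so
$\rho=0$ gives independent voters and $\rho=1$ identical ones. This is a
simulation convention, not a claim about real model correlation.

The phantom does **not** emulate beam hardening, streaks, ring artefacts,
partial-volume effects or anatomical tooth shapes. Passing the simulation
suite therefore demonstrates the *mechanisms* — that majority voting
suppresses independent false positives at the binomial-tail rate, that
opening removes sub-element speckles with the stated metric directions, that
the evaluation arithmetic is exact — not that any particular DSC level will
be reached on patient scans, where voter errors are correlated and anatomy
is harder.

## Problem sizes used for validation

The shipped checks run at desk scale, chosen so the whole suite and the
acceptance script each complete in a few minutes on one CPU: voting and
morphology oracles on exhaustive bit patterns and 12³–16³ random grids; the
analytic-vs-empirical false-positive comparison on 10⁶ background voxels;
ensemble-benefit and E&D-direction simulations on 100 and 20 seeded 64³
phantom replicates; statistical-test calibration on 2000 null replicates of
n = 50; and U-Net training smoke tests with a depth-2, 8-feature network on
32×32 axial slices of a 32³ phantom (the reference depth-4, 512×512
configuration is exposed as defaults but not trained in the tests). Under
those conditions the five-voter vote beat the best individual voter in 100
of 100 replicates and the trained reduced U-Net reaches a training-set
slice DSC above 0.8 within 30 epochs; `scripts/acceptance.R` recomputes all
of these quantities from scratch.

## Known limitations

* The bundled U-Net trains on one CPU in pure R; it is meant for validation
  and small studies, not for full-resolution clinical training runs. The
  predictor contract (aligned probability or binary masks) is the intended
  integration point for external models.
* DICOM support covers uncompressed little-endian single-frame series
  (explicit or implicit VR) without undefined-length sequences; convert
  anything else to NIfTI/NRRD first.
* Voting operates on binarised masks, as the ensemble design prescribes;
  probability-level fusion (averaging, STAPLE) is out of scope.
* `semiautoContour` is the batch counterpart of an interactive workflow:
  polygon ROIs and thresholds must be supplied programmatically.
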