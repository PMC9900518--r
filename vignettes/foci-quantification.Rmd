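---
title: "Quantifying the DNA-damage response: nuclear foci, lesion frequencies and colocalization"
author: "fociQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the DNA-damage response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociQuant)
```

## What the package measures

Cells mark DNA double-strand breaks (DSBs) with punctate nuclear
accumulations — *foci* — of repair factors: 53BP1 foci indicate engagement
of non-homologous end joining, Rad51 foci indicate homologous
recombination, and phosphorylated H2AX (γH2AX) marks break sites
themselves. Counting bright foci per nucleus before and after a genotoxic
challenge, and expressing the change as a fold change over the
pre-treatment baseline, is a standard readout of DSB signalling.

`fociQuant` implements the three quantification tasks that usually
surround such an experiment:

1. **Foci counting** from multi-plane fluorescence z-stacks (7--9 planes
   at ~0.8 µm is the acquisition regime the defaults assume), producing
   per-nucleus, per-field and per-well tables and fold changes.
2. **Lesion-frequency estimation** from long-amplicon qPCR (LA-qPCR)
   band intensities, expressed as lesions per 10 kb via Poisson
   zero-class inversion.
3. **Colocalization and intensity readouts**: nuclear-masked Pearson
   correlation between two channels, and marker intensity normalized to
   the DAPI nuclear stain.

Every stage can be validated against the package's own synthetic-scene
generator, which plants nuclei and foci with known ground truth.

## The imaging pipeline

The processing chain for each imaged field is deliberately simple and
fully deterministic:

1. **Bilateral smoothing, per plane.** Each z-plane is filtered with an
   edge-preserving Gaussian bilateral filter before any projection, so
   noise is suppressed without blurring focus edges. Weights are the
   product of a spatial Gaussian (`sigmaSpatial`, default 2 px) and a
   range Gaussian (`sigmaRange`, default 0.1 × the plane's dynamic
   range); the window (half-width `2 * ceiling(sigmaSpatial)`) is
   truncated at image borders rather than padded, so no pixel values are
   invented. Output is always inside the local min/max envelope — the
   filter cannot overshoot.
2. **Maximum intensity projection (MIP).** Per-pixel maximum over
   planes. Smoothing strictly precedes projection.
3. **Normalization.** The MIP is mapped linearly to [0, 1]. A constant
   (blank) field becomes all zeros with a warning instead of an error so
   control plates flow through.
4. **Nucleus segmentation.** The nuclear-channel MIP is binarized at a
   per-pixel threshold
   `blend * localMean + (1 - blend) * globalOtsu`.
   Otsu's threshold maximizes between-class variance over a 256-bin
   histogram; class means use exact per-bin intensity sums, so the
   result equals an exhaustive search over bin edges (ties break toward
   the lower edge). The default `adaptiveBlend = 0` is pure global Otsu —
   transparent and adequate for evenly illuminated fields; raising the
   blend engages local-mean adaptation for uneven illumination. Holes
   are then filled (background traversed 4-connected, the complement of
   the 8-connected foreground), components outside the area window
   (defaults 200--20,000 px²) are discarded, and border-touching nuclei
   are dropped by default because clipped nuclei bias per-nucleus
   counts. Holes are filled *before* the area filter so each recorded
   area is the void-free pixel count of its label. Touching nuclei are
   *not* split; the method relies on sub-confluent fields.
5. **Focus detection.** On the normalized foci-channel MIP, the
   extended-maxima transform marks peaks whose prominence exceeds `h`:
   the h-maxima transform is the greyscale morphological reconstruction
   of `I - h` under `I` (computed with the hybrid raster + queue
   algorithm, which reaches the same fixpoint as iterated geodesic
   dilation), and its regional maxima — equal-valued plateaus with
   strictly darker borders — form the focus mask. The mask is invariant
   to additive intensity offsets, and the component count can only
   shrink as `h` grows. Components are filtered by area (defaults 2--200
   px²) and assigned to the nucleus containing their intensity-weighted
   centroid; detection runs on the whole field (not masked to nuclei)
   so near-boundary maxima are not clipped, and extranuclear foci are
   reported but never counted.
6. **Aggregation.** Per-well statistics pool fields — total foci over
   total nuclei — rather than averaging per-field means, so sparsely
   populated fields do not dominate. Fold change is the ratio of pooled
   means, treated over baseline, and is undefined (an error) when the
   baseline mean is zero or the baseline well is empty.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `sigmaSpatial` | 2 | px | mild smoothing below nucleus scale |
| `sigmaRange` | 0.1 × dynamic range | intensity | preserves focus edges (steps ≫ noise) |
| `adaptiveBlend` | 0 | — | pure Otsu unless illumination is uneven |
| `minNucleusArea`, `maxNucleusArea` | 200, 20000 | px² | set from geometry in real use |
| `h` | 0.1 | [0,1] intensity | peak prominence on the normalized scale |
| `minFocusArea`, `maxFocusArea` | 2, 200 | px² | rejects 1-px noise spikes, giant blobs |
| `minDynamicRange` | 0.05 | intensity | blank-field guard: a flat image has no peaks |

The flat-field guard exists because the regional-maxima definition
degenerates on a constant image: the whole field is one maximal plateau.
Blank control fields therefore return zero foci rather than one
field-sized "focus" (the focus area filter provides a second line of
defence).

## LA-qPCR lesion frequencies

Lesions block the polymerase, so only zero-lesion template molecules
amplify. If lesions are Poisson-distributed along the template with rate
λ per amplicon, the amplifiable fraction is `P(0) = exp(-λ)`. The
pipeline therefore computes, per gene,

* relative amplification
  `rel = (treated long/short) / (control long/short)` — the short
  amplicon (0.192--0.286 kb vs 10.4--12.2 kb for the long ones) serves
  as loading control because a ~50× shorter fragment has a
  correspondingly lower probability of containing a break; the vehicle
  control is set to unity by construction;
* `λ_amplicon = -log(rel)` and `lesions/10 kb = λ_amplicon × 10 / L`
  with `L` the long-amplicon length in kb.

Replicates are inverted individually and summarized as mean ± SEM per
gene × condition; no significance testing is performed. Two deliberate
choices:

* `rel > 1` (treated amplifying better than control, i.e. noise) yields
  a *negative, flagged* estimate instead of clamping to zero, so the
  noise structure of an experiment stays visible in the replicate table.
* The short amplicon is treated as perfectly lesion-free by default.
  This understates the rate by the factor `(L - L_short)/L` (≈ 1.6--2.8%
  at the assay lengths above); `correctShort = TRUE` models the short
  fragment's own zero-class and removes that bias exactly. It is off by
  default because the uncorrected ratio is what the band-normalization
  convention defines.

## Colocalization and intensity ratios

`pearsonWithinMask()` computes the sample Pearson correlation of two
channels over masked pixels only (typically the union of nucleus
labels). It is invariant under positive affine transforms of either
channel and errors — naming the offending channel — when one channel is
flat within the mask. No Costes randomization or Manders coefficients
are computed, and no background subtraction is applied before
correlating. `intensityRatio()` reports, per nucleus, mean marker
intensity over mean DAPI intensity, flagging (and excluding from the
pooled mean) nuclei with zero DAPI signal.

## The synthetic-scene generator

`simulateScene()` emulates the acquisition regime at desk scale so that
segmentation and counting can be validated against exact ground truth:

* **Geometry.** Non-overlapping axis-aligned ellipses stand in for
  nuclei (radii 12--18 px by default) — the simplest shape family that
  still exercises area filtering and hole filling. Placement retries up
  to 500 times per nucleus and fails loudly when the field cannot host
  the request; a feasibility check in `sceneConfig()` rejects clearly
  impossible configurations up front.
* **Foci.** Planted inside their nucleus (with a margin), at a minimum
  mutual separation (default 4 px), with axial positions spread across
  the inner planes so the MIP step is consequential (axial sigma 1.2
  planes). Laterally a focus is a *flat-core* disc (radius 1 px) with a
  Gaussian skirt (sigma 0.8 px): repair foci are sub-micron chromatin
  domains, not point sources, and a finite core is what makes the
  h-maxima plateau of a focus robustly larger than a single pixel.
* **Intensities and noise.** Arbitrary detector units: background 100,
  nuclear signal 400, focus amplitude 300 above the local level, with
  Poisson shot noise and additive Gaussian read noise (sd 10) — the two
  standard fluorescence noise components; both can be switched off.
  15% of the nuclear signal bleeds into the foci channel as the dim
  nuclear outline typical of reporter lines.
* **Determinism.** Every generator is a pure function of its
  configuration including the seed.

What the generator does **not** model: optics (no PSF convolution beyond
the focus profile itself), photobleaching, nucleus-to-nucleus intensity
variation, touching or overlapping nuclei, and 3-D segmentation truth
(the pipeline is 2-D after projection). Passing the ground-truth
recovery tests therefore demonstrates correctness of the *algorithms*
under a realistic noise model, not robustness to every property of real
micrographs — segmentation parameters still need tuning on real data.

`simulateColocPair()` draws masked pixel pairs from a bivariate normal
via `B = ρA + sqrt(1 - ρ²)ε`, so the target correlation is exact in
expectation and `ρ = 1` gives a perfect affine copy.
`simulateLAqPCR()` is molecule-level: each of `n` molecules draws
Poisson lesion counts for the long and short amplicon independently and
band intensity is the zero-lesion fraction (floored at `0.5/n` to keep
recorded intensities positive) times log-normal multiplicative noise of
a given CV.

## Numerical choices and degenerate inputs

* Reconstruction, regional maxima, labeling and hole filling are exact
  integer/float algorithms with no tolerances; reconstruction's hybrid
  implementation is tested for exact equality against the iterative
  geodesic-dilation definition.
* Otsu ties break toward the lowest candidate edge; thresholding uses
  `>=`, so the upper mode of a two-valued image is always foreground.
* Constant images: `normalize01` warns and returns zeros;
  `otsuThreshold` errors (the caller handles blank fields);
  `segmentNuclei` returns zero nuclei; `extendedMaxima` returns an
  empty mask via the dynamic-range guard.
* Focus→nucleus assignment rounds the intensity-weighted centroid to
  the nearest pixel; a focus straddling the boundary is counted iff
  that pixel carries the nucleus label.
* Label ids are assigned in column-major first-encounter order, making
  every table deterministic; per-nucleus counts are invariant to label
  renumbering.

## Problem sizes used in validation

The test-suite and acceptance runs use 400 × 400 px fields with 22
nuclei (the package's desk-scale choice; real fields held > 100 cells at
full resolution and the generator default is 512 × 512 with 25), 4
fields per simulated well, Poisson-distributed planted counts (mean 2)
for recovery checks, and fixed 1 vs 4 foci per nucleus for the
fold-change experiment. LA-qPCR recovery uses 100,000 molecules per
band, 2% band noise, and rates between 0.2 and 2 lesions/10 kb at both
assay amplicon lengths. Oracle-equivalence checks run on ≥ 100 random
images up to 32 × 32 against brute-force reference implementations.

## Known limitations

* No watershed splitting: confluent fields under-segment, which inflates
  areas past `maxNucleusArea` and silently drops those cells.
* "Adaptive" thresholding is a blend of global Otsu and a local mean;
  other adaptive schemes (per-tile Otsu, sensitivity-scaled Otsu) fall
  outside the blend parameterization.
* The extended-maxima `h` is a single global prominence: dim foci below
  `h` on the normalized scale are invisible, and no per-nucleus
  brightness adaptation is attempted.
* Lesion estimation assumes the PCR stays in its linear range, as the
  assay design requires; saturated bands violate the zero-class model.
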