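# fociQuant

Quantification of DNA-damage-response readouts in R, for labs measuring
double-strand-break (DSB) signalling and repair-pathway choice:

* **Nuclear foci counting** — bright 53BP1 / γH2AX / Rad51 foci per
  nucleus from multi-plane fluorescence z-stacks, and the fold change in
  foci per nucleus after a genotoxic challenge.
* **LA-qPCR lesion frequencies** — DNA lesions per 10 kb from
  long-amplicon qPCR band intensities.
* **Colocalization** — Pearson correlation of two channels restricted to
  the nuclei, and marker intensity normalized to DAPI.

A seeded synthetic-scene generator with exact ground truth
(`simulateScene()`, `simulateLAqPCR()`, `simulateColocPair()`) makes
every stage verifiable without microscopy or gel data.

## The methods in brief

**Imaging.** Each z-plane is smoothed with an edge-preserving Gaussian
bilateral filter, the stack is collapsed to a maximum intensity
projection (MIP), and intensities are normalized to [0, 1]. Nuclei are
segmented from the nuclear-channel MIP by Otsu's threshold (optionally
blended with a local-mean threshold for uneven illumination), hole
filling and an area filter. Foci are detected on the foci-channel MIP
with the extended-maxima transform — the regional maxima of the
h-maxima transform `hmax(I) = reconstruct(I - h, I)` — filtered by
area, and assigned to the nucleus containing their intensity-weighted
centroid. Wells aggregate by pooling: mean foci per nucleus =
Σ foci / Σ nuclei, and

```
fold change = mean foci/nucleus (treated) / mean foci/nucleus (baseline)
```

**LA-qPCR.** Lesions block the polymerase, so the amplifiable fraction
of template molecules is the Poisson zero class `P(0) = e^(-λ)`. With
`rel` the long/short band ratio of a treated sample over that of the
vehicle control (control ≡ 1),

```
λ_amplicon = -ln(rel),   lesions per 10 kb = λ_amplicon · 10 / L_kb
```

with `L_kb` the long-amplicon length (HPRT 10.4 kb, POLB 12.2 kb;
shorts 0.286 / 0.192 kb serve as loading controls).

## Worked example

Simulate a baseline well (1 planted focus/nucleus) and a treated well
(4 planted foci/nucleus), two fields each, and run the full pipeline:

```r
library(fociQuant)
tmp <- tempfile(); dir.create(tmp)
for (s in 1:2)
  writeScene(simulateScene(sceneConfig(fieldShape = c(256, 256), nNuclei = 8,
    fociPerNucleus = 1, seed = s)), file.path(tmp, "baseline"), sprintf("f%02d", s))
for (s in 11:12)
  writeScene(simulateScene(sceneConfig(fieldShape = c(256, 256), nNuclei = 8,
    fociPerNucleus = 4, seed = s)), file.path(tmp, "treated"), sprintf("f%02d", s))

res <- runFociPipeline(file.path(tmp, "baseline"), file.path(tmp, "treated"),
                       file.path(tmp, "report"))
res$perWell
#>   condition       well nNuclei nFoci meanFociPerNucleus
#> 1  baseline baseline01      16    16              1.000
#> 2   treated  treated01      16    62              3.875
res$foldChange
#>   treatedWell baselineWell baselineMean treatedMean foldChange
#> 1   treated01   baseline01            1       3.875      3.875
```

All 16 baseline nuclei are found with exactly their planted focus
(mean 1.000); the treated well reads 3.875 foci/nucleus, i.e. a measured
fold change of 3.875 against a planted truth of 4 (two of the 64 planted
foci are lost to detection at this field size). The per-nucleus and
per-field tables, and a parameter log, are written to `report/`.

Lesion frequencies invert analytically — a relative amplification of
`exp(-1.22)` on the 12.2 kb POLB amplicon is exactly one lesion per
10 kb:

```r
lesionsPer10kb(exp(-1.22), 12.2)
#>   relativeAmplification lambdaAmplicon lesionsPer10kb flagged
#> 1             0.2952302           1.22              1   FALSE
```

And colocalization within segmented nuclei recovers a planted channel
correlation of 0.9:

```r
sc <- simulateScene(sceneConfig(fieldShape = c(256, 256), nNuclei = 8,
                                fociPerNucleus = 0, seed = 2))
nuc <- segmentNuclei(normalize01(maxIntensityProjection(smoothStack(sc$nuclear))))
pair <- simulateColocPair(labelImage(nuc) > 0, 0.9, seed = 4)
pearsonWithinMask(pair$a, pair$b, nuc)
#>    pearsonR nPixels maskSource
#> 1 0.8975557    6086     nuclei
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fociquant-cli.R` (subcommands `simulate-scene`,
`simulate-laqpcr`, `foci-run`, `lesions-run`, `coloc-run`).

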