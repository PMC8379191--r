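# mamspat

Spatial quantification of brightfield H-DAB immunohistochemistry from
the developing mammary gland, with a synthetic terminal duct lobular
unit (TDLU) simulator that plants known ground truth so the entire
analysis chain is testable end to end.

The package is aimed at quantitative pathology / tissue image analysis
work on questions like these: is epithelial proliferation (nuclear
Ki67) polarised towards the advancing tips of developing TDLUs? Are
intraepithelial macrophages (IBA1+) periodically spaced along ducts,
and does their spacing differ between age groups? Are stromal
macrophages denser centrally than peripherally? Do stromal B/T
lymphocyte aggregates organise into tertiary lymphoid structures?

## What it implements

* **Synthetic H-DAB fields** (`simConfig()`, `generateField()`,
  `assignKi67()`, `renderField()`): lobules along a growth axis with
  two-layer ducts/ductules, axis-polarised Ki67, arc-periodic
  intraepithelial macrophages, central/peripheral stromal macrophage
  densities, T cells, TLS, Beer-Lambert rendering with pixel-perfect
  label masks.
* **Macenko stain handling** (`rgbToOD()`, `estimateStainMatrix()`,
  `normalizeToReference()`): stain-matrix estimation by SVD of the OD
  cloud and percentile angles; colour normalisation through robust
  maximum concentrations.
* **Segmentation** (`segmentNuclei()`, `segmentEpithelium()`,
  `extractCentroids()`): a deterministic classical pipeline producing
  the binary epithelium mask and mutually exclusive Ki67+/Ki67-
  nucleus label maps (the same mask contract as the trained networks
  used on real slides), plus centroid records.
* **Getis-Ord GI\*(d) hotspots** (`gridDiscretise()`, `getisOrd()`,
  `permutationNull()`, `hotspotMask()`, `polarisationIndex()`): grid
  counts, the self-excluded local ratio

  `G_i(d) = sum_{j!=i} w_ij(d) x_j / sum_{j!=i} x_j`,

  its conditional-randomisation moments `E = W_i/(n-1)` and variance,
  z-scores, an exhaustive/sampled permutation null (compiled kernel),
  hotspot masks at `Z >= 1.96`, and a leading-edge polarisation index.
* **Quantification** (`ki67EpithelialRatio()`, `detectPeriodicRuns()`,
  `interMacrophageDistances()`, `placeCountBoxes()`,
  `classifyBoxLocation()`, `countCellsInBox()`, `immuneDensities()`,
  `detectTLS()`): the epithelial Ki67+:Ki67- pixel-area ratio,
  periodicity runs (at least 4 positions, gap CV <= 0.3) with
  arc-length spacing, blinded 400 x 230 um count boxes with the
  >50% / top-right-edge counting rule, central/peripheral
  classification, immune densities, and TLS detection (B core with a
  distinct adjacent T zone).
* **Group statistics** (`dagostinoTest()`, `mannWhitney()`,
  `pairedT()`, `compareGroups()`, `emulateMeasurementTables()`): the
  D'Agostino-Pearson normality gate, exact/approximate two-tailed
  Mann-Whitney, paired t, and a per-animal measurement-table emulator
  for the 13-lamb two-age-group design.
* **Pipeline** (`validateConfig()`, `runPipeline()`): one call from
  configuration to `stats_report.csv`, deterministic given the seed.

## A worked example

```r
library(mamspat)

## simulate a young (< 2 months) field and render the Ki67 IHC
cfg <- simConfig(seed = 1)
gt  <- generateField(cfg, "young")
img <- renderField(gt)

## estimate stains, segment, extract centroids
sm  <- estimateStainMatrix(img)
ms  <- segmentEpithelium(segmentNuclei(img, sm))
cent <- extractCentroids(ms)

ki67EpithelialRatio(ms)$ratio
#> [1] 0.5826309

## hotspot map of epithelial Ki67+ nuclei, d = 250 px at full scan
## scale (62.5 px here), and its polarisation along the growth axis
pos <- cent[cent$phenotype == "ki67_pos" & cent$epithelial, ]
g   <- gridDiscretise(pos, c(1580, 1145), 12.5, "ki67_pos")
go  <- getisOrd(g, 62.5)
pol <- polarisationIndex(hotspotMask(go, 1.96),
                         gridAxisCoord(go, gt@lobules))
pol$index
#> [1] 0.6049544

## macrophage periodicity: pooled arc-length spacing (planted 60 um)
mean(fieldMacrophageDistances(gt))
#> [1] 58.52605

## the 13-animal age contrast on emulated per-animal tables
tab <- emulateMeasurementTables(seed = 1)
compareGroups(tab, "inter_macrophage_distance_um")$p.value
#> [1] 4.946833e-65
```

The Ki67 ratio is the pixel-area ratio of Ki67+ to Ki67- nuclei
inside the epithelium mask (the planted truth for this field is
0.609). A polarisation index of 0.60 means 60% of significant Ki67
hotspot cells lie on the leading half of their lobule (0.5 = no
polarisation). The spacing mean recovers the planted 60 um
intraepithelial macrophage spacing, and the Mann-Whitney on the
emulated 13-animal table reproduces the expected strongly significant
young-versus-old spacing contrast.

## Documentation

The methods vignette (`vignettes/mamspat-methods.Rmd`) describes the
models, parameter choices, numerical conventions and limitations in
detail.
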