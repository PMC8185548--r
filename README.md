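# cellquant

Per-cell quantification of Proximity Ligation Assay (PLA) fluorescence and
K-means scoring of calreticulin localization in brightfield IHC, with the
nonparametric statistics applied to their outputs and seeded synthetic-scene
generators that give every stage a known ground truth.

## The problem

A PLA produces punctate fluorescence wherever two antibody-tagged proteins
sit within ~40 nm of each other, so the integrated signal per cell proxies
the abundance of a protein–protein interaction (e.g. CD47 with the chemokine
receptor CXCR4). Without a membrane stain there is no cell boundary to
integrate over, so the signal must be attributed to cells from the nuclear
channel alone:

1. **Nuclear mask** — pixels of the Hoechst channel strictly above
   `mean(I) + k · sd(I)` (population SD over the image, default `k = 2`).
2. **Watershed split** — seeds at local maxima of the Euclidean distance
   transform, thinned to a minimum separation, then region growing inside
   the mask; touching nuclei become separate labels. Components outside a
   size window are discarded as artifacts; survivors are renumbered
   deterministically in raster order.
3. **Territories** — each nucleus is dilated by a Euclidean disk
   (default radius 100 px = 8.5 µm), giving a nucleus + perinuclear ring
   that covers most of the cell's footprint.
4. **Even splitting** — a pixel covered by *m* territories contributes
   weight `1/m` to each cell involved, so summed weights over any covered
   pixel equal 1 and overlap handling conserves total intensity.
5. **Per-cell intensity** — for background *b* (median of all pixels
   outside every territory, overridable),

   corrected(c) = Σ_{p ∈ T_c} w(p, c) · (I(p) − b).

For IHC, RGB pixels of a tile are clustered with K-means (`K = 4`,
k-means++ starts, Lloyd iterations): the brightest centroid is the bare
slide, the centroid nearest a configurable reference DAB brown is
calreticulin-positive, and the **fraction of calreticulin-negative tissue
pixels** is the localization score — diffuse cytoplasmic staining gives a
low fraction, membrane-restricted ecto-calreticulin a high one.

Group comparisons use the two-sided Fisher exact test (probability-mass
convention), Mann–Whitney and two-sample Kolmogorov–Smirnov, wrapped with
explicit exact/approximate path selection.

## Worked example

```r
library(cellquant)

sc  <- simulatePLAScene(seed = 1, nNuclei = 5, nTouchingPairs = 1)
res <- runPLAPipeline(sc$hoechst, sc$pla, ringRadiusPx = 17, verbose = TRUE)
#> [segment] threshold = 1315, n_cells = 7
#> [quantify] background = 200.3, covered px = 14192 (15.7% shared)
res$cells[, c("cell_id", "territory_area_px", "corrected_intensity")]
#>   cell_id territory_area_px corrected_intensity
#> 1       1            1812.3             51532.1
#> ...
#> 7       7            2287.0             53651.6
perCellDistribution(res$cells, "control")
#> ConditionDistribution 'control': n = 7, mean = 49857.1, SD = 2165.98
```

Seven nuclei are found (five isolated plus a touching pair split by the
watershed), the estimated background (200.3) matches the generated level
(200), and each cell's corrected intensity recovers the generated per-cell
total of 50,000 counts; the two cells of the touching pair have smaller
weighted territory areas because their shared pixels count half for each.

```r
tile <- simulateIHCScene(seed = 2, positiveFraction = 0.3)
classifyIHC(tile$rgb, seed = 2)
#> IHCClassification: K = 4, positive class 1, background class 3
#>   tissue px: 49152, positive px: 14746, negative fraction: 0.7000

fisherExact2x2(rbind(c(4, 16), c(15, 5)))
#> Fisher exact test, two-sided (probability-mass)
#>   statistic = 0.0902024, two-sided p = 0.00123186 (n = 20, 20)
```

A tile built with 30% DAB-positive tissue is scored at a negative fraction
of 0.700, and the 4/20 vs 15/20 tumour-rejection table gives p = 0.0012.

A command-line front end over the same functions lives at
`inst/scripts/cellquant.R` (`simulate pla|ihc`, `segment`, `quantify-pla`,
`quantify-ihc`, `stats fisher|mw|ks`, `run --config cfg.yaml`).

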