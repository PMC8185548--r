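---
title: "Per-cell PLA quantification and IHC localization scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell PLA quantification and IHC localization scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellquant)
```

# Overview

`cellquant` implements two image-quantification procedures and the
statistics applied to their outputs:

* **Per-cell PLA intensity**: nuclei segmented from the Hoechst channel
  (global mean + 2 SD threshold, seeded watershed on the distance
  transform, size filter), a perinuclear ring territory per cell
  (disk dilation, 100 px / 8.5 µm by default), even splitting of pixels
  covered by several territories, and background-corrected intensity sums.
* **IHC calreticulin localization**: K-means colour clustering (K = 4) of
  raw RGB pixels, identification of the DAB-positive and white-background
  classes, and the fraction of calreticulin-negative tissue pixels.

Because quantification pipelines of this kind are usually validated
against manual annotation that does not exist for synthetic-free data, the
package ships seeded scene generators with exhaustive ground truth; every
claim the test suite makes is a claim about recovery of known truth.

# The PLA model and its assumptions

The method attributes signal to cells without a membrane stain. Its
assumptions, made explicit:

1. Nuclei are the only bright structures in the Hoechst channel, so a
   global threshold at `mean + k·sd` isolates them. The SD is the
   **population** SD over all pixels of that image (at image scale the
   sample/population distinction is immaterial, but it must be fixed for
   bit-reproducibility), and the statistics are computed **per image**,
   not per experiment. The mask comparison is **strictly greater**, which
   makes the constant-image case unambiguous (empty mask).
2. A disk dilation of the nucleus (the "ring") covers most of the cell's
   surface, so the nucleus ∪ ring territory captures most of that cell's
   PLA signal. The default radius of 100 px corresponds to 8.5 µm at the
   0.085 µm/px of the original acquisitions; `buildTerritories()` can
   derive the pixel radius from a physical radius and the image's pixel
   size instead (`preferPhysical = TRUE`, rounded to nearest integer).
   "Ring of 100 pixels" is read as a dilation *radius*; the alternative
   reading (an annulus of 100 px thickness around the nucleus) is the
   same morphological operation, so only the radius interpretation is
   exposed.
3. Where territories overlap, the pixel's intensity is divided **evenly**
   among the m cells involved (weight 1/m each). Nuclei are not special:
   a pixel inside nucleus B that falls within ring A has m = 2. The even
   split conserves intensity exactly — the per-pixel weights sum to 1 —
   so the summed per-cell values always equal the background-subtracted
   total over the covered area. The split is even, not proportional to
   any distance or intensity model; for two cells with similar signal
   density in the shared region the attribution error cancels in
   expectation, but individual scenes fluctuate (see *Validation design*).
4. Background is spatially uniform. The default estimator is the
   **median of all pixels outside every territory** — robust to stray
   puncta; mode and percentile estimators and an explicit value are
   available. Negative residuals after subtraction are **not clamped**:
   clamping would break the conservation identity and bias sums upward.
5. Cells whose territory is clipped by the image border are **flagged**
   (`touches_border`) but not excluded; exclusion policy is left to the
   analyst.

# Segmentation details

* Watershed flavour: seeds are local maxima of the Euclidean distance
  transform of the mask, thinned greedily (strongest first, ties broken by
  raster position) to a minimum pairwise separation, then grown inside the
  mask (`EBImage::propagate`). The default separation is 0.7 × the median
  equivalent radius (√(A/π)) of the pre-watershed components — small
  enough to place two seeds in a touching pair of nuclei, large enough not
  to shatter a single nucleus.
* Size filter defaults are relative: components outside 25%–400% of the
  median post-watershed component area are removed. Absolute bounds can be
  set in `segmentationParams()`.
* Holes are filled by default, so dim chromocenters do not punch holes
  into nucleus intensity sums.
* Components are 8-connected; labels are renumbered 1..n by raster-scan
  order of each region's top-left pixel, so a rerun on the same input
  produces an identical `LabelMap`. Coordinates are row-major and
  pixel-centred.
* An image with nothing above threshold yields a valid empty label map,
  not an error.

# The IHC model

Pixels are clustered in raw RGB space (no optical-density transform),
K = 4 by default: DAB brown, hematoxylin blue, white slide, and one
intermediate/mixed class. Lloyd iterations start from k-means++ seeds;
10 restarts keep the lowest within-cluster sum of squares; centroids are
fitted on a uniform random subsample of at most 2×10⁵ pixels (identical in
expectation, seed-reproducible) and all pixels are then assigned to their
nearest centroid, ties to the lowest index. Iterations run to an
assignment fixed point (cap 300), which is at least as strict as a
centroid-shift tolerance.

Class identities are not part of K-means, so two rules are applied:
the **background** class is the centroid with maximum luminance
(0.299 R + 0.587 G + 0.114 B), and the **positive** class is the
non-background centroid nearest a configurable reference DAB colour
(default RGB (120, 80, 45); a parameter because chromogen hue varies
between stains and scanners). The localization score is

negative fraction = #(tissue pixels ∉ positive class) / #(tissue pixels),

with tissue = non-background. Restricting the denominator to tissue makes
the score independent of how much bare slide the tile contains; computing
it over whole images would make it mount-area-dependent.

# Statistics

* `fisherExact2x2()`: exact hypergeometric test, two-sided by the
  **probability-mass** convention (sum of all tables with the observed
  margins whose probability does not exceed the observed table's, with a
  1e-7 relative slack on the comparison). Under this convention the
  published tumour-rejection table 4/20 vs 15/20 gives p = 0.0012. The
  doubled-one-tail convention is exposed behind
  `convention = "doubled-tail"` but is not the default.
* `mannWhitneyU()`: midrank U; exact enumeration when the pooled size is
  ≤ 16 with no ties, otherwise the normal approximation with tie and
  continuity corrections. All-identical samples return p = 1.
* `ksTwoSample()`: sup-distance D between ECDFs; exact permutation path
  when pooled size ≤ 16 and tie-free, otherwise the asymptotic Kolmogorov
  distribution at effective size mn/(m+n).

A calibration caveat the test suite makes explicit: at n = 20 per group
the two-sample KS statistic takes values k/20 only. The discrete rejection
region nearest nominal 5% has null mass ≈ 3.4%, and the next one ≈ 8%, so
*no* valid KS p-value — exact or asymptotic — can have size close to 5%
at this sample size; the test is conservative there by construction.
Mann–Whitney, whose statistic is much less discrete at n = 20, calibrates
to nominal. The acceptance suite records both empirical sizes as measured.

# What the generators emulate — and what they do not

`simulatePLAScene()` renders round nuclei as hard disks smoothed by a
σ = 1 px Gaussian (a sharp, deterministic recovery target for the
threshold), puncta as Gaussian spots whose centres fall uniformly in the
cell's nucleus ∪ ring footprint (shrunk by 3 spot sigmas so tails stay
inside) and whose rendered per-cell sum equals the requested total
exactly, plus uniform background and additive Gaussian noise clipped at
zero on a 16-bit-style count scale. Touching pairs are placed at 1.5
nucleus radii and declared in the truth; an undeclared overlap is an
error, because its ground truth would be ambiguous.

Default study conditions, chosen once as a desk-scale version of a
confocal field and not revisited: 256 × 256 px at 0.5 µm/px; nucleus
radius 10 px (5 µm); ring 17 px (8.5 µm — the physical ring width at this
pixel size); nucleus plateau 3000 counts over background 200 with noise
SD 60; 50,000 counts of PLA signal per cell in 20 puncta of σ = 1.2 px.
The acquisition noise of the original microscope is unknown; additive
Gaussian noise is a stand-in, not an inference.

Not modelled: point-spread-function optics, uneven illumination,
out-of-focus light, nucleus shape variation, spatial texture in IHC tiles
(class positions are a random permutation — K-means is blind to
arrangement), and stain physics. Passing tests therefore demonstrate
algorithmic correctness against the stated model, not robustness to every
artifact of real micrographs.

`simulateIHCScene()` builds tiles with exact per-class pixel counts (the
truth fraction is exact by construction), Gaussian per-channel colour
noise, clamping to [0, 255] and integer rounding. Tiles whose minimum
pairwise class-colour distance is not larger than 6 × the noise SD are
flagged non-separable and warned about. The intermediate class is
parameterised as a share of the *non-DAB* tissue so that any positive
fraction in [0, 1] is a valid input.

# Validation design and problem sizes

The test and acceptance suites run entirely on generated scenes:

* conservation and brute-force-oracle equivalence on twenty 128 × 128
  scenes containing a touching pair and wide rings (forced overlaps);
* parameter recovery on scenes with four nuclei on a fixed grid 128 px
  apart, so territories are disjoint and every count is attributable to
  exactly one cell. This isolates the quantifier: under territory
  *overlap* the even-splitting rule redistributes signal between the
  cells involved (conserving the total — that behaviour is what the
  conservation and oracle checks measure), so overlapping scenes do not
  measure recovery of the per-cell generative totals. The noisy arm uses
  noise SD equal to 2% of the noiseless PLA channel's maximum — the
  scene's realised dynamic range;
* segmentation recovery on one hundred 6-nucleus fields and fifty
  touching-pair fields at the default SNR;
* IHC fraction recovery on fifty noisy tiles with truth fractions cycling
  over 0.1–0.9;
* statistical calibration on 2000 null replicates at n = 20 per group,
  and Fisher against exhaustive enumeration on random tables.

These sizes keep a full run in the order of minutes on a single core
while leaving Monte-Carlo margins far from the asserted bounds.

# Known limitations

* The ring is a proxy for the cell footprint; in dense cultures
  territories overlap heavily and per-cell attribution degrades
  gracefully (even split) rather than resolving true boundaries.
* The global threshold assumes reasonably uniform illumination; a
  gradient background would bias both the mask and the background
  estimate.
* K-means with a fixed K = 4 assumes the tile's palette matches the
  four-population model; tiles dominated by a single class can split it
  and the reference-colour rule then picks the nearest fragment.
* The background estimator needs at least one pixel outside all
  territories; fully confluent fields require an explicit background
  value.
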