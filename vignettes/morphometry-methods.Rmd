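---
title: "Measuring pericyte-endothelial interactions in segmented capillary sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pericyte-endothelial interactions in segmented capillary sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericytemorph)
```

## The measurement problem

Pericytes are mural cells that wrap capillary endothelium and sit embedded
within the vascular basement membrane (BM). They communicate with endothelial
cells at direct cell-cell contacts -- flat appositions where the BM is locally
absent, and peg-and-socket junctions where a finger-like pericyte protrusion
(the *peg*) inserts into an endothelial invagination (the *socket*). Serial
ultrathin sections (~80 nm) imaged by transmission electron microscopy and
manually segmented into six classes (background, BM, endothelium, pericyte,
peg, lumen) are the raw material; this package turns those label maps into
numbers:

* **vessel diameter** `D = C / pi`, with the circumference `C` taken as the
  length of the outer perimeter of the basement membrane;
* **volume fractions** of pericyte, BM, and endothelium relative to the
  non-lumen vessel volume (lumen content, including erythrocytes, never
  enters a denominator);
* **pericyte coverage** and **direct contact**, measured on a skeleton of the
  BM plus the contact lines, with every skeleton pixel classified as direct
  contact (Class 1), covered-but-separated (Class 2), or uncovered (Class 3);
  coverage% = (L1+L2)/(L1+L2+L3), contact% = L1/(L1+L2);
* **peg depth, area and frequency** from an exact Euclidean distance
  transform of the endothelium + pegs + lumen mask;
* **mural coverage on fluorescence images** (alpha-SMA channel), per vessel
  branch, with branch diameters from the skeleton distance transform;
* **group statistics**: four normality screens (reported, never gating),
  tie-corrected Kruskal-Wallis omnibus, Dunn pairwise z-tests with Holm
  adjustment, with vessels as the statistical units.

## Geometry conventions

A pixel is a unit square whose edge is `pixel_size_nm`; indices are
row-major. There is deliberately **no default pixel size**: calibration is
mandatory metadata, carried in the JSON sidecar of every stack. Section
spacing defaults to 80 nm, the nominal ultrathin section thickness. Stacks
keep excluded sections (poor quality, artifacts) flagged rather than dropped,
and every aggregation skips them.

## Perimeter and length estimation

Boundary lengths are measured on the oriented 8-connected contour chain (unit
axis steps, sqrt(2) diagonal steps). The raw chain systematically
overestimates smooth isotropic boundaries by a factor (8/pi)(sqrt(2)-1) ~
1.055, so by default all perimeters and skeleton lengths are multiplied by
the reciprocal (~0.948, Kulpa's corner correction); measured circle
perimeters are then accurate to a few tenths of a percent and converge as
the pixel size shrinks. `perimeter_correction = "none"` gives the raw chain
(an axis-aligned 100x100 px square then measures exactly 396 unit steps).
Degenerate regions with fewer than three contour points fall back to
crack-edge counting, so an isolated pixel has perimeter 4 edges.

Class lengths on the skeleton use a half-edge decomposition: each retained
skeleton pixel receives half the length of every incident skeleton edge.
This makes lengths exactly additive, so L1+L2+L3 equals the total retained
skeleton length whatever the class boundaries. A `pixel_count` mode
(summing skeleton pixels, the convention of the original description) is
retained for fidelity checks; the coverage and contact *ratios* are
insensitive to the choice.

## Skeleton classification

The skeleton (an in-package Guo-Hall two-subiteration thinning, followed by a
simple-point cleanup; one pixel wide, topology preserving, 8-connected) is
built from the BM mask united with the contact mask -- pericyte pixels within
one 3x3 dilation step of the endothelial mask. Classification:

1. Skeleton pixels inside the dilated contact mask are **Class 1** (the
   medial axis may sit one pixel off the contact line; contact, the most
   specific observation, wins conflicts).
2. Remaining pixels are classified by a radial probe from the vessel
   centroid: probing **outward**, the first non-BM class met decides --
   pericyte/peg gives **Class 2**, background gives **Class 3**.
3. Pixels whose **inward** probe meets pericyte before endothelium belong to
   the skeleton of the BM wrap over the pericyte's abluminal face; they are
   **discarded**. Counting that wrap as "uncovered" length would put the
   covered arc in the denominator twice. This reading of the "outer
   perimeter" rule is a deliberate design choice and is the main sensitivity
   knob of the coverage statistic; the radial probe assumes star-shaped
   sections, which capillary cross-sections satisfy in practice and the
   generator guarantees.

When pegs are present, their outlines touch the endothelium and therefore
enter the contact mask (with the default `merge_peg_into_pericyte = TRUE`);
peg walls then legitimately contribute direct-contact length. Recovery tests
of the programmed arc fractions use peg-free vessels for exactly this
reason: the arc ground truth describes only the circumferential interface.

## Peg depth

The mask M = endothelium + pegs + lumen is closed with a disk structuring
element of physical radius 134 nm, rasterized as all integer offsets with
r^2 + c^2 <= R^2 where R = round(134 / pixel_size_nm). Closing seals clefts
narrower than the element (a 100 nm BM film between peg and socket wall)
while genuine gaps wider than twice the radius survive; a radius below one
pixel at coarse calibrations is clamped to 1 px with a warning. The exact
Euclidean distance transform of closed M (distance to the nearest pixel
outside M) then increases from the abluminal endothelial surface toward the
lumen, and each peg component (8-connected, at least `min_component_px = 4`
pixels) reports the maximum over its pixels, plus its area
(`pixel count x pixel_size_nm^2`). Depths are per 2-D section component --
pegs are not linked across sections. Peg components with no adjacent
pericyte pixel are flagged (`orphan`) but never silently dropped.

## Fluorescence branch coverage

The vessel mask is a white top-hat (disk radius `tophat_radius_um = 15`,
which must exceed the widest vessel radius of interest) followed by a fixed
low threshold (`low_threshold = 0.05` on [0,1]-scaled images) and
small-object removal. The alpha-SMA mask applies Otsu's threshold to the
top-hat image *restricted to the vessel mask* -- background pixels would
dominate the histogram otherwise. Otsu presumes bimodality; a unimodal
histogram (between-class variance share eta^2 below 0.75, versus ~0.64 for a
pure Gaussian) is resolved by the `saturated_floor` (default 0.3): above it
the vessel is uniformly SMA-positive, below it uniformly negative (empty
mask with a warning). Branches are skeleton segments between branch points
(skeleton pixels with more than two neighbours); segments shorter than
`min_branch_um = 2` are absorbed by the nearest remaining branch when every
vessel pixel is assigned to its nearest branch-skeleton pixel (an exact
partition). Branch diameter is twice the mean distance-transform value along
the branch skeleton -- exact for even pixel widths, one pixel high for odd
ones, hence the 10% accuracy contract at four or more pixels per width.
Whether the mean or median is used is configurable (`diameter_stat`).

## Statistics

`compare_groups()` mirrors a standard nonparametric reporting layer:
D'Agostino-Pearson K^2 (implemented in-package), Anderson-Darling,
Shapiro-Wilk and Lilliefors tests are reported per group but never switch
the test; the omnibus comparison is always tie-corrected Kruskal-Wallis
(H = 0, p = 1 when all observations tie), and pairwise contrasts use Dunn's
rank z-tests with Holm adjustment (configurable). Groups with fewer than
three vessels are excluded with a warning. No adjustment is applied across
metrics. At very small samples (n <= 7) the chi-square approximation to the
null of H is accurate (within 0.05) only in the rejection-relevant tail of
the exact permutation distribution; at moderate H it overshoots the discrete
exact p -- a known limitation worth remembering when n is tiny.

## The synthetic generator

`generate_vessel()` emulates the statistical structure of segmented
capillary sections so every stage is testable without the original
micrographs: a lumen disk, an endothelial annulus (500 nm), a thin BM ring
(150 nm) on uncovered arcs, and on the covered arc a BM film, a pericyte
crescent (400 nm) and a BM wrap over its abluminal face. Over a programmed
sub-fraction of the covered arc the film is absent (direct contact); pegs
are radial fingers carved from the abluminal surface into the endothelium,
continuous with the pericyte through a bridge in the film. The outer
boundary carries a low-frequency radial jitter (harmonics 2-4, total
amplitude <= 2%), keeping sections star-shaped. Defaults follow realistic experimental
conditions: capillary diameters (a warning outside 4-12 um), ~50% coverage,
80 nm section spacing, 20 nm pixels, and cohort sizes of 19/16/18/23
vessels across four groups. Ground truth (diameter from the analytic
boundary integral including the arc-end steps, volume fractions from exact
annular areas, arc fractions, per-peg depth and area) is computed from the
generating geometry *before* rasterization, so measured-vs-true comparisons
expose genuine estimator bias, not shared discretization.

Problem sizes are chosen so the whole validation runs on a laptop: the
generator auto-sizes its grid to the vessel extent (an 8 um vessel at
20 nm/px occupies ~430^2 pixels), recovery tests use single sections, and
the cohort demonstration uses 40 nm pixels with 1-3 sections per vessel
(a few dozen serial sections per vessel would be i.i.d. replicates of the same
per-section measurement here, so more sections only narrow within-vessel
spread). What the generator does **not** emulate: real TEM texture and
segmentation error, oblique sectioning (vessels cut at an angle), non-star
shaped or collapsed vessels, 3-D peg continuity across sections, and
multiple vessels per animal (no hierarchical structure). Passing recovery
tests therefore validate the measurement chain's correctness on clean
geometry, not robustness to segmentation noise.

## Known limitations

* The coverage denominator depends on the discard rule for the abluminal BM
  wrap (see above); alternative readings change coverage% by a few points.
* Diameter assumes near-circular cross-sections; no obliquity correction is
  applied, and the vessel value is the unweighted mean of per-section
  diameters.
* The peg class map carries a single PEG class; reverse (endothelial into
  pericyte) protrusions are not distinguished.
* Otsu-based SMA segmentation needs an intensity scale; the fixed low
  threshold and saturation floor are stated configuration, not estimated
  from data.
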