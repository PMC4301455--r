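---
title: "Segmenting confluent cell sheets by geodesic region growing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting confluent cell sheets by geodesic region growing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogbankr)
```

## The problem

In a confluent epithelial sheet every cell touches its neighbours; there is
no background between cells for a thresholding method to exploit.
Watershed-style algorithms address this by growing regions from seed
points, but they suffer from two classic failure modes: *over-segmentation*
(noise creates spurious intensity minima, each of which nucleates a
fragment) and unrealistic *straight-line interfaces* (when pixels are
assigned to the nearest seed by Euclidean distance, the recovered borders
ignore the membrane geometry the microscope actually imaged). This package
attacks both: percentile quantization of the intensity axis suppresses
noise minima, and geodesic distance — path length measured through
traversable pixels only — makes region growth respect membrane obstacles.

## Model and assumptions

The input is a single-channel 2-D intensity image. The method assumes:

* cells form a contiguous sheet distinguishable from background by its
  gradient content (texture, membranes), not necessarily by intensity;
* cell-cell boundaries image as thin intensity extrema — bright ridges in
  phase contrast (`boundary_polarity = "bright"`), dark lines in some
  other modalities (`"dark"`);
* each cell contains exactly one seed structure detectable either as a
  large connected basin of the intensity histogram or as a cluster of
  dark round nucleoli;
* mitotic cells, if present, are markedly brighter than everything else
  and approximately round.

Intensities are never rescaled on read: every threshold in the pipeline is
a percentile of the image (or ROI) itself, so the method is invariant to
affine intensity changes by construction.

## Geodesic distance and the boundary mask

For pixels $a, b$ the geodesic distance $d_I(a,b)$ is the minimum length
of a pixel path joining them that stays inside the traversable set, and
$\infty$ when they are not connected. The traversable set is the ROI minus
the pixels above the `boundary_percentile` (default 85) of ROI
intensities. Path length is counted in steps under 8-connectivity, with
diagonal steps costing 1 by default; the cost is isolated behind
`diag_cost`, so $\sqrt 2$-weighted chains can be selected when metric
fidelity matters more than speed. Ties between equidistant seeds always
resolve to the smaller label, which makes every assignment deterministic
and independent of enumeration order.

## Seed detection

**Histogram quantization.** The percentile table $p(0), \dots, p(100)$
bins the ROI intensities into 100 levels of 1% each (linear-interpolation
percentiles, the single convention used package-wide). Thresholding is
*strict* (`I < p(i)` ascending, `I > p(i)` descending): at the extreme
level nothing strictly exceeds the range, so the full ROI can never
collapse into one degenerate seed. At each level, a connected component
of at least `S_T` pixels containing no previously accepted seed becomes a
new seed; a component containing exactly one seed extends that seed's
provisional extent; a component bridging two or more seeds freezes them.
This last rule is the only reading of level interaction that both grows
seeds monotonically and prevents later levels from flooding distinct
basins together — seed identities are immutable once accepted. `S_T`
should be a sizable fraction of the expected cell area (a third to a
half): it is precisely the knob that rejects noise basins.

**Nucleoli modeling.** One threshold at percentile `t` (default 2, the
"bottom 2%" appropriate when nucleoli are the darkest objects) is
followed by size (`S_T`) and circularity (`C_T`) filters and
single-linkage clustering of the surviving components at centroid
distance `D_N` (the approximate nucleus diameter). Single linkage is the
correct reading of "nucleoli closer than `D_N` belong to the same cell":
the relation chains transitively. The threshold comparison here is
*inclusive* (`I <= p(t)`): on 8-bit images an entire nucleolus population
can sit exactly at the percentile value, and a strict comparison would
silently discard it. A seed produced by clustering may consist of several
disjoint nucleoli — this is intended (one label per nucleus), and region
growing merges their basins.

**Circularity.** $C = 4\pi \cdot \text{area}/\text{perimeter}^2$ with the
perimeter measured as the Moore-traced outer boundary chain (axial steps
1, diagonal steps $\sqrt2$). A digital disk of radius 15 scores 0.911, a
$1 \times 50$ line 0.065, a large square tends to $\pi/4$. We considered
the crack-length estimator (count of exposed pixel edges) but rejected
it: it assigns a disk $C = \pi^2/16 \approx 0.62$, which would break the
natural calibration "round $\approx$ 1" that users of `C_T` expect.
Single-pixel components return 1 by convention; interior holes are
ignored.

## Region growing

Growth starts from the seeds and admits pixels level by level — the 100
percentile bins by default, every distinct intensity when
`quantize = FALSE`. Within one level all pixels are assigned
simultaneously by multi-source shortest path from the current region
boundaries, restricted to already-assigned pixels plus the current level
(so a pixel cannot be claimed through territory that has not been grown
yet). Pixels unreachable at their own level are retried automatically at
later levels because the bins are cumulative. After all levels, two kinds
of ROI pixels can remain: non-traversable membrane pixels, and pockets
walled off from every seed. Both are assigned in a final pass by nearest
label with obstacles ignored (but still inside the ROI), so the output
partitions the foreground — mirroring reference masks, where membrane
pixels always belong to some cell. The label set after growth equals the
label set of the seeds: regions are never created, merged or lost.

The growth direction is a modality choice: ascending (dark first) for
phase contrast, where membranes are bright and must come last; descending
for dark-boundary modalities. The percentile table used for growth is
recomputed over the traversable ROI rather than reusing the seed-stage
table; the two differ only through the excluded boundary pixels, and
recomputation keeps each stage self-contained.

**Ablation.** `quantize = FALSE` with `grow_metric = "euclidean"`
reproduces the "without percentile grouping" variant used as an internal
control: every distinct intensity is a level and pixels join the
Euclidean-nearest seed boundary, with the traversability mask ignored.
On ridge-bounded synthetic sheets this variant is consistently worse than
the default (acceptance criterion 5), which is the qualitative behaviour
reported for the original method; unquantized growth is intended for
integer-valued images, where the number of levels is bounded.

## Mitotic cells

Components of `I > p(mitotic_percentile)` (default 97, strict — the
percentile pixel itself is not "above" it) within the ROI that are at
least `mitotic_min_size` pixels and at least `mitotic_circularity` round
are overlaid onto the grown mask with fresh labels, overwriting the cells
beneath; the hosts keep their remaining pixels. Defaults for the size and
roundness knobs (30 px, 0.5) are package choices: the source material
defers its values to supplementary settings that are not part of the
method's definition.

## Evaluation metrics

The contingency table counts overlap pixels between reference cell $i$
and test cell $j$ over the pixels foreground in *at least one* mask
(union convention); a pixel foreground in only one mask contributes a
singleton group on its background side, so row/column sums reconcile with
the total $T$, and background–background pixels are discarded entirely.
The Adjusted Rand Index is evaluated from that table with integer-exact
$\binom{n}{2}$ arithmetic; the degenerate case (both partitions trivial)
returns 1 by convention. The printed source formula uses a binomial
notation that reads as the reciprocal of the standard coefficient; the
standard $\binom{n}{2} = n(n-1)/2$ is implemented, as in the literature
the formula derives from.

Cell-level matching is mutual-majority: reference cell $i$ is a true
positive iff one test cell covers more than half of $i$ and $i$ is in
turn that test cell's majority. A reference cell claimed by two or more
mostly-inside test cells is over-segmented; a test cell majority-covering
two or more reference cells is under-segmenting; `CCA = TP/(N + FP)`.
The majority threshold (0.5) is exposed as `overlap_fraction`.

## The synthetic world

`make_confluent_sheet` draws a blob-shaped colony (an ellipse covering
roughly half the frame), tessellates it into `n_cells` Voronoi regions
around Poisson-disk-sampled centers (minimum spacing $0.6\sqrt{A/n}$ —
uniform sampling would produce sliver cells no segmenter should be
expected to recover), and renders: membrane ridges (210 counts) along
interfaces and the sheet edge, cell interiors as a spatially correlated
texture field (mean 110, sd 5; correlation from a 5-pixel box blur —
organelle-scale structure, *not* iid camera noise, because real cytoplasm
is smooth at the pixel scale and iid texture would make every histogram
basin degenerate), non-overlapping dark nucleoli (35 counts, radius 3) on
a small ring near each cell center, optional bright mitotic disks (245),
flat mid-gray background (95), optional additive Gaussian noise, and
8-bit quantization. The mid-gray background reflects phase-contrast
reality: nucleoli are the darkest structures in the field; an early draft
used a dark background and promptly broke the bottom-2% rule, which is a
faithful reproduction of how the real method would fail on such a
modality (the percentile would have to be retargeted).

Ground truth is the exact tessellation — ridge pixels keep their own
Voronoi label — so metric checks are exact. What a green end-to-end test
establishes: seed detection, geodesic growth and the metrics compose
correctly on scenes with the stated geometry and contrast. What it does
not establish: performance on real optics (phase halos, shading,
defocus), on DIC (known not to suit the method), or at the paper-scale
reference benchmark, which requires manually drawn masks.

## Numerical choices and edge cases

* Percentiles: `stats::quantile` type 7 everywhere.
* Connectivity: 8 for foreground/seeds/cells, 4 for the hole-filling
  complement; a single `connectivity` parameter threads through the API.
* Constant images: empty foreground (no gradient tail), all-zero output.
* Zero seeds: `fogbank_segment` falls back to one label per foreground
  component.
* Label images: non-negative integers, 0 = background; written as 16-bit
  TIFF, escalating to 32-bit beyond 65535.
* Degenerate ARI denominator: 1 by convention.
* All randomness in the generator flows through one seeded stream that is
  saved and restored, so library calls never disturb user RNG state.

## Known limitations

Anisotropic pixels are not handled; geodesic distances are step-counted,
not sub-pixel; the foreground threshold criterion is a documented
stand-in for the published gradient-threshold technique (isolated in one
function, `egt_threshold`); multi-page/z-stack inputs and time-lapse
tracking are out of scope.
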