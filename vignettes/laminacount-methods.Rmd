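---
title: "Quantifying neuronal survival in spinal cord sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal survival in spinal cord sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminacount)
```

## The problem

After a contusive spinal cord injury, neurons die in a spatial pattern:
loss is near-total at the injury epicenter and wanes with rostro-caudal
distance, and some Rexed laminae are hit much harder than others.
Quantifying that pattern from histology means (i) identifying neurons in
two-channel fluorescence sections (a neuronal-marker channel such as NeuN
and a nuclear counterstain such as DAPI), (ii) reconciling identifications
that disagree between observers and methods, (iii) registering each
section to a reference atlas of laminae and nuclei, and (iv) summarizing
counts as survival percentages relative to uninjured controls.
`laminacount` implements this pipeline end to end, together with a
synthetic-section generator so that every stage can be validated against
known ground truth without any microscopy data.

## The synthetic-section model

`build_toy_atlas()` constructs a stylized butterfly-symmetric grey-matter
outline partitioned into horizontal laminar bands (`L1` dorsal to `L10`
ventral by default) plus five named nuclei (`IML`, `ICI`, `IMM`, `D`,
`LDCom`) occupying one intermediate band. It is a procedural stand-in for
a reference spinal-cord atlas section: simple polygons, no overlaps, exact
tiling of the outline, deterministic for fixed inputs. It does not attempt
anatomical fidelity — laminar boundaries in real cords are curved and
section-specific — but it preserves everything the downstream maths
relies on: a region partition, a grey-matter boundary, region classes
(dorsal / intermediate / ventral) with distinct densities and
vulnerabilities.

`simulate_section()` draws the number of neurons in each region from
Poisson(density × area × survival), places somas uniformly in their
region polygon, and renders each soma as a disc in the neuronal channel
with a smaller colocalized disc in the nuclear channel. Artifacts
(autofluorescent debris) are rendered in the neuronal channel only —
that is what makes nuclear colocalization an effective filter, mirroring
how human observers and pixel classifiers reject bright objects without a
nucleus. A per-section multiplicative staining gain (log-normal),
an optional Gaussian point-spread blur, and additive Gaussian noise
complete the image model.

Key defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| control total | ~283 neurons/section | typical census of an uninjured thoracic section |
| soma radius | 5 ± 0.8 µm, truncated at 3.5 µm | keeps every soma above the 25 µm² particle filter, so the filter separates somas from noise rather than truncating the soma population |
| survival anchors | (0.6 mm, 2.3%), (0.8, 20%), (1.0, 40%), (1.2, 40%) | the injury gradient: ~20 percentage points of recovery per 200 µm, plateauing at 40% from 1.0 mm |
| region-class survival factors | dorsal 1.5, intermediate 0.6, ventral 1.0 | dorsal laminae are relatively spared, the intermediate grey (including the nuclei) is hit hardest |
| staining gain sd | 0.15 (log scale) | section-to-section staining variability large enough to defeat a single global threshold |
| artifact rate | 2 /mm² | a handful of bright nuclear-free objects per section |
| pixel size | 2 µm/px | coarse for microscopy but sufficient for ~5 µm somas; tests use 1–4 µm/px depending on what they measure |

The region-class factors are renormalized at simulation time so that the
density-weighted mean survival over the atlas equals the overall curve.
Section totals therefore follow the configured gradient exactly (in
expectation) while regions differ in the configured direction — without
this normalization the per-class factors would silently distort the
total-survival gradient that the end-to-end tests recover.

`simulate_observer()` models an imperfect manual analysis: each true
neuron is found independently with probability `sensitivity`, found
positions get isotropic Gaussian jitter, and false positives arrive as a
Poisson process over the grey matter. With K independent observers of
equal sensitivity p, the number of analyses that find a given neuron is
Binomial(K, p) — the generative model behind the agreement-class
histograms, and a closed-form target the consensus module is tested
against.

`simulate_probability_map()` emulates a pixel classifier's output:
probability near 1 inside true somas, near 0 on background *and on
artifacts* (a trained classifier's main advantage over thresholding).
`miscalibration` widens both sides with truncated Gaussian deviations;
at 0 the map is the exact truth indicator, giving the noiseless limit in
which detection must recover truth exactly.

What the generator does **not** model: realistic tissue texture and
background gradients, white matter, anisotropic or overlapping somas in
depth (sections are treated as true 2-D), chromatic shifts between
channels, and deformation between section and atlas geometry (sections
are generated in atlas space; registration is exercised with synthetic
warps instead). Passing tests therefore demonstrate the correctness of
the *analysis machinery* under the stated statistical model, not detection
performance on real microscopy.

## Detection

`segment_neurons()` re-implements the macro-style route: threshold the
neuronal channel (`otsu`, `triangle`, `isodata`, `mean`, `fixed`, or
`auto`, which picks the method with the best foreground/background
contrast — a reproducible replacement for per-image manual choice),
restrict to the grey-matter mask, label 8-connected components
(optionally watershed-splitting touching somas on the distance
transform), drop components that do not intersect the 1-px-dilated
thresholded nuclear mask, and discard particles with area not strictly
above 25 µm². The area rule is applied strictly (`> 25`, not `>=`), and
the same strict rule governs `probmap_to_detections()`, the
post-processing contract for pixel-classifier output: components of
pixels with p > 0.5 and area > 25 µm².

Connected components use 8-connectivity (diagonal pixels join), built as
a union-find merge over the 4-connected labeling; a breadth-first
flood-fill oracle in the test suite checks the partition exactly.

## Consensus across analyses

`match_detection_sets()` partitions the pooled points of K analyses into
objects under two constraints: at most one point per source per object,
and all pairwise distances within an object at most the matching radius
(default 10 µm ≈ one soma radius). Linking is greedy over all
cross-source candidate pairs in increasing distance with deterministic
tie-breaks (source index, then coordinates), merging two groups only when
both constraints hold. Because the pair list is pooled and globally
sorted, the result does not depend on the order in which the sets are
supplied. The exhaustive counterpart
(`match_detection_sets_exhaustive()`) enumerates every feasible
partition — feasible objects are confined to connected components of the
within-radius graph, which keeps enumeration exact and affordable — and
minimizes cost = radius × (number of objects) + Σ point-to-centroid
distances, a formulation under which "merge iff closer than the radius"
is optimal. The greedy matcher is required to attain the exhaustive
minimum cost on randomized instances.

Each object's agreement class k counts the manual analyses that
identified it; class 0 collects objects contributed only by automated
sets. The Reference Number of Neurons is the weighted consensus
RNN = Σ k/K over objects, a weighting chosen because it makes the RNN
equal the arithmetic mean of the per-analyst counts — an identity the
tests verify to 10⁻⁹ rather than assume.

## Concordance statistics

`bland_altman()` reports the bias, the sample standard deviation of
paired differences, and the 95% limits of agreement bias ± 1.96 sd.
Agreement plots often label these lines "95% confidence intervals"; they
are limits of agreement in Bland–Altman's sense and the package names
them so. For two repeated counts with independent noise σ each, the sd of
differences is √2 σ — the recovery the tests check within 10% over 500
replicates. `accuracy_correlation()` reports Pearson r, r² and the
two-sided p (published accuracy figures are quoted either way), and
`repeatability_model()` screens OLS models of the count difference on
candidate predictor subsets (mean count, analysis time, analyst
experience, section condition), comparing nested fits by ANOVA F-tests
and ranking by adjusted R².

## Registration

`fit_tps()` solves the standard thin-plate-spline system with kernel
U(r) = r² log r² (U(0) = 0) and an affine part, using the null-space
(QR) formulation: the kernel system is solved in the orthogonal
complement of the affine space, which enforces the side conditions
Σw = 0 and Σw·x = 0 exactly and keeps the solve well conditioned with
coordinates in µm (no unit rescaling is performed; the kernel matrix
entries are large but the reduced system is benign). With λ = 0 the
transform interpolates every landmark (residuals < 10⁻⁶ µm across the
11–53-landmark range used in practice); affine-related landmark sets
yield kernel weights below 10⁻⁸ in norm, and residuals grow monotonically
with λ. The default direction maps atlas (moving) space onto the section
(fixed) space, so detections are never deformed; the inverse fit is
available for atlas-space analyses.

`warp_regions()` densifies polygon edges (default 25 µm) before mapping
vertices so curved warps of straight atlas edges are preserved, and flags
warped polygons that self-intersect — their counts should be treated as
low confidence. `assign_to_regions()` uses the even-odd rule per region
in atlas order; the first containing region wins, which resolves shared
boundaries deterministically (boundary assignment has no principled
answer when the atlas comes from a different individual; a fixed order is
at least reproducible).

## Quantification

`region_counts()` pivots assignments into the sections × regions matrix
(detections outside every region are tracked separately, and excluded
sections are simply absent rows — never zeros). `survival_percent()`
uses the per-region *median* across control sections as the reference —
the median, not the mean, because staining-intensity outliers can double
a section's count — and flags regions with zero control median as
undefined rather than dividing by zero. `distance_profile()` summarizes
median total survival per distance with per-step increments, and
`kruskal_wallis()` wraps the rank test (H and the chi-square p from
`stats::kruskal.test`) with an optional Monte-Carlo permutation p that
reuses the fixed rank vector per permutation. No multiple-testing
correction is applied across regions; the pipeline records the number of
tests performed instead.

## Numerical choices and degenerate inputs

* Coordinates are continuous µm, origin at the top-left pixel corner,
  y downward; pixel (i, j) covers [(j−1)s, js) × [(i−1)s, is) and its
  center is ((j−½)s, (i−½)s). All annotation and registration maths is
  µm; pixel conversions happen only at raster boundaries.
* Thresholds are strict (`>`), both for probability (`p > 0.5`) and area
  (`area > 25 µm²`): a 24 µm² or exactly-25 µm² particle is rejected.
* Constant images under histogram thresholding fall back to the single
  intensity with a warning rather than erroring inside a pipeline.
* Matching ties (equal distances) break by source index then (x, y);
  exact ties are measure-zero for continuous data but the rule makes
  outputs reproducible bit-for-bit.
* A single master seed expands into deterministic per-section child seeds
  (`seed + 104729 × index`, mod 2³¹ − 1) so stages can be re-run
  independently; identical configuration and seed give identical images,
  truth, and downstream CSV output.
* Degenerate zero-density configurations yield empty sections and empty
  detection sets throughout (no special-casing needed downstream);
  Kruskal–Wallis on all-identical observations returns H = 0, p = 1.

## Validation scale

The test suite validates the pipeline at desk scale, chosen to keep the
full run in minutes on one CPU: the end-to-end survival recovery uses 100
simulated cohorts (4 control + 8 injured sections each, 4 µm/px frames of
2000 × 1500 µm) through the probability-map route, requiring the median
recovered total survival at each distance to fall within 5 percentage
points of the generator's curve; detection efficiency (merged touching
somas, sub-resolution somas at coarse pixels) cancels in the
survival ratio because control and injured sections share the soma and
optics model. The chi-square vs permutation agreement for Kruskal–Wallis
is checked at ~60 observations per group with 10⁵ permutations; at very
small n the chi-square approximation departs from the exact permutation
distribution by more than Monte-Carlo error for *any* implementation,
so the check is placed where the asymptotic test is the right tool.
Observer-agreement recovery uses K = 5 observers at sensitivity 0.8 over
500 well-separated truth objects, compared to the zero-truncated
Binomial(5, 0.8) by chi-square at the 0.99 quantile over 100 runs.

## Known limitations

* The toy atlas is geometrically stylized; region-wise results on real
  sections depend on registration quality and atlas fidelity that the
  synthetic tests cannot probe.
* The exhaustive matcher is exponential within a within-radius component
  and guards against components larger than 14 points; it is a validation
  tool, not a production matcher.
* The watershed split is exposed but not part of the validated default
  path: touching-soma separation is intrinsically ambiguous and the
  default pipeline prefers under-segmentation (which cancels in survival
  ratios) to arbitrary splits.
* Probability-map simulation is spatially unstructured (iid
  miscalibration); real classifier errors are correlated along
  structures, so real class-0 and artifact rates will differ from the
  synthetic ones.
* `tiff::writeTIFF` cannot embed resolution tags, so files written by the
  package carry pixel size in the JSON sidecar; resolution tags are still
  honoured when reading third-party TIFFs.
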