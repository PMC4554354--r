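---
title: "Counting DNA-damage foci: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting DNA-damage foci: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focicount)
```

## The problem

After ionizing radiation, repair proteins such as γ-H2AX and 53BP1 accumulate
at DNA double-strand breaks and appear in immunofluorescence micrographs as
punctate *foci* inside nuclei. The foci count per nucleus tracks damage
induction and repair kinetics — roughly linearly with dose in the clinical
range (published induction rates are around 15–19 foci per nucleus per Gray) —
so radiation biologists count foci across hundreds of nuclei per condition.
Manual counting is slow and investigator-dependent; `focicount` automates the
full chain on single-plane, multi-channel images: one nuclear-stain channel
defines the regions of interest (ROIs, one per nucleus), and one or two
antibody channels carry the foci.

The pipeline per image is:

1. **Segment nuclei** on the ROI channel: threshold → optional hole filling →
   connected components (8-connected) with optional watershed separation →
   size / circularity / edge filters.
2. **Detect foci** per ROI and channel as prominence-filtered local maxima,
   with an optional absolute intensity cutoff.
3. **Measure** per-ROI area, intensity statistics, per-channel counts and
   area-corrected densities; optionally flag outlier nuclei by a percentile
   rule.
4. **Colocalize** foci across the two channels within a distance tolerance.
5. **Export** per-focus, per-ROI, per-image and batch-summary tables (CSV).

Raw pixel data are never modified — no smoothing, contrast change or
rescaling; every measurement is taken on the values as loaded.

## Foci as prominence-filtered maxima

The detector follows the semantics of the interactive "find maxima" tools
this field uses. For a local maximum $m$ with value $v$ in an ROI and a noise
tolerance $\tau$ (config `foci.noise_level_*`), consider the connected region
reachable from $m$ through pixels of value $> v - \tau$, restricted to the
ROI. $m$ is a focus iff that region contains no pixel strictly brighter than
$v$. Equivalently, $\tau$ is a *prominence* threshold: a bump must rise at
least $\tau$ above the saddle connecting it to brighter signal. Properties
that follow (and are asserted by the test suite):

* counts are non-increasing in $\tau$ and in the cutoff;
* adding a constant to the raster changes nothing (shift invariance);
* pixels outside an ROI can neither create nor suppress foci inside it
  (outside values are treated as $-\infty$);
* the brightest pixel of an ROI is always accepted — prominence alone cannot
  reject a global maximum. The absolute cutoff (`foci.cutoff_*`, applied as
  `peak >= cutoff`) exists for exactly this reason: in a focus-free nucleus it
  removes the one noise maximum that prominence must accept.

Pinned numerical conventions: 8-connected neighborhoods; a plateau of
equal-valued maximal pixels yields one focus at the plateau pixel nearest the
plateau centroid (ties by ascending x, then y); a plateau with *no* strictly
lower in-ROI neighbor (a constant component) is not a peak; no sub-pixel
localization — exported positions are 0-based integer pixel coordinates with
x = column, y = row. Foci are deliberately *not* watershed-split: separating
merged foci would require requantizing the image, losing the intensity
information the cutoff and the exports rely on. Overlapping foci therefore
merge into one detection at small separations; this is the main known cause
of undercounting at high dose.

The implementation (single descending-order flood pass with early abort) is
checked against a brute-force oracle — per-plateau flood-fill by repeated
dilation — for set-equality on hundreds of random rasters.

## Segmentation choices

**Threshold.** Foreground is `value >= t`. `t` is either manual or automatic;
automatic defaults to the iterative intermeans (isodata) recursion on the
image histogram, with Otsu available (`seg.auto_method`). The chosen value is
reported in the log and in `run_metadata.yaml`. Auto mode refuses degenerate
images: a constant raster, and any raster whose intermeans separation is
below 1.8 total standard deviations. The latter is a bimodality guard — a
unimodal Gaussian split at its mean yields a separation of
$2\sqrt{2/\pi} \approx 1.6$ SD by closed form, while any usable stained image
separates far more strongly — so a blank, noise-only frame fails loudly
instead of yielding speckle ROIs.

**Shape filtering.** Circularity is $4\pi \cdot \text{area} /
\text{perimeter}^2$, capped at 1 (rasterization can push small objects above
1). The perimeter estimator matters for reproducible circularity values and
is pinned: Moore-neighbor boundary tracing of the outer contour, with the
Vossepoel–Smeulders corrected chain-code weights (0.980 per straight move,
1.406 per diagonal move, −0.091 per corner). On a rasterized radius-20 disk
this yields a perimeter within a few percent of $2\pi r$ and circularity in
[0.85, 1.0]; a thin bar falls below 0.5. Holes are ignored by the tracer;
enable `seg.fill_holes` when staining leaves dark interiors. Edge exclusion
(`seg.exclude_edge`) drops any object with a pixel on the outermost rows or
columns — the simplest testable reading of "partially outside the image".

**Watershed.** Touching nuclei are split on the Euclidean distance transform:
seeds are prominence-filtered maxima of the distance map (prominence ≥ 2 px),
seeds closer than 4 px merge (the deeper survives), and a component is split
only when it holds ≥ 2 seeds — so an isolated convex nucleus is never
fragmented. Seeded region growing assigns every foreground pixel to exactly
one label. The standard distance-transform and propagation primitives come
from EBImage; labeling is 8-connected (EBImage's 4-connected labeling plus a
diagonal merge pass).

## Measurement and the percentile filter

Per ROI the package reports area, mean/min/max intensity (on the nuclear
stain channel by default, configurable via `measure.intensity_channel`),
per-channel foci counts, and the area-corrected density
`count / area × factor` (`measure.area_correction_factor`, default 1000, so
typical densities land near 1–30 per "kilopixel²"; supply
`measure.pixel_size_um` to also get foci/µm²). S-phase cells can show many
replication-associated γ-H2AX foci unrelated to the exposure; the percentile
option flags, per image, every nucleus whose focus count lies strictly above
the nearest-rank p-th percentile (the `ceil(p/100·n)`-th order statistic).
Flagged nuclei stay in the per-ROI export — no focus is ever dropped from the
tables — but are excluded from all summary means. Direction, variable and
method of this rule are package conventions; they are stated here because
other tools may differ.

## Colocalization

Foci from the two channels of one ROI are matched one-to-one when their peak
distance is ≤ `coloc.tolerance` (Euclidean, pixels). Candidate pairs are
taken greedily in ascending distance (ties broken by coordinates), then the
matching is lifted to maximum cardinality by alternating-path augmentation.
Plain distance-greedy can strand a matchable focus behind an already-taken
partner — a three-focus counterexample loses a pair — and an undercount here
biases the colocalized percentage, so the augmentation step is part of the
contract; the suite checks equality with exhaustive maximum-cardinality
search on all small instances. Percentages are per channel,
$100 \cdot n_{\text{matched}} / n_c$, pooled image-level percentages are
computed from totals (not averaged over ROIs), and matching operates on
post-cutoff foci only.

## The synthetic generator

Every validation claim in this package is made against images with exact
ground truth, produced by `fc_synth_spec()` / `fc_generate_image()`. The
generator emulates the assay's geometry: elliptical nuclei (uniform semi-axes
and orientation) placed with disjoint, margin-separated bounding boxes on a
dark background (or inverted for light-background material); foci as 2-D
Gaussian bumps planted inside the nuclei with a minimum spacing; an optional
second channel whose foci are either partners of channel-1 foci (offset ≤
`coloc_offset_max`) or decoys placed ≥ 10 px from every channel-1 focus; and
additive Gaussian noise, rounded and clipped to the bit depth.

Default intensities are an SNR design chosen once, up front: 16-bit range,
background 400, nucleus pedestal +1500, noise σ = 25, focus amplitude 250
(10 σ) with a 1.5 px Gaussian width, minimum spacing 6 px, detection noise
level 100 (4 σ). The reasoning: at spacing 6 px and width 1.5 px, the saddle
between two adjacent foci sits near 0.27 of the amplitude, i.e. ≈ 2.7 σ,
while the flood threshold sits at amplitude − 4 σ ≈ 6 σ — a ≥ 3 σ margin
against both false merging and noise-driven splitting. A 2 px Gaussian width
at the same spacing would put the saddle at 0.65 of the amplitude and merge
neighbors routinely. Dose series draw each nucleus' focus count from a
Poisson distribution with mean `foci_per_gy × dose` and record exactly what
was planted.

What the generator does *not* emulate — hence what green tests do not prove
about real micrographs: optics (no PSF beyond the Gaussian spot, no
chromatic offset between channels), uneven illumination and nuclear texture
(a low-frequency gradient option exists but is off by default), Poisson
photon statistics (a Gaussian approximation is used), focus-size variation
with dose and repair time, clustered or overlapping foci beyond the spacing
limit, and autofluorescent debris. Parameter choices for real data — above
all the noise level and cutoff — remain the user's responsibility and should
be tuned on a few images before a batch run.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run, per seed: 100 random 32×32
rasters against the maxima oracle; nuclei recovery for k ∈ {1, 5, 20} nuclei
on 384²–768² frames over 20 seeds; foci recall/precision pooled over 50
seeds of 4 nuclei × 6 foci at the default SNR; a dose series at
{0.5, 1.5, 3} Gy × 16 foci/Gy with 40 nuclei per dose on 1280² frames
(nucleus semi-axes 32–44 px there, so that ~50–70 foci fit per nucleus at
the 6 px spacing without saturating the packing); colocalized fractions
{0, 0.25, 0.5, 1} over 50 seeds each at tolerance 2 px with σ = 5 noise —
the low noise isolates the matching stage, detection robustness being
covered by the recall/precision block; and byte-identity of repeated batch
runs. These sizes were chosen as the smallest at which the recovered
quantities are statistically stable.

## Known limitations

Single-plane analysis only (no z-stacks or time series); at most three
role-bound channels (one ROI + two foci channels); no foci-level watershed
(see above); TIFF and PNG input only — convert proprietary microscope
formats (ZVI/LIF/CZI) with existing converters first; RGB images are
rejected rather than auto-split, because silent channel-role guessing is the
classic source of wrong counts; CSV is the canonical output (it imports
directly into any spreadsheet or statistics package; no native xlsx writer
is included). Batch aggregation reports both the unweighted mean over images
and the ROI-weighted pooled mean — with unequal nuclei per image they
differ, and both are labeled in `summary.csv`.
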