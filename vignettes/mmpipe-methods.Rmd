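---
title: "Methods: classical mother-machine image analysis in mmpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classical mother-machine image analysis in mmpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpipe)
```

## The problem

The mother machine is a microfluidic device in which rod-shaped microbes
grow in single file inside narrow, one-ended channels that open into a flow
trench. The cell at the closed end (the "mother") is imaged for hundreds of
generations while its progeny are pushed toward the open end and flushed
away. Extracting physiology from such an experiment requires a specialized
chain of image-analysis steps: locating the growth channels in each field
of view, correcting stage drift, separating cells from the dark device
features, segmenting individual cells, and linking the segments through
time into lineages from which cell-cycle statistics are computed.

`mmpipe` implements this chain with classical (non-learning) computer
vision, together with a synthetic-experiment generator that provides ground
truth for every stage, and an evaluation harness for cell-level
segmentation quality. Every stage is usable as an R function and as a CLI
subcommand (`inst/scripts/mmpipe.R`).

## Pipeline stages and their assumptions

### Channel detection and compilation

Channels are vertical, evenly spaced, and brighter inside than the
surrounding device. The detector computes the column-intensity profile of
the drift-corrected temporal mean image, convolves it with a Mexican-hat
(Ricker) kernel at the expected channel width (a scale-selective matched
filter), and keeps local maxima that sit on the best-fitting lattice with
the expected channel separation. The channel's vertical extent is the row
range over which the cross-column intensity variation of the channel
structure persists, padded by `compile.y_pad` (default 10 px). Crops add
2 px of wall on each side of the nominal channel width.

Drift is estimated per frame as the integer shift maximizing the FFT
cross-correlation against the first frame, searched within
`subtract.align_pad`. Sub-pixel registration is deliberately out of scope:
the fixture's ground truth is integer-shifted, and real stage drift at
this scale is adequately handled at integer resolution.

Full/empty classification uses the time correlation of the channel's
y-profile (row means of the crop): empty channels are static, so their
profiles stay correlated; channels with growing and dividing cells
decorrelate. Two scores are offered. The default correlates each frame's
profile with the *temporal mean* profile; the alternative (`"adjacent"`)
correlates consecutive frame pairs. We chose frame-vs-mean as the default
after measuring both on rendered fixtures: with per-pixel noise at
realistic levels, the adjacent-frame score of a genuinely empty channel is
noise-limited (both empty and full channels score below the natural
threshold), whereas the mean-profile reference averages the noise down and
cleanly separates the two classes (empty about 0.98, full about 0.87 at
default contrast). The threshold `compile.empty_threshold` defaults to
0.97 and is user-overridable; the classification CSV written by the
compile stage can be hand-edited before subtraction (replacing interactive
curation).

### Background subtraction

An empty channel, averaged over time, serves as the background template
for each field of view. Each full-channel frame is aligned to the template
by exhaustive integer search over ±`subtract.align_pad` px (default 10),
maximizing normalized cross-correlation; the subtracted image is
`clip(template - frame, 0)`, which subtracts the device image and inverts
the contrast in one step, leaving the phase-dark cells as the only bright
objects on a near-zero background. Alignment scores below 0.5 are
reported, since misalignment leaves wall artifacts that downstream
segmentation can mistake for cells. On rendered fixtures with most of the
channel occupied by cells, the alignment score is dominated by the cell
content and typically sits near 0.5–0.6 even when the alignment is exactly
correct; the score is a warning signal, not a quality measure of the
subtraction itself.

### Segmentation

The classical chain, in order: (1) binarize at `segment.otsu_scale` times
the Otsu threshold (the threshold maximizing between-class variance of the
256-level histogram; ties across empty histogram gaps resolve to the
plateau midpoint); (2) morphological opening with a disk of radius
`segment.first_opening` (a disk of radius r contains all offsets within
r + 0.5 px); (2b) fill fully enclosed holes — isolated sub-threshold
pixels inside cells would otherwise zero the distance transform locally
and split cells, while an enclosed-hole fill cannot bridge the open gap
between adjacent cells; (3) Euclidean distance transform; (4) keep pixels
at distance ≥ `segment.distance_threshold`; (5) opening with radius
`segment.second_opening`; (6) remove regions smaller than
`segment.min_object_size` and regions touching the crop border;
(7) label connected components (4-connectivity); (8) seed a random walker
on the subtracted intensities with those labels, the background class
seeded from pixels farther than twice `segment.distance_threshold` from
the binary foreground.

The random walker solves the combinatorial Dirichlet problem exactly on
the 4-connected lattice with edge weights `exp(-beta * dI^2)` on
range-normalized intensities plus a small conductance floor (1e-6), via a
sparse Cholesky/LU solve; the output is fully deterministic. The
sharpness `segment.walker_beta` defaults to 500: at much lower values a
single edge crossing costs about as much as a long path through a thin
background corridor, and cell labels occasionally leak along the channel
walls; at much higher values the walker fragments regions. Each refined
region contains its (already filtered) seed, so the size and border
filters are not re-applied after refinement.

### Tracking

Tracking is a per-frame decision tree built on the physics of the device:
cells grow by a small factor between frames, divide into two similarly
sized daughters, and cannot pass each other in the channel. Cells and
regions are ordered along the channel axis and matched with a two-pointer
scan that cannot cross links, which enforces order preservation by
construction. For each cell, a one-region (growth) and a two-region
(division) hypothesis are tested: growth requires frame-to-frame length
and area ratios inside `track.growth_length_ratio` and
`track.growth_area_ratio` (defaults (0.8, 1.3)); division requires the
combined daughters to satisfy the same ratios against the mother and each
daughter to hold 25–75% of the pair. When both hypotheses pass, the one
whose total length ratio is closest in log to the geometric mean of the
growth bounds (≈1.02, the expected per-frame growth) wins. Unmatched
cells are retried for `track.lost_cell_time` frames (gaps interpolated
linearly and flagged) and then finalized as lost; unmatched regions
become new cells only within `track.new_cell_y_cutoff` px of the closed
end, and never while an unmatched cell sits within one cell length of the
region — in a mother machine cells cannot appear mid-channel, so a region
next to a cell that just failed its ratio check is that cell, and
instantiating it as a new record would create a duplicate that corrupts
later division links.

Cell length defaults to the region's extent along the channel axis. The
moment-based equivalent-ellipse major axis (`length_method = "moment"`) is
also available, but note that for a solid rod it overestimates the true
length by up to sqrt(4/3) (15% for a rectangle), so extent is the default
whenever lengths are compared with physical ground truth. Width is the
mean row width; volume uses the capsule (spherocylinder) model.

At a division, the mother's division length `S_d` is recorded as the sum
of the two daughters' birth lengths, so length is conserved exactly at
the split and the septum ratio (upper daughter / total) is well defined.
Generation time is `(division frame − birth frame) ×
calibration.frame_interval`; the elongation rate is the least-squares
slope of log length against time over the cell's observations.

### Physiology statistics

Population statistics are computed on complete cycles only: cells with an
observed birth and division *and* a tracked parent and two tracked
daughters. Distribution summaries report n, mean, SD (n−1) and CV.
Correlation plots use equal-count (quantile) bins with a minimum of 20
points per bin by default, reporting the per-bin mean and standard error;
a weighted line through the bin means tests e.g. the adder signature
(slope ≈ 0 of added length vs birth length, slope ≈ 1 of division vs
birth length).

Fluorescence is integrated over each cell's mask pixels (plus per-area and
per-volume normalizations). Foci are detected by a Laplacian-of-Gaussian
filter at a configurable spot scale; local maxima above a threshold in
units of the response SD become foci and are assigned to the cell whose
mask contains the peak. The spot scale and threshold are exposed as
parameters.

### Evaluation

Segmentation quality is scored at the cell level: per frame, predicted and
ground-truth regions are matched one-to-one greedily in descending IoU,
accepting pairs at IoU ≥ 0.6 (inclusive; a strictness flag is provided
because printed descriptions of this threshold vary). Matches are true
positives; unmatched predictions and truths are false positives and
negatives; the Jaccard index is TP/(TP+FP+FN). Greedy matching equals the
optimal assignment on all small frames we generate (verified against an
exhaustive oracle in the tests); summaries print JI at two decimals,
machine output keeps full precision.

## The synthetic generator

The generator is the package's source of ground truth, not a photorealism
exercise. Its defaults emulate slow-growing rod-shaped bacteria imaged
every 2 min at 0.1 µm/px: mean added length 2 µm with CV 0.15, elongation
rate ln(2)/60 min⁻¹ with CV 0.07 (60 min doubling), septum position
0.5 ± 0.03, cell width 0.8 µm in a 13 µm channel. Added length, rate and
septum fraction are drawn independently per cell from normal distributions
truncated at ±3 SD (septum additionally to (0.1, 0.9)); the near-symmetric
unimodal distributions seen in real data motivate the choice, but no
published generative model exists for these experiments, so all
distributional choices here are explicitly ours. Division is resolved at
frame resolution: the first frame at which the added length reaches the
per-cell target is the division frame, which introduces a small positive
overshoot in realized added lengths (about half a frame's growth, ~2% at
the default frame interval) — visible as a slight excess of the realized
mean added length over the drawn mean at coarse frame intervals.

Rendering draws cells as anti-aliased capsules (dark on a light channel
interior, dark device walls, bright trench), applies an integer random-walk
stage drift (±1 px per frame, clipped to ±5), a 1 px Gaussian blur, and
additive Gaussian noise, quantized to 16 bits. The default noise SD is
0.043, putting the cell/background separation at roughly 10 noise SD. We
verified that at 5 SD of separation the per-pixel margin between the Otsu
threshold and the cell interior falls to ~2.3 sigma and the
distance-transform cores begin to fragment, so 5x renders are treated as
stress tests (the noise knob is exposed) rather than the default
condition. What passing on these fixtures does *not* show: robustness to
uneven illumination, cell-width variation, filamentation, out-of-focus
drift, or the textured phase halos of real micrographs — none of which
the renderer emulates.

## Numerical choices and degenerate inputs

- Otsu on a constant image is an error ("no contrast"); a constant or blank
  subtracted frame segments to zero regions, which is valid.
- Threshold ties across empty histogram bins resolve to the plateau
  midpoint, making the binary partition deterministic.
- The random walker is seeded-label-preserving; with a single seed class
  the whole frame takes that class; with no unseeded pixels it is the
  identity.
- Channel classification of a zero-variance (constant) profile pair scores
  1 by convention (a perfectly static scene), labeling the channel empty;
  single-frame stacks cannot be classified and are labeled full with a
  warning.
- Alignment of identical frames returns shift (0, 0) with score 1; a flat
  drift-correlation surface yields zero shift with a warning.
- Coordinates are 1-based (R convention) with row 1 at the closed channel
  end; crop boxes are inclusive ranges. Calibration defaults to 1 µm/px
  and 1 min/frame, i.e. uncalibrated output is in px and frames.

## Problem sizes used in the checks

The end-to-end checks run a seeded fixture of 5 occupied channels (plus
one empty template channel) over 300 frames (10 generations at the
default 2 min interval), yielding roughly 100 fully tracked complete
cycles and ~5,600 cell instances — enough for 3-standard-error comparisons
of the cycle-parameter means while keeping a full run in the low minutes
on one core. The threshold-bias sweep re-segments the same fixture at
Otsu scales 0.8–1.2. Property checks (threshold oracle, matching oracle,
morphology oracle) use hundreds of small randomized toys instead of large
images.

## Known limitations

- The classical chain is tuned for tightly confined, well-separated rods
  in phase contrast; it is expected to fail on crowded 2D growth, strongly
  tilted devices, or low-contrast modalities.
- Division detection is frame-quantized and intensity-driven; on real
  data classical thresholding tends to split cells one or two frames later
  than boundary-based methods, systematically shifting birth/division
  times but not generation times (the shift cancels in differences). The
  lineage comparison helper therefore tolerates ±2 frames.
- The threshold-bias sweep on rendered fixtures shows the expected
  monotone shrinkage of mean cell area with increasing threshold scale,
  but the random-walker refinement re-anchors boundaries to the intensity
  gradient, so the magnitude (~1% over the 0.8–1.2 sweep) is smaller than
  the inter-method discrepancies reported on real data (5–10%), where
  methods differ in more than the threshold.
- Rotation correction, proprietary microscope formats, learning-based
  segmentation and tracking, and interactive curation GUIs are out of
  scope.
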