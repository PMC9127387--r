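---
title: "Models and design choices in fluorotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in fluorotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fluorotrack` tracks two kinds of targets in videofluoroscopic swallowing
study (VFSS) video: an amorphous, flowing barium bolus and rigid tissue or
organ landmarks. This vignette explains the underlying models, the
parameters that matter, how the synthetic benchmark is built, and the
design decisions taken where the methods left genuine freedom.

## Conventions

Frames are numeric matrices on the 0--255 scale with rows indexing y
(down) and columns indexing x (right); pixel coordinates are 0-based.
Boxes are `(x, y, w, h)` with the half-open convention
`[x, x+w) x [y, y+h)`. The rotation into a spine-anchored coordinate frame
composes translate(-O), clockwise rotation, translate(+O) in homogeneous
coordinates and samples the source bilinearly with zero fill; a numerical
identity test (100 random angles) confirms the composition equals the
direct closed form.

## Watershed segmentation and the "segmentation level"

All region extraction runs marker-controlled watershed on the Sobel
gradient magnitude (the standard gradient preprocessing that removes
quantization-induced minima). The *segmentation level* `c` is realized as
an h-minima marker suppression of depth

\[ h = h_\mathrm{base}\, 2^{\,c-1}, \qquad h_\mathrm{base} = 4
   \text{ intensity levels}, \]

so larger `c` merges shallower basins and yields coarser partitions;
lowering `c` never decreases the region count (a tested invariant). The
doubling schedule makes each level a clearly distinct granularity while
keeping `c` a small integer, which is how the level is used operationally
(start at `c = 4`, lower toward `c_min = 1` while refining). `EBImage`'s
watershed `tolerance` implements exactly this suppression on the inverted
gradient.

## Discrete-point bolus tracking

The bolus deforms freely, so the tracker stores no appearance template.
Its state is a mask, a set of `round(gamma_p |S_p|)` random pixels of the
mask (default `gamma_p = 0.1`), the mask's mean gray `g_avg`, and a
centroid velocity. Each new frame: predict the box by the velocity, expand
by 1.2, segment, and score each region by

\[ \mathrm{Eva} = \theta_0 + \theta_1 \frac{n_\mathrm{in}}{n_\mathrm{tot}}
   + \theta_2 \frac{n_\mathrm{in}}{\mathrm{area}}
   + \theta_3 \lvert \overline{g} - g_\mathrm{avg} \rvert . \]

The weights are free parameters. Defaults are
`theta = (0, 0.5, 0.3, -0.01)` with acceptance band `[0.25, Inf)`: a
region holding most points scores above 0.25 from the first two terms
alone, and the **negative** `theta_3` makes a gray mismatch penalize the
score. A positive weight on an unbounded absolute gray difference would
let bright, point-free background regions enter the acceptance band, so
the penalty sign is a deliberate design choice. Rejected regions are
re-segmented one level lower (restricted to their own pixels); an
oversized rejected region (area above `beta_img = 0.5` of the box)
triggers a global re-segmentation of the whole box one level lower; at
`c_min` the fallback is gray-band thresholding with
`[g_0, g_1] = [0, g_\mathrm{avg} + 25]` (the bolus is darker than the
anatomy; at initialization, before `g_avg` exists, `g_1` defaults to the
Otsu threshold of the box). Accepted pixels are merged, opened and closed
with a 3x3 box element, and the points are resampled from the new mask —
resampling rather than advecting points is the right choice for a target
whose material turns over every frame.

## Improved inter-frame differencing

The classical difference mask `|f_t - f_{t-1}| > m` responds both where
the target arrived and where it left; the vacated "residual" is the main
false-positive source. The improved detector works inside the expanded
tracking box with exactly `{previous ROI, previous frame, box}` as state:

1. bilateral denoising of both frames in the box (spatial sigma 2 px,
   range sigma 25 levels), then a shared linear stretch of the box range
   so both frames map identically;
2. `d_frame`: thresholded absolute difference (`t_diff = 15`, scaled with
   the stretch);
3. `d_seg`: previous-ROI pixels whose current gray exceeds `t_p` (Otsu of
   the box by default) — the residual, now bright background;
4. `seg_c = (d_frame OR seg_p) AND NOT d_seg`, then a 3x3 open-close.

The combination is implemented as set operations. Read as plain pixel
arithmetic, a vacated pixel (`d_frame = 1`, `seg_p = 1`, `d_seg = 1`)
would evaluate to 1 and the residual would survive — the opposite of the
method's purpose — so the union-minus reading (with the output clipped to
{0,1}) is the one implemented.

Localization then fuses the mask with the discrete points and gray
information: connected components are kept if they contain a point or
their mean gray is within 20 levels of `g_avg`, and the kept mask is
re-grown to the connected gray-band pixels it touches. The re-growth step
matters in practice: denoising and morphology each shave a few boundary
pixels per frame, and without re-growth those losses compound along the
frame chain until the mask dies. When the recovered mask collapses below
40% of its predecessor (violent motion carrying the target outside the
search box — the scenario this detector exists for), the frame is retried
with a doubled box expansion.

## Correlation-filter tracking

The position filter is a kernelized correlation filter: ridge regression
over all cyclic shifts of the search window (2.5x the target box), with a
Gaussian kernel (`sigma_k = 0.5` on normalized features,
`lambda = 1e-4`), gray plus 9-bin HOG features on 4-px cells, a cosine
(Hanning) taper, and a Gaussian regression target of bandwidth
`sqrt(wh)/16`. All correlations are frequency-domain products; a
brute-force spatial oracle verifies them to 1e-8 in the tests. The
response peak is interpolated with a one-cell parabola, which recovers
sub-cell displacements despite the 4-px HOG grid. Templates update by
exponential blending at `theta = 0.02`.

The scale filter is a 1-D discriminative correlation filter over a
33-level pyramid (step 1.02, symmetric around 1): each level is resized to
a fixed scale-model size (32 px max side), HOG-featurized, unit-normalized,
projected on a PCA basis learned at initialization (32 dims), and
Hanning-weighted across scales. Single-step zooms near 1.02 sit below the
one-shot sensitivity of so small a pyramid; the filter is incremental by
design and follows a 1% per-frame zoom to the correct final size, which is
what the tests assert.

Watershed edge correction snaps the box *size* (never the position, which
the correlation peak owns) to the dominant watershed region's bounding box
when that region overlaps the box with IoU >= 0.5 and comparable area
(ratio within [0.7, 1.4]), and only on high-confidence frames — an
occluder's edges must never be learned into the scale.

### Occlusion handling

The confidence signal is the normalized cross-correlation (NCC) of a
lightly smoothed, target-sized crop at the candidate position against a
stored target template, maximized over a +/-4 px neighborhood. Unlike the
filter's response peak or a whole-window similarity (both were evaluated
and discarded — the search window is mostly background, so those signals
barely move when the target disappears), the target-crop NCC is close to
0.8--0.95 when the target is present and near zero over an occluder or
background, on an absolute scale.

A frame is occluded when the NCC falls below `occl_enter = 0.45`. While
occluded the filters are frozen (the dual coefficients are bit-identical
across occluded frames), and the box coasts on a velocity that is only
ever learned from high-confidence frames, damped by 0.85 per occluded
frame so it cannot run away. Reappearance is tested each frame at four
point hypotheses — the detector's candidate, the coasted position, the
anchor (last position with NCC >= 0.7) and the undamped velocity
extrapolation from occlusion entry — accepting at `occl_exit = 0.55`; if
all fail, a coarse template sweep of the search area may relocate the
target, but such a long-range jump requires NCC >= 0.7, since a partial
match at a passing distractor must not capture the tracker. Template
learning on unflagged frames scales with the NCC, so an occlusion the gate
misses still pollutes the filter only marginally. A 20-frame cap releases
a falsely entered occlusion state.

The MOSSE, gray-only (CSK-like), no-scale (KCF) and gray+scale
(DSST-like) baselines in `compare_trackers()` run with the occlusion
machinery and the watershed correction disabled: those are contributions
of the combined method, and an ablation that leaves them in the baselines
would not measure anything.

## Background-subtraction baselines

ViBe keeps 20 samples per pixel initialized from the first frame's
8-neighborhoods; a pixel is background when at least 2 samples lie within
radius 20 of its value (the classic published defaults, verified
pixel-for-pixel against a counting oracle). The stochastic update runs at
1-in-16 per background pixel, temporally on the pixel's own model and
spatially on a random neighbor. The spatial update refreshes the
neighbor's model with the *neighbor's* current value: with the textbook
variant (inserting the updating pixel's value) a suddenly stopped
foreground object is never absorbed into the background, whereas the
"random protection" strategy is described precisely as integrating stopped
objects — so the absorbing variant is implemented, and a test demonstrates
the absorption.

The EGMM baseline is the non-parametric balloon estimator: per pixel, the
kernel half-width expands until it covers the `k = 5` nearest of the last
50 history values; the density estimate `k / (2 L D_k)` is compared
against a threshold of 0.005, chosen so that a value at the mode of a
tight history (spread <= 5 levels) is background while a value 100 levels
away is foreground. `D_k` is computed by binary search on the 0--255
integer grid — the resolution the 8-bit data carries.

Both baselines store 20--50 values per pixel; the improved difference
detector stores one frame and one binary mask, which is the
memory-footprint contrast the detector comparison also asserts.

## Metrics

APE is the mean Euclidean center distance over common frames (mask
centroids for detectors, box centers for trackers); AOR is mean
intersection-over-union (chosen over overlap/truth-area for symmetry);
accuracy is the success rate at IoU >= 0.5, the standard benchmark
operating point, with the threshold configurable.

## The synthetic benchmark

No clinical recordings ship with the package, so the generator emulates
the scene structure the trackers face: a mid-gray anatomy background
(blurred random field plus a fixed dark spine band), a dark deformable
bolus (ellipse with seeded smooth jitter of radius, eccentricity and
intensity) advected along a smooth path, rigid textured organ patches
under translation and scale, opaque occluder bars, and
Gaussian-plus-Poisson-like noise added last; truth (masks, boxes,
centroids, occlusion flags) is recorded pre-noise so metric ceilings are
exact. Scene sizes follow the two study views: 50-frame side-view scenes
and 30-frame elevation scenes whose small target dwells motionless and
then moves abruptly at ~6 px/frame.

The six-preset suite (`clean_translation`, `occlusion_pass`,
`forward_lean`, `bolus_interference`, `scale_change`,
`elevation_small_target`) was fixed once as the study conditions.
Problem sizes (120x160 or 100x120 px, 30--50 frames) keep a full
comparison run in minutes on one CPU.

What passing these tests shows — and does not. The generator reproduces
the geometry and noise character of the tracking problems, not radiograph
physics: no scatter, no beam-hardening, no anatomical deformation of the
background, no soft tissue moving behind the bolus, and its occluders are
uniform bars rather than hands. Success here demonstrates that the
algorithms behave as designed under their intended failure modes;
clinical-grade accuracy numbers can only come from clinical data.

Detector and tracker comparisons are seed-averaged (5 and 3 replicate
scenes respectively): single-scene success rates sit near the ceiling and
can tie or flip by one frame.

## Degenerate inputs and numerical notes

Constant frames make global contrast stretching undefined (returned
unchanged with a warning); frames are double matrices throughout, so the
stretch maps endpoints exactly and intermediate values are not truncated.
Empty bolus masks flag the state lost; the box coasts on the frozen
velocity, and the multi-target manager terminates a target only after more
than `lost_patience = 10` consecutive lost frames (an occluded organ is
*not* lost — the combined tracker's whole point is to survive occlusion).
All RNG flows through explicit seeds; per-target and per-frame streams are
derived from the base seed so that multi-target runs are independent
target by target (running any subset reproduces its trajectories exactly)
and every pipeline is byte-reproducible.

## Known limitations

* The bolus tracker assumes the bolus is the darkest structure in its
  search box; a second dark object entering the box can be absorbed into
  the mask (the multi-target manager runs separate instances instead).
* The improved difference detector needs a sensible first-frame
  initialization (watershed in a user box); it does not self-initialize.
* The scale filter quantizes to 2% steps and is insensitive to sub-step
  one-shot zooms.
* Rotation into the spine frame uses one fixed anchor per sequence; a
  per-frame tracked anchor is possible by feeding a tracked landmark back
  into `rotation_spec()`, but is not automated.
* AVI input is not read; export the video as a PNG or TIFF stack.
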