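---
title: "Methods: tonotopic map analysis and core delineation in tonocore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tonotopic map analysis and core delineation in tonocore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tonocore` implements a quantitative analysis chain for tonotopic maps of
human auditory cortex measured on flattened cortical patches: estimation of
voxel preferred frequencies and tuning widths from 7-point frequency
response functions, tonotopic gradient fields with automated
gradient-reversal detection, delineation of the auditory core from
functional (frequency selectivity) and structural (myelin) markers, ROI
geometry in a Heschl's-gyrus (HG) coordinate frame, and cohort-level
circular statistics with pixelwise Hotelling T² consistency testing. A
synthetic-cohort generator with fully known ground truth makes every stage
testable end to end. This vignette documents the models, the parameters
that matter, the numerical choices, and the known limits.

# The cochlear (ERB-number) frequency scale

All tuning computations run on the ERB-number ("Cam") scale,
`E(f) = 21.4 * log10(0.00437 f + 1)` with `f` in Hz, on which one unit
equals one normal cochlear filter bandwidth,
`ERB_N(f) = 24.7 (4.37 f/1000 + 1)` Hz. Tuning widths expressed in ERB_N
are standard deviations in Cam units (one ERB_N step = one Cam). The 7
stimulus frequencies are evenly spaced on this scale between 251 and
6009 Hz; the formula reproduces the presented 4th and 6th values (1501 and
3839 Hz) exactly, while positions 2 and 5 land on 507 and 2424 Hz, 2 and
1 Hz away from the presented 505 and 2423. The rounding convention behind
those two presented values is not recoverable, so interior frequencies are
treated as reproducible to ±3 Hz. No Cam-to-octave conversion is offered:
no single convention we tried reproduces the usual printed octave
equivalences, so the package does not promise one.

# Preferred-frequency estimation and debiasing

Voxel tuning curves are the 7 GLM amplitudes `beta_i` at the stimulus
positions `F_i` (Cam). The centroid
`C = sum(max(beta_i,0) F_i) / sum(max(beta_i,0))` is strongly biased toward
the middle of the stimulus range: values at the edges can only occur when
all other responses vanish. The debiasing procedure samples a bank of
hypothetical Gaussian tuning curves (modes every 0.1 Cam from 0 to the Cam
position of 16.2 kHz; widths on a 60-step geometric grid from 0.4 to 20
ERB_N), computes each entry's (C, S) exactly as for measured curves, and
assigns each measured curve the mode of the entry closest in the (C, S)
plane (sum of squared differences, both coordinates in Cam; distance ties
resolve toward the smaller mode, then the smaller width). Matching operates
in Cam because the stimulus positions enter the centroid in cochlear units.

The spread uses the weighted-standard-deviation reading
`S = sqrt(sum(w (F_i - C)^2) / sum(w))`, `w = max(beta_i, 0)`. A literal
unnormalized variant (`sum((F_i - C)^2) / sum(beta_i)`, no radical) is
selectable via `tuning_spread(form = "literal")` but is not recommended:
its scale is dominated by total response mass and it degrades mode
recovery badly.

**Identifiability limit.** The map (mode, width) → (C, S) is not injective
for widths that are narrow relative to the ~4-Cam stimulus spacing: for
example a Gaussian at mode 10.77 with width 1.00 and one at mode 9.70 with
width 0.68 produce the same (C, S) to three decimals. No bank density or
tie-break can separate such pairs, so debiased modes of very narrow curves
(width ≲ 2 ERB_N) can err by several Cam between stimulus positions. For
widths ≥ ~4 ERB_N — the physiologically typical regime here — recovery is
accurate to about one bank step. This is a property of the
centroid-and-spread matching procedure itself, demonstrated in the test
suite and accepted as a documented limitation.

Preferred-frequency maps average the debiased estimates over the middle 5
of 11 cortical depths (depth fractions 0.3–0.7) and receive no surface
smoothing, to retain maximal spatial detail.

# Tuning-width fitting

Tuning widths come from fitting, not from the spread: zero-clipping
distorts curve shapes. Curves are first recentred by an integer index
shift so that the centroid aligns with the nearest stimulus position
(vacated samples become missing and are excluded), averaged across all 11
depths, and each of the 7 aligned sample maps is smoothed with a ~3-mm
(9-pixel) isotropic Gaussian kernel. A 4-parameter Gaussian — mode, width
(bounded to [0.4, 20] ERB_N), height (non-negative) and a non-positive
baseline offset — is then fitted per pixel by least squares. The
implementation profiles the two linear parameters exactly on a dense
(mode, width) grid (modes ±4.5 Cam around the central stimulus in 0.25
steps, 40 geometric widths) and polishes the solution with a vectorized,
damped Gauss-Newton iteration with an active set; because the objective
has two basins for wide curves (mode shifted by about one stimulus
spacing, compensated by height and offset), the best grid point on each
side of the central stimulus is polished and the better final fit wins.
This is nonlinear least squares by variable projection, run
simultaneously for all pixels, and recovers noiseless widths to better
than 2% in [2, 10] ERB_N. Exactly flat curves carry no
tuning information and are marked invalid, as are pixels with fewer than 5
aligned samples or a degenerate (zero-height) optimum.

# Responsive-voxel selection

With trial-series input, per-run series are high-pass filtered by
projecting out discrete-cosine components below 0.01 Hz (run mean
retained), converted to percent signal change about the run mean, and
concatenated. The GLM has one indicator regressor per stimulus frequency
plus one intercept per run (the silence baseline); whether the original
analysis used run-wise intercepts after concatenation is unstated, so the
per-run choice is configurable. Auditory-responsive voxels are those whose
joint sound-versus-silence F-test (7 numerator degrees of freedom)
survives FDR correction.

The FDR routine — shared between voxel selection and the consistency
analysis — defaults to the two-stage adaptive step-up: stage one runs the
linear step-up at level `q` and estimates the null count as `m - r1`;
stage two reruns it at `q * m / (m - r1)`. Since the stage-two level is
never below `q`, the selection always contains the plain BH selection, and
mixture simulations confirm realized-FDR control at `q`. The more
conservative variant with both stages at `q/(1+q)` and plain BH are
selectable. With beta-stack input (no trial series), the responsive mask
uses the display criterion instead: at least one response above 1% signal
change, evaluated on depth-averaged amplitudes.

# Gradient fields and reversal detection

Gradients come from the standard 3×3 Sobel kernels, scaled to map units
per pixel; pixels whose 3×3 neighborhood leaves the mask are invalid. All
smoothing is mask-aware normalized Gaussian convolution (kernel
renormalized over in-mask support), which preserves constants on any mask.

Reversals are detected per pixel along 180 equidistant orientations: the
gradient vectors of the two straddling neighbors (nearest pixel at ± one
unit step; the sampling scheme is not specified in the original
description, and opposite-neighbor straddling is the default) are
projected onto the orientation, and a strict sign change counts as a
reversal at that orientation. The per-pixel count (0–180, which is also
the relative angle of the flanking gradient directions in degrees) is
thresholded at a criterion of 10 — reading the published "10°" as at least
10 reversal orientations. Individual-hemisphere fields are smoothed with a
6-mm FWHM kernel first; group maps remain interpretable down to 2–4 mm.

Frequency denominations are assigned by a local-extremum test: the
across-reversal axis at a pixel is the axial (angle-doubled) mean of its
reversal orientations, pooled count-weighted over a small neighborhood to
stabilize band-flank pixels; the preferred frequency is sampled
bilinearly one pixel to each side along this axis, and the pixel is
`low` at a strict local minimum, `high` at a strict local maximum. On an
oblique mirror-symmetric field the thresholded count band is several
pixels wide (the per-orientation flip loci fan out when the field carries
an along-axis component), but the denominated pixels localize the reversal
line to well under one pixel RMS.

Clusters are 8-connected components per denomination; each cluster's axial
orientation is the first right-singular vector of its centred pixel
coordinates. Disconnected but collinear clusters (axes within 20°, closest
endpoints within 3 mm — tolerances chosen here, since the original joining
rule is not described) are merged.

# ROI geometry

The HG frame comes from the curvature map: Sobel gradients within the HG
ROI point across the gyral ridge, so the second right-singular vector of
the gradient matrix runs along it; the frame origin is the ROI centroid. A
singular-value ratio below 1.05 flags an unstable axis. The HG ROI itself
is algorithmic by default (thresholded positive curvature within the
responsive mask), with manual masks accepted as overrides; positive across
coordinates are anterior by convention. All axial quantities are processed
via angle doubling to avoid 0/180 wrap artifacts.

Core ROIs threshold the tuning-width map (below criterion) or the
conditioned myelin map (above criterion) at an individualized criterion
set midway between the mean over the TE1.0 label and the mean over the
pooled anterior/posterior non-core labels; the supplementary variant using
all three TE labels is selectable, as is restriction to the largest
connected component (off by default — the original choice is unstated).

Gradient ROIs fill the bands between the joined reversal polylines
(anterior high line to low line, low line to posterior high line),
expressed in the HG frame and clipped by the responsive mask; their
mediolateral ends are bounded only by that mask. A 1-mm margin adjacent to
each bounding line is excluded: reversal pixels mark the border itself,
where gradient directions mix across the reversal, and including them
biases ROI-average directions toward the HG axis.

Overlap between a core ROI and a gradient ROI divides the intersection by
the smaller of the two; the overlap ratio (anterior over posterior) runs
from 0 to infinity with 1 meaning balanced overlap. The low-reversal
orientation is the pixel-count-weighted axial mean of low-cluster
orientations within the HG ROI. Curvature-by-frequency tables bin ROI
pixels by preferred frequency (equal-count by default) and average
curvature per bin.

# Structural map conditioning

MTR is `(M0 - MSAT)/M0`. Depth stacks are residualized per depth on the
PD-proxy (standing in for the B1 error), curvature, and thickness, by OLS
with intercept; the output is residual plus intercept, preserving the map
mean — pure residuals would lose the level needed for thresholding (the
original treatment of the mean is unstated; mean preservation is this
package's documented choice). Only linear covariate removal is performed.
Depth averaging uses the plateau depths 0.3–0.7 followed by minimal ~2-mm
smoothing.

# Circular statistics and consistency testing

Directional angles live in (-180, 180], axial orientations in [0, 180)
with doubling. Mean directions are resultant-vector arguments; confidence
intervals use the standard Fisher-style circular construction employed by
the common circular-statistics toolboxes (documented in the code); it is
mildly conservative at moderate concentrations (~97% empirical coverage at
the 95% level for κ = 4, n = 24), which we accept since any standard
circular CI is admissible here. The one-sample Hotelling T² test uses
`T2 = n xbar' S^-1 xbar` and `F = (n-2)/(2(n-1)) T2` with (2, n-2) degrees
of freedom. The consistency map smooths each hemisphere's HG-frame-aligned
field by 3 mm, tests each pixel with at least 3 valid hemispheres, and
FDR-adjusts over the responsive mask with the shared routine.

# The synthetic cohort

The generator emulates the study geometry with analytic ground truth. In
the HG frame (u along the axis, v across), the preferred-frequency field
is

    cam(u, v) = cam_min + g u + s_side * tri(|v - v0|)

where `tri` folds at the band width (8 mm by default), creating the
low-frequency reversal line at `v0` parallel to the HG axis and
high-frequency reversal lines at `v0 ± 8 mm` beyond which the field
mirrors back. Requiring gradient directions at ±70° from the HG axis
*and* a reversal line parallel to that axis forces the along-axis slope
`g = s cot(70°)`; consequently the field value varies along the reversal
lines, and the configured `cam_range` is realized as the across-band span
(every across-axis section attains the extremes on the reversal lines).
The default span is 10–18 Cam (about 450–1350 Hz): with the induced
along-axis sweep this keeps the entire field inside the 7-stimulus span,
emulating a protocol whose stimuli cover the mapped range. Outside that
span the estimates degrade exactly as for real data (noisy monotone curves
map to expanded, then saturated, extreme modes), which is demonstrable by
widening `cam_range`.

Other truth components: a second-derivative-of-Gaussian curvature ridge
for HG (positive crest, negative banks), a thickness map with mild
along-axis undulation, elongated high-myelin and narrow-tuning ellipses
(11 × 4.5 mm and 12 × 5 mm semi-axes, parallel to HG), TE-style label
bands along HG, and anterior/posterior non-core labels. Betas are
Gaussians in Cam with mode and SD from the truth maps (height 2% signal
change), with i.i.d. noise per depth (SD 0.6 by default — a moderate
level chosen so that split-half reliabilities fall mid-range); structural
stacks add a depth profile (plateau at 0.3–0.7), a curvature-coupled
nuisance for residualization to remove, and noise. Per-hemisphere jitter
(angles SD 8°, offsets SD 1 mm, effect sizes SD 0.02) is drawn once per
hemisphere; identical seeds give bit-identical cohorts. The null-cohort
switch replaces the V geometry by a plane ramp in a uniformly random
direction per hemisphere, centred mid-range — a type-I-error condition
for the consistency analysis whose field is estimable everywhere (a ramp
extending below the stimulus span would hand every hemisphere the same
estimator-bias field, which the Hotelling test would correctly flag).

What the generator does *not* emulate: BOLD hemodynamics and adaptation,
pial-vein artifacts, flattening distortions (all hemispheres share one
grid, standing in for spherical normalization), curvilinear reversals
(truth lines are straight, which keeps recovery analytic), and duplicated
HG morphologies. Passing recovery tests therefore shows the analysis
chain is correct and calibrated on idealized geometry — not that it is
robust to those real-data complications.

# Problem sizes and determinism

Default grids are 120 × 120 pixels at 0.33 mm (a ~40 × 40 mm patch) —
desk-scale; the cohort-recovery checks run the full default cohort of 24
hemispheres, the ordering-property and unit-test cohorts use 8 or fewer
hemispheres and 60–80-pixel grids, and the null-consistency check runs 24
null hemispheres on a 60-pixel grid. All stochastic steps flow from
explicit integer seeds; two runs with the same configuration and seed
produce identical arrays and CSV outputs. The nearest-bank-entry search is
the one compiled (C++) kernel; everything else is vectorized R.

# Known limitations

* Debiased modes of very narrow tuning curves are not identifiable
  between stimulus positions (see above); the affected regime is below
  the widths used in the synthetic conditions.
* The overlap ratio is sensitive to the detected low-line position; with
  asymmetric gradient angles the smoothed valley shifts toward the
  shallower side, so individual-hemisphere ratios scatter around 1 even
  for a perfectly symmetric core, and cohort medians are the meaningful
  summary.
* Reversal-count bands widen with field smoothing for oblique fields;
  localization relies on the denominated (extremum-tested) pixels.
* Hemispheres with extreme angle jitter can lose a detectable
  high-frequency reversal on one side; the pipeline marks them failed and
  continues, matching the intended error contract.
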