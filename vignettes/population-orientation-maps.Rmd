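---
title: "Modelling population orientation maps from non-oriented receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population orientation maps from non-oriented receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfpopmap)
```

## The scientific problem

Wide-field calcium imaging of mouse superficial superior colliculus (sSC)
shows maps of orientation-selective responses that sit along the edges of
the stimulus and change systematically with aperture size, shape and
stimulus spatial frequency — behaviour that looks nothing like the
stimulus-invariant orientation selectivity of primate visual cortex.
`rfpopmap` implements an image-computable population model showing that
such maps arise from populations of *non-oriented*, circular-symmetric
center-surround receptive fields (RFs): the aperture edge vignettes the
grating, injecting oriented energy into the stimulus spectrum, and a
bandpass RF near the edge responds most to grating orientations orthogonal
to that edge ("radial" orientations). The same machinery with V1-like
(Gabor) RFs separates what single units and pooled populations can each
explain.

## Model components and conventions

**Pixel grid.** Stimuli and RFs live on a square grid of pixel centers,
evenly spaced and endpoint-inclusive over ±`fov_half` degrees; the default
is 200 pixels over ±60°. x increases rightward and y upward; images are
matrices indexed `[ix, iy]`. The sampling limit is `1/(2·spacing)` ≈ 0.83
cycles/degree (cpd), well above the highest stimulus frequency used
(0.32 cpd).

**Gratings.** Static sinusoids at 100% contrast on a mid-gray background
(luminance in [−1, 1], background 0). Orientation follows the polar-angle
convention: 0° is a horizontal grating and angles grow counterclockwise.
Internally the wave vector sits at `orientation + 90°`; with y-up pixel
coordinates this sign realizes the counterclockwise convention (the
negated variant, natural in row-down image coordinates, would mirror every
oblique orientation). The standard probe battery is 12 orientations in 15°
steps × 4 phases in 90° steps.

**Apertures.** Hard-edged: circle, square, diamond (the square rotated
45°), half-plane edges, or none. Membership is by pixel-center inclusion
with `<=` boundary tests — reproducible hard edges with no anti-aliasing.

**Center-surround RFs.** Difference of two circular Gaussians.
`cs_ratio` is the ratio of the *volume* under the surround to the volume
under the center Gaussian, so the surround peak multiplier is
`cs_ratio · σc²/σs²`. This volume reading is the one that reproduces the
published preferred spatial frequencies (0.08 cpd for σ = 0.8/4.7 with
ratio 0.4; 0.04 cpd for 1.5/11.4 with 0.8), which we verified by
closed-form differentiation of the DoG spectrum (`dog_peak_sf()`);
a peak-amplitude reading does not. Off-center RFs are exact negations.

**V1-like RFs.** A carrier grating at the preferred frequency multiplied
by an elongated Gaussian envelope (rescaled to max 1) whose major axis is
parallel to the stripes; `σ_min = n_sub/(4√2 f_pref)` and
`σ_maj = (lw/n_sub)·σ_min` with `n_sub = 2`, `lw = 4`. Two members in
quadrature (carrier phases 0°/90°) give the phase-invariant energy
response. RF images are not norm-equalized across orientations;
discretization-induced norm differences are below 10⁻³ at the default
grids.

## The response pipeline

Responses are dot products between vectorized RF and stimulus images.
On/Off pairs are thresholded at zero and summed — for an exact
opposite-polarity pair this equals `|r|` and is invariant to stimulus
luminance polarity. Gabor pairs are squared and summed (energy).

**Stimulus-phase collapse.** The combined On/Off response at stimulus
phase φ is `|A cos(φ − ψ)|`, where ψ depends on the unit's position and
the grating's orientation. A plain 4-point mean over the sampled phases
equals `(A/2)(|cos ψ| + |sin ψ|)` — an orientation-dependent quadrature
factor that swings ±20%, an order of magnitude larger than the weak
(1–10%) edge tuning that drives every phenomenon here. Because the model's
responses are *designed* to be phase invariant, `rfpopmap` collapses
phases exactly: any balanced phase battery (one whose doubled-angle
phasors cancel, such as 0/90 or 0/90/180/270°) lets us reconstruct
`A = sqrt((2/P)·Σ r²)` and take the exact phase-circle mean `2A/π`. The
literal arithmetic mean remains available
(`average_over_stimulus_phases(…, method = "arithmetic")`). Energy
responses are already phase clean, and their balanced 4-phase arithmetic
mean is exactly invariant to the phase origin.

**Normalization and total response.** Phase-averaged responses are min-max
normalized to [0, 1] *jointly across all RF locations and conditions of
one stimulus manipulation* (all aperture conditions of the aperture
experiment, all frequencies of the frequency experiment, …), preserving
the cross-condition response ratios that drive preference transitions.
Near-constant tensors (relative range below 10⁻⁹) map to zero with a
warning — this also prevents discretization dust from being amplified to
full scale in the no-aperture condition. The total response is
`R = α·RΔ + β + ω` with α = β = 1 (a 100% ceiling over baseline) and
optional seeded Gaussian noise ω ~ N(0, 0.01²); noise is off by default
except where it is the object of study.

**Maps.** Because all RFs of a type are translated copies, responses at
every pixel are computed as zero-padded FFT cross-correlations of stimulus
and kernel, which equal per-unit dot products exactly on the pixel lattice
(tested to 10⁻⁶ relative). Per-location preferred orientation is half the
argument of the orientation-doubled resultant (falling back to the argmax
below a 10⁻¹² resultant); selectivity is the gOSI, whose display alpha is
min-max normalized per manipulation.

## Where the radial band actually lives

A center-surround unit centered *exactly on* a curved aperture rim has
half its RF off the stimulus and prefers edge-parallel (anti-radial)
orientations at every frequency; units just outside prefer the same,
weakly but selectively. The radially tuned band that the published maps
display lies about one surround SD *inside* the rim. Canonical edge
probes are therefore defined at 45° polar steps around the boundary,
inset by `σ_surround` along the inward normal for curved rims (capped at
half the in-radius; `σ_center` for surround-free cells). Straight edges
are different: the flanking aperture keeps the boundary midpoint itself
radial, so square and diamond probes sit on the boundary, matching the
edge-midpoint readouts of the aperture experiment. With this convention
the spatial-frequency sweep at the right-edge probe classifies 0.01–0.08
cpd radial and 0.16–0.32 cpd anti-radial — the transition between 0.08
and 0.16 cpd — at every one of the eight probes.

A related subtlety: classification of the 0.32 cpd condition degrades on
grids much coarser than 200 pixels (0.32 cpd approaches the coarse-grid
sampling limit), so both scale presets keep the 200-pixel stimulus grid
and reduce only the anatomical grid, the bar grids, and optional outputs.

## Bar stimuli

A 2°-wide bright bar sweeps across a simulated display (background 0)
surrounded by dark offscreen area (−1). Display edges act either as a
*mask* (the bar slides behind the edge) or a *boundary* (the bar is no
longer shown once it would cross the edge along its motion axis; the last
frame has its leading edge exactly on the edge). Sweeps have fixed
duration: every center position is one frame, and positions where no bar
is shown are blank frames with baseline response. This is precisely the
mechanism of edge selectivity — an RF at a vertical display edge sees
boundary-limited vertical bars for a shorter total time than horizontal
bars sweeping the full display.

Bar responses use the linear on-center route with the no-bar baseline
subtracted; after subtraction the response is the bar-overlap integral,
which the thresholded route yields as well (the rectified pair would make
the negative display-edge baseline non-monotone in bar overlap and break
the zero-baseline bookkeeping). Responses are normalized per RF to a
maximum of 1 across all presentations; `OS_bar = |R̄h − R̄v|/(|R̄h| + |R̄v|)`
with preference given to the larger mean. Because the DoG kernel and
every bar frame minus its background are separable (rank-1), bar response
fields are assembled exactly from 1-D Gaussian correlations and outer
products — verified against rendered-frame dot products — making the full
1200-pixel grid sweep cheap. Bar grids use *even* pixel counts (1200
full / 240 test over ±30°): odd grids place pixel centers exactly on the
display edge and bias the orientation sums by half a peak-column mass,
whereas with even grids the mask-mode horizontal:vertical ratio is exactly
1 at any resolution. Larger RFs spread selectivity farther from the
display edge; this is summarized as the |OS_bar|-weighted mean distance
from the edge, which increases strictly across the three RF sizes (a
fixed-threshold selective *area* is not monotone — the largest RF is
weakly selective everywhere — so the spread statistic is the faithful
reading of "more widespread").

## Retinotopy and population pooling

The anatomical↔visual correspondence is trained from ten anchor pairs by
natural-neighbor (Sibson) interpolation, implemented from first principles
via convex polygon clipping of Voronoi cells (no installed package
provides it): exact at anchors, linear-precision, continuous inside the
anchor hull, with queries outside the hull excluded rather than
extrapolated. The published anchor coordinates exist only as a figure, so
the default anchor set is *synthetic*: a 90° rotation (clockwise from
visual to anatomical space) with a mild radial warp spanning the ±0.83 mm
anatomical and ±40° visual windows. No quantitative result depends on it —
all acceptance-level quantities are evaluated in visual coordinates — and
`read_anchors()` accepts measured anchor CSVs.

Responses at anatomical grid points (241 × 241 by default) are bilinear
averages of the four surrounding visual-grid responses; population
responses are Gaussian-smoothed on the anatomical grid (SD 0.0083 mm ≈
0.44° of visual space). The kernel is truncated at 4 SD and renormalized:
at 3 SD the truncated kernel's second moment falls 2.7% below its nominal
value, while at 4 SD both the mass (10⁻⁴) and moment (0.1%) errors are
negligible. Missing cells propagate through smoothing by renormalizing
the kernel over valid pixels.

For V1-like populations, one of the eight RF orientations is drawn
uniformly at random per anatomical sample and kept across all stimulus
conditions there. Population pooling of these random draws is what makes
the V1-like population radial along the aperture: in the visual-coordinate
emulation the draws are made on a 2× upsampled grid so that the 0.44°
kernel pools roughly the published 16–25 independently oriented units.
Even then single pooled pixels keep finite-sample orientation noise
(≈ depth/√n), so the population-scale radial claim is evaluated as the
alignment aggregated over the whole ring at the aperture boundary, where
the V1-like band lies; the center-surround probe statistics are pointwise
and exact.

## Preference switching

A fixed set of 53 units inside the central 20° × 20° region views 36
orientations through a horizontal half-disc, a vertical half-disc, or no
aperture. The published per-unit coordinates are figure-derived and not
available, so the default placements are seeded uniform draws over the
quadrant of the central region that stays stimulated under *both* edge
conditions (x, y ∈ [1, 10]°) — the configuration consistent with the
reported robust preference switching; exact coordinates can be supplied.
Per-unit preferences are read from fitted von Mises curves
(`baseline + amplitude·exp(κ cos 2(θ − μ))`, Levenberg–Marquardt with
multiple starts, κ ≥ 0; the fitted curve is duplicated over 180–360° for
polar display), matching the model's single-unit tuning method: the
doubled-angle resultant — also reported — is biased by up to ~16° toward
the aperture's radial energy for units within a degree or two of the
edge. Center-surround units switch between 90° (horizontal edge) and 0°
(vertical edge) with a mean switch of ~90°; V1-like units stay within 15°
of their intrinsic orientation in every condition. With no aperture and
noise on, center-surround preferences scatter uniformly (resultant length
below the Rayleigh-style 95% bound `sqrt(−ln 0.05 / n)`) with negligible
gOSI.

## Numerical choices and degenerate inputs

* Aperture membership, bar membership and display membership all use
  closed (`<=`) comparisons on pixel centers.
* Flat tunings: gOSI of an all-zero tuning is defined as 0 (with a
  warning); preference falls back to the argmax with lowest-index ties;
  min-max normalizations of constants return zeros with a warning.
* The von Mises optimizer multi-starts over μ (argmax ± one step) and κ
  (0.1, 1, 5); if all starts fail *and* the curve is flat to within 5% of
  its mean level, the limiting flat fit (κ = 0) is returned, otherwise the
  failure is an error.
* Invariant phase collapse refuses unbalanced phase sets (the envelope is
  not reconstructible from them).
* Natural-neighbor weights fall back to an exact-anchor shortcut within
  10⁻⁹ of an anchor; on-hull-boundary queries are valid but their Voronoi
  cell is truncated by a large bounding box (relative error ~10⁻⁴), so
  quantitative tests use interior queries.

## Problem sizes

The `"full"` preset matches the published setup: a 200-pixel ±60° stimulus
grid, RF responses at every lattice point via FFT correlation, a 241×241
anatomical grid, and 1200-pixel bar grids with 0.25° position steps. The
`"test"` preset keeps the stimulus grid and reduces the anatomical grid to
41×41 and the bar grid to 240 pixels with 1° steps; classification-level
results are unchanged (single-unit probe computations are identical in
both presets). Full anatomical resampling is the slowest step (the
hand-rolled Sibson interpolation is a few milliseconds per query), which
is why anatomical maps are opt-in (`include_anatomical = TRUE`).

## Limitations

* RFs are purely spatial: no temporal dynamics, hence no direction
  selectivity, and static rather than drifting gratings.
* RF properties are uniform across the simulated sSC; real populations
  mix sizes and preferences, which likely accounts for the messier
  empirical transition at 0.16 cpd.
* The default retinotopic anchors are synthetic; anatomical-coordinate
  maps are qualitatively, not quantitatively, comparable to imaging.
* The synthetic stimulus battery is noise-free and perfectly calibrated
  (no display gamma, no eye movements); passing tests demonstrate the
  model's internal consistency and its reproduction of the published
  simulation results, not agreement with any particular imaging dataset.
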