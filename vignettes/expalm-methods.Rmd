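---
title: "Methods: quantitative analysis of expansion-microscopy PALM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of expansion-microscopy PALM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expalm)
```

## Scope and data model

Combining expansion microscopy (ExM) with photoactivated localization
microscopy (PALM) multiplies two independent resolution gains: the sample is
physically enlarged roughly fivefold in a swellable gel, and individual
photoconvertible fluorophores are localized with nanometre precision. The
price is a set of quantitative quality-control questions — how large is the
expansion factor, is it spatially uniform at the scale of molecular
neighbourhoods, how much fluorescent protein survives gelation and
digestion, and what localization precision is actually achieved at imaging
depth. `expalm` implements the analysis chain that answers them.

Everything operates on two data structures. A *localization table* is an
ordinary `data.frame` with columns `x`, `y` (continuous nm), `frame`
(0-based integer) and optionally `intensity` and `track_id`. Coordinates
live in a fixed Cartesian convention — origin at the top-left corner of
camera pixel (0,0), the centre of raster pixel (r,c) at ((c+0.5)p,
(r+0.5)p) for pixel size p — so rendering, reading and writing never
disagree by half a pixel. An *image stack* is a (frame, row, col) array
with its physical pixel size (129 nm for the camera data this package
emulates, 10 nm for reconstructions). All simulation and analysis is 2-D:
the experiments image a single focal plane, and every quantity measured
(widths, nearest-neighbour distances, drift) is planar.

## The synthetic-data generator

No raw data accompany the study this pipeline serves, so the package ships
a generator whose ground truth is known exactly; parameter recovery on its
output is the package's acceptance surface.

A fission-yeast cell is modelled as a 2-D spherocylinder, default width
2.4 µm (the measured non-expanded cytosol width) and length 9 µm (a
typical interphase cell), optionally with a nuclear disk of diameter
2.36 µm excluded from the cytosolic marker distribution. Molecules are
placed uniformly over the interior by rejection sampling. Blinking follows
the simplest model that produces the adjacent-frame re-detections NeNA
needs: each molecule emits a geometric number of frame-contiguous bursts
(default mean ≈ 2), each of geometric length (default mean 1.5 frames),
started uniformly over the movie, for a default of 3 localizations per
molecule overall. These photophysical defaults are deliberately not tuned
to any particular fluorophore — no blinking statistics are published for
the emulated system — and are constrained only by the generator's own
invariants (emission counts, containment, reproducibility).
`on_time_frames = Inf` produces photostable, always-on emitters; this is
not mEos2 photophysics but a deliberately idealized marker configuration
used by the drift benchmarks, where the quantity under test is the
estimator, not the fluorophore.

Observed positions are `expanded true position + drift(frame) + N(0,
sigma_loc^2)` per axis. Drift is shared by all molecules of a frame and
never touches the ground truth, mirroring physical stage drift; it is the
sum of a linear component and a random walk. Localization precision
defaults follow the study regime: ~14 nm non-expanded, ~27 nm expanded.

### Expansion and distortion

`apply_expansion()` scales about the point-cloud centroid, so pairwise
distances multiply exactly by the factor — the definition of a perfectly
isotropic expansion. Imperfect expansion is modelled as a smooth,
band-limited, zero-mean displacement field added after scaling: K = 4
random sinusoidal plane-wave modes per axis, wavelengths drawn uniformly
between the minor and major bounding-box extents of the scaled cloud,
rescaled so the realized RMS displacement magnitude equals the requested
amplitude.

The wavelength band is a considered choice. A displacement field whose
wavelength exceeds the cell is locally affine, and an affine map of a
homogeneous point pattern is again homogeneous: after density matching it
is *exactly invisible* to nearest-neighbour statistics, so such a field
cannot serve a power analysis of the isotropy statistic. Sub-cellular
wavelengths (between cell width and cell length) curve within the cell,
modulate local density, and are detected; they remain orders of magnitude
smoother than the ~100–300 nm inter-molecular spacing, so "microscale"
here means within-cell, not point-to-point.

### Spot and ring images

`simulate_spot_stack()` renders point sources as integrated 2-D Gaussians
(per-pixel flux is a product of two Gaussian integrals, so total flux is
conserved up to raster truncation) over a constant background, with
optional Poisson shot noise — the diffraction-limited image model for the
retention assay. `ring_positions()` arranges sources on a circle to build
nuclear-envelope-style images for the diameter assay.

## Tracking

`link_tracks()` is a greedy frame-ordered nearest-neighbour linker with a
blinking gap: an active track claims the nearest unclaimed localization
within `max_dist` across a frame difference of at most `max_gap` (default
5, the blinking interval used by the study's tracking). Conflicts resolve
by distance, then row index, then track age, making the assignment fully
deterministic. Greedy linking rather than global assignment matches what
standard SMLM trackers do at the sparse densities involved; the oracle
tests bound its error (>99% track purity on sparse fields).

`max_dist` is a required argument rather than a default. The natural scale
of a re-detection displacement is σ√2 per axis (two independent position
estimates), so a radius of 3σ_loc — an intuitive first guess — truncates
roughly a tenth of genuine links and fragments tracks badly; the drift
benchmarks use ~7σ_loc, where linking reaches its ground-truth floor at
the densities simulated. `filter_tracks()` implements the discard rule for
trajectories of three steps and less: a *step* is an inter-detection link,
so the default keeps tracks with ≥ 4 links (≥ 5 detections); whether the
original rule counted links or detections is not documented, so the
threshold is a plain argument. `merge_track_localizations()` collapses
each track to an intensity-weighted centroid with the first frame and
summed intensity.

## Drift estimation

Three estimators, one contract: a trajectory is the apparent motion of the
sample relative to frame 0, correction subtracts it, and
`apply_drift_correction(apply_drift(T, D), D)` is exact.

**Sub-stack cross-correlation** renders temporal sub-stacks (default 500
frames) as 2-D histograms on a common grid (default 10 nm bins), measures
each sub-stack's translation against the first by FFT cross-correlation
with a 3×3 centroid refinement around the peak, anchors each offset at the
sub-stack's central frame, and interpolates linearly between anchors.
Beyond the first and last anchors the trajectory is extrapolated
*linearly* from the adjacent anchor pair: constant extrapolation would
leave the outer half sub-stack of a steadily drifting movie with errors up
to (substack_len/2)·v, which for the benchmark conditions is several times
the bin size. The method needs high localization counts per sub-stack and
shared structure between sub-stacks (molecules that re-blink); it degrades
when sub-stack statistics are poor, which is what motivates the second
estimator.

**Frame-to-frame shifts from tracked data** average the displacement of
all track links spanning each consecutive frame pair, cumulate, and smooth
with a centred moving average (default 11 frames; the ends use shrinking
windows, and the result is re-anchored at frame 0). Pairs without links
contribute zero incremental shift rather than an interpolation —
conservative, with sustained gaps left to the reliability assessment. The
estimator's key property is that per-track noise telescopes along a
track's lifetime: with a few tens of concurrent tracks its error does not
random-walk over thousands of frames, which is why the protocol mixes
bright cytosolic marker cells into every sample.

**Fiducials** follow each marker as the nearest localization within a
radius of its seed position, require ≥ 50% frame coverage, subtract each
marker's frame-0 position and average. Note the frame-0 anchor: its noise
enters every frame as a shared constant, so with k fiducials of precision
σ the per-axis trajectory error is σ√(2/k), not σ/√k.

`assess_reliability()` returns the longest movie prefix over which a
trailing-window (default 50 frames) mean of the trajectory's support stays
above a threshold — the rule used to discard the low-density tails of
movies where drift correction degrades.

Benchmark conditions (used by the acceptance tests and script): 3000-frame
movies, 60 always-on marker molecules (≥ 50 concurrent tracks), drift =
linear (0.08, −0.05) nm/frame plus a 0.3 nm/frame random-walk step, about
260 nm of total motion — typical magnitudes for an SMLM stage over a
movie of this length. Under these conditions the frame-to-frame estimator
recovers the path with RMSE below σ_loc/2 and cross-correlation below one
render bin.

## NeNA localization precision

The distance between two position estimates of the same emitter in
adjacent frames follows

p(d) = d/(2σ²) · exp(−d²/(4σ²)),

a Rayleigh density with scale σ√2 whose mode sits at σ√2; σ is the average
localization precision. `fit_nena()` histograms the adjacent-frame
nearest-neighbour distances (100 bins over a fit range of 150 nm by
default, 300 nm recommended for expanded data) and least-squares fits this
kernel plus, optionally, a Gaussian bump and a linear term absorbing
nearby-molecule and uniform background contributions. All amplitudes and
scales are bounded non-negative; the optimizer is
Levenberg–Marquardt (`minpack.lm`), initialized at σ₀ = histogram mode/√2.
Histogram least squares rather than maximum likelihood reproduces the
published procedure's behaviour and is robust to the far tail. Whether the
original analyses enabled the correction terms is not documented; both
paths are first-class and the recovery tests exercise both (the correction
terms shift a clean-kernel estimate by well under a percent).

A deliberate property of the statistic: it senses only *per-frame drift
increments*, not accumulated drift, because both detections of a
re-detection pair are one frame apart. The end-to-end improvement
benchmark therefore uses deliberately fast drift (~7 nm/frame increments)
so that the before/after difference exceeds estimator noise on every run.

## Rendering

`render_histogram()` bins localizations at 10 nm (the study's
reconstruction scale) with half-open bins over a one-pixel-padded bounding
box; the image sum equals the localization count exactly.
`blur_gaussian()` convolves with an isotropic Gaussian — by convention the
NeNA value — using symmetric (edge-repeating) mirror padding, which
conserves total intensity to machine precision. Display normalization is
left to the caller and never feeds quantification.

## Size, intensity and retention quantification

`cytosol_width()` projects the cell's point cloud on the minor
second-moment axis and reports the 1st–99th percentile span. The
percentile gesture (configurable) tolerates the stray localizations of raw
SMLM data at the cost of a small negative bias — about 2.4% for a
uniformly filled 2.4 µm cell, calibrated against the generator. The bias
is common to expanded and non-expanded cells, so expansion *factors* are
unaffected: a dataset against its own ×4.9 copy reads 4.9 exactly.

`nuclear_diameter()` subtracts the image median, refines the intensity
centroid, takes a radial mean profile in 1-px annuli, and reports twice
the radius of the outer half-maximum crossing (linearly interpolated).
For a filled disk this reads the edge to within a pixel. For a thin ring
blurred by a PSF of width σ_psf the outer crossing sits √(2 ln 2)·σ_psf
beyond the ring radius — a +2.35·σ_psf offset on the diameter (about 14%
for a 2.36 µm ring at σ_psf = 142 nm) — so `rule = "peak"` (twice the
profile peak radius) is provided as the unbiased gesture for ring-like
images. Both rules scale exactly with the structure, leaving ratios and
expansion factors unbiased either way; the diffraction-limited nuclear
measurements are in any case flagged as not directly comparable to the
SMLM-derived cytosol widths.

`spot_intensity()` integrates a 14 × 22 px spot ROI and an equal
background ROI over the first three frames, means first, then subtracts —
an ordering fixed for bit-reproducibility (linearity makes it equivalent
to subtracting per frame). `retention_yield()` expresses each protocol
step's mean intensity as a percentage of a reference step with first-order
error propagation, as does `expansion_factor()` for size ratios.

## The isotropy statistic

The microscale-isotropy question — does expansion rearrange molecules
relative to one another — is answered by comparing nearest-neighbour
structure at matched density. Cell area is the convex hull of the
localizations (the quantity "points per cell area" needs an area the data
themselves define; the hull's finite-n bias cancels between populations,
which the null calibration verifies). For each expanded cell, every
reference cell is enlarged about its centroid by s = √(ρ_ref/ρ_target) —
the closed form that reaches the target density exactly, rather than an
iterative search for it — and its mean nearest-neighbour distance
computed; the expanded cell's own mean NN distance is standardized against
the reference population's mean and (n−1) standard deviation. Since the
matching transform is a similarity, the scaled reference's mean NN
distance equals s times its unscaled value; the implementation uses this
identity (a test asserts the equality against explicit rescaling). The
scores are summarized by a two-sided one-sample t-test against zero; a
two-sample Welch variant on density-normalized mean NN distances
(mean NN · √ρ, dimensionless) is provided because the original description
does not say which population entered the test.

Under pure isotropic scaling the scores are calibrated (pooled over five
independent 30-reference/100-expanded replicates: mean z ≈ 0, sd ≈ 1,
about 5% beyond |z| = 1.96 — slightly heavy-tailed, as expected when σ is
estimated from 30 cells). A distortion field of RMS 10% of the cell width
drives mean |z| above 2 in every benchmark run. Because z-scores are
invariant to any common coordinate scale, the statistic needs no knowledge
of the expansion factor.

## Numerical and design notes

* Determinism: every stochastic routine accepts a seed and restores the
  caller's RNG state; fixed seeds give bit-identical output.
* Problem sizes in the test-suite benchmarks (3000-frame drift movies, 10⁴
  NeNA distances, ~2000 points per isotropy cell, 30 spots per retention
  condition) were chosen to match the study's reported data scales while
  keeping each benchmark in the seconds-to-minutes range.
* Degenerate inputs fail loudly and early: empty sub-stacks are
  interpolated with zero support, an all-collinear hull is an error, a
  reference population with zero spread is an error, frames outside a
  trajectory's domain are an error.
* What passing these tests does *not* show: the generator contains no
  fluorophore photophysics beyond geometric blinking, no 3-D PSF or focal
  drift, no camera gain model, and its distortion fields are smooth
  sinusoids rather than the sharp local anchoring failures real gels can
  produce. Recovery on simulated data validates the estimators, not the
  chemistry.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates every headline
quantity from scratch — worked-example ratios from the published means,
NeNA recovery at 13.9/26.5 nm, drift-recovery RMSEs, before/after NeNA on
a drifting movie, isotropy null and distortion response, simulated
retention yields at the reported 46%/22% levels, and an expansion factor
recovered from simulated cell widths — and writes them as JSON.
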