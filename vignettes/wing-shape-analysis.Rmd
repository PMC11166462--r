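---
title: "Quantifying dynamic wing shape: descriptors, shape variables and condition comparisons"
author: "wingmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic wing shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The problem

A flapping wing tracked by dense surface markers yields, at every
frame, a configuration of 3D landmark coordinates. That configuration
confounds two things: rigid stroke kinematics (where the wing is and
how it is oriented) and wing shape (how the wing is deformed). This
package separates them and quantifies the shape part in two
complementary languages:

* **Parametric descriptors** — pre-selected biomechanical measurements
  (area, second moment of area, twist, camber) with direct aerodynamic
  interpretation.
* **Shape variables** — data-driven axes of shape variation obtained
  by Procrustes alignment, tangent-space linearization and singular
  value decomposition, which capture whatever deformations are
  actually present, ranked by explained variance.

The bridge between the two (cross-correlations, standardized
regressions) is what lets the abstract shape variables be read in real
morphological terms, and the cyclic-spline machinery compares the
phase-resolved shape trajectories between behavioural conditions.

## Kinematics and the wing surface

Wing position is described by the azimuth and elevation of the
direction from the wing base (shoulder landmark) to the landmark
centroid, and by the angle α of the total-least-squares plane through
the landmarks. Elevation is reported against the horizontal plane and
α against the vertical plane of the lab frame, so a wing lying flat in
the horizontal plane has elevation 0° and α 90°. The lab frame is
right-handed with +Z opposing gravity; the wing frame has x spanwise
(shoulder to tip), y chordwise (leading to trailing edge) and z
dorsal. These conventions fix the signs of twist and camber.

Stroke cycles are segmented from the azimuth series: a light low-pass
filter (second-order Butterworth, cutoff at five times the dominant
frequency) suppresses tracking jitter, local extrema are refined to
sub-sample precision with a three-point quadratic fit, and extrema
within a quarter period of the series ends are discarded because
zero-phase filtering distorts the boundary. Azimuth maxima are taken
as pronation (downstroke onset) and anchor phase 0; per-cycle stroke
frequency is the reciprocal cycle duration.

The wing surface is reconstructed in the way a practitioner would
trace it from markers: 40 points are interpolated along the leading
and trailing edges of a template pose (the first mid-downstroke) and
joined into chordal segments; the planform is filled with internal
points at ≈0.5 mm spacing and triangulated (Delaunay, via the
`interp` package), pruning faces whose centroids fall outside the
perimeter polygon formed by the ordered edge landmarks closed across
the wing root. Edge points are paired *spanwise* — each edge is
interpolated against its normalized projection on the base-to-tip
axis — rather than by matched arclength; arclength pairing tilts the
chords in-plane wherever one edge is longer than the other (always,
for a tapered wing) and systematically distorts the sectional angles.
Two numerical details matter for the triangulation: fill points are
laid on a staggered (offset-row) grid, because square grids are
degenerate, cocircular input for a Delaunay triangulator; and the
triangulation consumes coordinates perturbed by a tiny deterministic
jitter (1% of the spacing, a fixed trigonometric hash of position)
while all areas and radii are computed from the exact coordinates.
Without this, collinear landmark runs make the triangulator fall back
on random jitter, which both corrupts the mesh (overlapping faces) and
breaks run-to-run reproducibility.

Per frame, the template mesh is projected through the tracked landmark
positions with a thin-plate spline from the template parameter plane
to the frame's 3D landmarks, ridge-regularized on the bending weights
(`lambda = 1e-4`; landmark residuals are far below 0.1 mm on
noise-free data). The system matrix is factorized once per trial, so
the per-frame cost is a pair of small matrix products. From the
projected surface come the area *S*, the non-dimensional second
moment of area *Ŝ₂² = Σ r² dA ⁄ (S R²)* (with *r* the element
centroid's distance from the wing base and *R* the wing length from
the spanwise-camber reference line), chordwise camber per section
(maximum perpendicular height of the sampled strip over its chord,
divided by chord length, the mid-span profile taken as
representative), and spanwise camber along the line from a point
0.05 c behind the shoulder to the tip.

Twist is measured from chord segments interpolated along the *tracked
edges* themselves rather than from the smoothed surface — the surface
fit mildly oversmooths the sparsely-markered tip and biases the tip
sectional angle. Sectional angles are measured against a wing-attached
frame built from the span axis and the mean chord direction. Two
properties motivated this frame over the lab horizontal: the
tip-to-root twist Θ = α_tip − α_root becomes exactly invariant to
rigid lab-frame motion (a property the descriptor should have, since
it describes shape), and by the tangent subtraction identity a uniform
sectional rotation shifts all section angles equally, so Θ recovers an
injected linear twist essentially exactly. The overall wing-plane
angle α remains lab-referenced, as a kinematic quantity. Sections for
the twist and camber profiles stop at 98% span because the chord of a
tapered wing degenerates to a point at the tip.

## Shape decomposition

Generalized Procrustes alignment iterates: center each configuration
(and scale to unit centroid size when scaling is on), rotate to the
current mean by orthogonal Procrustes with reflections excluded (the
smallest singular direction is sign-flipped when the unconstrained
optimum would reflect), re-estimate the mean, and stop when the
template changes by less than 1e-9 (relative; at most 200 iterations).
The fitted model for frame *t* is *X_t = λ_t (X_M + e_t) Γ_t + b_t*
and reconstruction through the stored transforms reproduces the input
to machine precision — this identity is tested. The residual norm is
the Procrustes distance ε, related to the Riemannian distance by
ρ = 2 asin(ε/2).

Scaling is realized as unit centroid size. Scaling is not cosmetic:
it determines where wing folding (an area change) lands. With scaling
on, folding survives as in-plane *shape* variance; the package's
fold-mode generator confirms that more than 95% of the fold residual
energy is in-plane under scaled alignment.

Tangent projection is the orthogonal projection of unit pre-shapes
onto the hyperplane tangent to the pre-shape sphere at the template:
the template maps to zero and a shape at Riemannian distance ρ to a
vector of norm sin ρ. Unscaled alignments are normalized internally
for the projection and rescaled afterwards. The tangent coordinate
matrix is column-mean-centered before the SVD so that *d²/Σd²*
describes variance about the mean trajectory; the GPA template and the
column mean differ only slightly, and the centered convention keeps
the variance language exact. A deterministic sign convention (the
largest-magnitude loading of each shape variable is positive) makes
scores and reconstructions reproducible across platforms.

Reduced-rank reconstruction inverts the projection
(*u = √(1−|p|²) m̂ + p*); at score 0 the template is returned exactly.
The in-plane/out-of-plane character of a shape variable is the mean
angle between each landmark's displacement vector and the template
plane (π/2 − ϕ in spherical coordinates about the plane normal). The
angle is computed on the tangent displacement field itself: the
spherical shrink of the full reconstruction toward the template is a
pure size artifact of the projection and would otherwise contaminate a
purely out-of-plane mode with apparent in-plane motion.

New series are scored on an existing basis by aligning each frame to
the fixed template (no re-estimation), projecting, centering with the
*training* column means and multiplying by V — this is how
treatment-condition data are measured on axes defined by the reference
condition alone, so an unbalanced design cannot tilt the basis.

Landmark sampling curves ask how much of the full marker set's shape
information survives subsampling: for each random subset the full
alignment + SVD pipeline runs on the subset and the complete-set
tangent coordinates are regressed on the subset scores; recovered
variance is 1 − RSS/TSS. The spec of the fitting step was genuinely
open (regression, interpolation, or Procrustes refitting); regression
was chosen because it is the least favorable to the subset (it cannot
exploit information outside the linear span of the subset scores) and
is deterministic. Subset draws use a private seeded RNG stream.

## Temporal statistics

Periodograms use a Hann taper and zero-padding to the next power of
two, with the zero bin excluded from the peak search. Cross-
correlations are computed at integer-frame lags, converted to
stroke-cycle fractions with the trial's mean frames-per-cycle, rounded
to the nearest 0.02 phase (the maximum-magnitude coefficient is kept
within a bin), and tested with the heteroskedasticity-robust
t-statistic t = Σe ⁄ √(Σe²) on the centered cross products
e_t = (x_t−x̄)(y_t−ȳ). The statistic's form is standard for robust
correlation testing but its calibration is verified by simulation
rather than assumed: on independent noise (1000 frames, 200 seeds) the
acceptance suite requires the flagged fraction to sit within 1.5
points of the nominal 5%.

Standardized regressions z-score response and predictors and fit
ordinary least squares with HC3 (sandwich) robust intervals; R² is
reported with and without the kinematic covariates (azimuth,
elevation), which are included to absorb mutual correlation with
stroke phase. This is a deliberate frequentist replacement for a
Bayesian multilevel fit: deterministic, dependency-light, and with the
same inferential surface (which standardized coefficients exclude
zero). For the same reason the spline intervals below are the
penalized-spline model-based intervals rather than bootstrap
intervals; a cycle-level block bootstrap was considered and rejected
because the model-based intervals are the standard practice for these
smoothers, are deterministic, and their null behaviour is verified by
simulation in the test suite.

Cycle normalization resamples each complete pronation-to-pronation
cycle onto a common phase grid by linear interpolation on the
*cumulative* phase (cycle index + phase), so neighbouring cycles
bracket the grid ends and no extrapolation artifact appears at the
cycle boundaries. The reference smooth of the typical condition is a
penalized cyclic cubic regression spline on phase (20 basis functions,
smoothing by GCV, knots pinned at phases 0 and 1). Treatment
differences are fitted to treatment − reference-prediction as an
intercept (the average difference over the cycle) plus a cyclic
penalized difference smooth, with AR(1) prewhitening of within-cycle
residuals via `mgcv::bam(rho = …)`; phases where the pointwise
interval of the difference smooth excludes zero are flagged, and the
treatment mean fit equals reference + intercept + Δsmooth on the grid
by construction. Intervals are pointwise, not simultaneous, and are
labelled as such. The AR(1) coefficient is selected on a candidate
grid by an explicitly computed Gaussian AIC on the whitened
within-cycle innovations (including the √(1−ρ²) first-observation
term), which recovers a true ρ = 0.9 within 0.05 in simulation.

## The synthetic generator

The generator is first-class code, not a fixture: it defines the
conditions under which the pipeline is validated. Defaults emulate
typical hummingbird hoverfeeding — a 41 Hz stroke of 129° peak-to-peak
azimuthal amplitude and 13.3° stroke-plane tilt, elevation at twice
the stroke frequency (the J-shaped tip path) with amplitude 15% of the
stroke amplitude, 58–64 markers on a ~55 mm wing, recording at
2200 Hz, and isotropic Gaussian tracking noise of 0.05 mm (sub-pixel
scale for this kind of videography). Analyses typically thin the
2200 Hz record to 550 Hz. Four deformation modes are superposed in the
wing frame before the rigid kinematics:

1. *Twist* — sectional inclination linear in span, implemented as a
   vertical shear so the section angle at station x is exactly
   θ(x, t); peaks at the mid-strokes.
2. *Fold* — spanwise contraction by 1 − fold·(1+sin)/2, a quarter
   cycle offset from twist (area maximal at mid-downstroke).
3. *Spanwise bend* — z displacement ∝ x², at twice the stroke
   frequency.
4. *Area redistribution* — chordwise scaling varying linearly in
   span, at twice the stroke frequency, a quarter cycle offset from
   the bend.

Twist and bend displace only z (out-of-plane); fold and redistribution
only x and y (in-plane) — asserted componentwise in the tests. Each
pair at a common frequency sits in temporal quadrature so the two time
courses are uncorrelated and the SVD can separate them.

Three design choices make the four spatial patterns mutually
orthogonal in tangent space, which is what lets injected variance
shares be recovered as SVD variance proportions. Sectional rotations
and chord scalings pivot about the local chord midline; the
redistribution gradient pivots about the chord-variance centroid
(making it orthogonal to uniform chord scaling, the direction the
size-normalization of folding projects onto); and the default
planform tapers symmetrically about a straight mid-chord line with
interior landmarks placed in pairs mirrored across it. With a curved
midline, the rotation-removal step of alignment leaks a span-only
out-of-plane pattern out of the twist mode and into whatever mode
shares that shape (the spanwise bend), visibly distorting the
variance split. None of this changes what the modes *are*; it pins
down the degrees of freedom the source material leaves open so that
recovery is exact rather than approximate.

`calibrateModeAmplitudes()` solves amplitudes for target variance
shares in two stages: single-mode simulations (noise off) measure each
mode's injected tangent variance through the real alignment pipeline
and pin the amplitude scale (the noise floor at the configured
`noiseSd` fixes the absolute scale when the targets sum to less than
one; when they sum to one the scale is indeterminate and is chosen
small enough that the tangent linearization holds), then a joint-run
refinement matches the realized SVD variance proportions, assigning
components to modes by the correlation of score time courses with the
known injected signals. The refinement matters because the alignment
is mildly nonlinear: size normalization of a finite twist generates a
second-harmonic in-plane term that merges coherently with the
redistribution component — an "induced deformation" of exactly the
kind real wings exhibit, where twisting correlates broadly with other
deformation channels.

## What the synthetic tests do and do not show

Passing parameter recovery on the generator demonstrates that the
pipeline is internally correct: rigid motion is fully absorbed
(maximum Procrustes distance < 1e-9 on rigid-only input), injected
twist is recovered to under a degree against the injected
sectional-angle function evaluated at the measured stations, injected
variance shares are recovered within a percentage point, frequency
pairs land on the correct periodogram bins, and the statistical
procedures hold their nominal levels. It does not demonstrate
performance on real wings, whose deformation modes are not exactly
rank-one, whose markers are unevenly placed and individually noisy
(the real tracking-error process is heteroscedastic, not isotropic),
and whose surfaces have high-curvature features (secondary-feather
folds) that a smoothness-regularized fit will undersmooth. The
generator also contains no aerodynamic or inertial coupling between
modes.

## Problem sizes and defaults

The validation runs use 60 landmarks, 10 stroke cycles at 550 Hz
(≈1340 frames) for variance recovery, 20 replicates per subset size
for sampling curves, 200 seeds × 1000 frames for cross-correlation
calibration, and 25 simulated null datasets for the difference-smooth
level check — sizes at which every stage's Monte-Carlo error is well
below the tolerances being tested. Key defaults: GPA tolerance 1e-9
(max 200 iterations); thin-plate ridge 1e-4; mesh fill spacing 0.5 mm;
40 chord sections; 20 cyclic basis functions with GCV smoothing; 0.02
phase-lag grid; AR(1) candidate grid 0 to 0.95 in steps of 0.05.

## Known limitations

Frames must be complete (no missing-landmark imputation); the
perimeter polygon requires x-monotone ordered edge landmark lists; the
unscaled reconstruction path is linear (exact inversion is only
defined for unit pre-shapes); and the difference-smooth intervals are
pointwise, so the flagged-interval family-wise error rate is not
controlled.
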