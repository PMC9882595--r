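---
title: "Methods: from directional catch bonds to cellular co-alignment"
author: "catchlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from directional catch bonds to cellular co-alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchlink)
```

`catchlink` implements the chain of analyses linking a directional
molecular catch bond — the vinculin tail (Vt) gripping F-actin more
strongly under pointed-end load — to its cell-scale consequences. This
vignette documents the models, the conventions adopted where more than one
was defensible, the synthetic-data generators that stand in for molecular
dynamics trajectories and microscopy, and the limits of what the test
suite demonstrates.

## Hydrogen-bond occupancy and DAFS classification

A hydrogen bond between donor D (with hydrogen H) and acceptor A is
*present* in a frame when the D–A distance is strictly below 3.5 Å and the
acceptor–donor–hydrogen angle (measured at the donor, between the D→A and
D→H vectors) is at most 30°. The distance cutoff is strict and the angle
cutoff inclusive; a pair at exactly 3.5 Å is not a bond. *Occupancy* is
100 × the fraction of frames in which the bond is present. Runs are
replicated; the per-force occupancy is the arithmetic mean over replicate
runs, which keeps per-replicate values available for confidence intervals
(pooling frames across replicates would discard them — both conventions
give identical values for equal-length runs).

Lifetime classes use fixed occupancy thresholds: long-lived ≥ 40 %, medium
20–40 %, short < 20 %. The 40 % boundary belongs to "long" and the 20 %
boundary to "medium" (the interval is half-open, `[20, 40)`).

Force response is judged on the per-force profile over an *analysis
window*, by default 123–132 pN — the force range over which the Vt:F-actin
complex dissociates, so occupancy trends there are the informative ones.
Labels are assigned in a fixed priority order:

1. **absent** — occupancy identically zero;
2. **induced** — baseline (0 pN) occupancy below `epsBaseline` (default
   5 %) but exceeding it somewhere in the window;
3. **lost** — present at baseline, zero at some force and zero thereafter;
4. **strengthened** — mean occupancy over the upper half of the window
   exceeds the lower half by more than `deltaTrend` (default 10 %,
   relative);
5. **weakened** — everything else.

A bond is a **DAFS** interaction when it is induced or strengthened *and*
long-lived at its window peak under pointed-end pulling (F_P), while never
reaching long-lived occupancy at any force under barbed-end (F_B) or
normal (F_N) pulling. Directions without observations count as absent.
`epsBaseline`, `deltaTrend` and the window are explicit arguments; the
defaults are the package's declared convention, since prose descriptions
of "strengthened with force" do not pin down a numeric rule.

The synthetic generator draws each bond's occupancy-versus-force curve
from a piecewise-linear family — baseline below the response window, a
linear slope inside it, a plateau above, and a hard rupture force beyond
which occupancy is zero — clamped to [0, 100]. This is the simplest family
that realises every label above. Sampling noise, when requested, is
binomial at the stated number of frames per run. `exampleHbondScenario()`
composes a roster matching the observed directional census (34 bonds under
F_P: 5 long-lived/3 medium/26 short; 20 under F_B with none long-lived; 21
short-lived under F_N), with the five long-lived F_P bonds weak or absent
elsewhere — the planted DAFS set.

## Umbrella sampling and WHAM

Constant-force pulling is bookkept exactly: a discretized step potential
with energy jump `dE` per distance `dR` exerts `f = dE/dR`, converted at
1 kcal/mol/Å = 69.48 pN, so the canonical `dE ≈ 0.015` kcal/mol over 1 Å
is a 1 pN quantum; the full sweep (0–150 pN at 1 pN, three directions, ten
replicates) enumerates 4530 conditions.

`simulateUmbrellaWindows()` draws window samples by inverse-CDF sampling
of the biased density `∝ exp(−[U(ξ) + k/2 (ξ−ξ₀)²]/kT)` tabulated on a
fine grid (4096 points). This is exact and seedable — no Markov chain, no
burn-in or autocorrelation ambiguity — which makes the estimator, not the
sampler, the thing under test.

`whamSolve()` iterates the standard two self-consistency equations
(unbiased bin probabilities and per-window free-energy shifts) with a
Jacobi simultaneous update, converging when no shift moves by more than
`tol` (default 1e-7 kT; cap 1e5 iterations, exceeded → error carrying the
residual). Defaults: 100 histogram bins over the sampled range; bins never
visited are flagged unreliable and carry `NA`. With a single unbiased
window the equations collapse to the plain histogram estimator — asserted
bin-for-bin in the tests. Non-overlapping adjacent windows trigger a
warning naming the gap.

ΔG is read off the PMF as *mean over the unbound plateau minus minimum
over the bound region*; the regions are explicit arguments defaulting to
the last 10 % of the reliable grid and the whole grid respectively. The
reference double-well used throughout the tests has a known depth, and the
truth value is the same functional applied to the exact potential — the
estimator is validated at n = 10³ and 10⁴ samples/window (accuracy must
improve with n). The published Vt:F-actin values (ΔG of 54.73, 33.09 and
25.02 kcal/mol for F_P, F_B, F_N from 26 windows over 1–20 Å of
centre-of-mass separation) depend on all-atom sampling of the real
complex; only the estimator, not those numbers, can be validated at desk
scale.

## Sensitized-emission FRET

The forward imaging model for each channel is
`raw = shading × (background + signal) + dark`: dark current is additive
after the optics, so the correction order *subtract dark → divide by
mean-normalised shading → subtract background* inverts it exactly.
Background is the median over a cell-free region. Channel misalignment in
a single-camera filter-wheel acquisition is shift-dominated, so
registration is translation-only: FFT cross-correlation with a parabolic
sub-pixel peak fit.

Bleed-through coefficients are ratios on corrected calibration
acquisitions — `d_bt = I_f/I_d` on donor-only cells binned by
donor-channel intensity, `a_bt = I_f/I_a` on acceptor-only cells binned by
acceptor intensity — with 16 equal-count quantile bins and the median as
the per-bin robust mean. Intensities outside the calibrated range use the
nearest bin; scalar coefficients are accepted wherever a binned table is.
The corrected FRET image `F_c = I_f − d_bt(I_d)·I_d − a_bt(I_a)·I_a`
retains negative pixels: clipping at zero would bias region means, so
clamping happens only in the final reported efficiency.

`G` converts corrected FRET signal into donor-equivalent photons and is
estimated from two donor–acceptor fusion constructs of different constant
efficiency as `G = −Δ(F_c/I_a)/Δ(I_d/I_a)` (medians over masked cell
pixels; identical constructs are a degenerate pair and an error).
Efficiency is `E = (F_c/G)/(I_d + F_c/G)`, the standard sensitized-emission
form consistent with that definition of `G`; pixels with non-positive
total donor signal are masked, and both raw and [0, 1]-clamped maps are
kept in the returned `EfficiencyImage`.

The scene generator inverts this model exactly, so the noiseless round
trip recovers planted efficiencies to machine precision and the noisy one
(Poisson shot noise plus zero-mean Gaussian read noise, the standard sCMOS
model — the actual camera's noise spectrum is not published, so this is a
stand-in, not a reproduction) to ±0.03.

## Focal-adhesion morphometrics

Adhesions are segmented by smoothing (σ = 1 px), thresholding within the
cell (default: the 0.995 intensity quantile), watershed splitting of the
intensity surface, and a minimum-area filter (10 px). These parameters are
package defaults, configurable; published descriptions of the "water
algorithm" defer the exact values to prior work.

Morphometrics are moment-based. `blobMoments()` returns *pure discrete*
binary-weighted central moments (`u00` = area; a 3-pixel horizontal line
has `u20 = 2`). `faEllipseMetrics()` normalises by `u00`, adds the
unit-pixel-square variance 1/12 to the diagonal — treating each pixel as a
unit square, so a w × h pixel rectangle recovers the continuous moments
w²/12 and h²/12 — and reports the equivalent ellipse: full axis lengths
`4·sqrt(λ)`, ratio `sqrt(λ₁/λ₂)`, orientation
`θ_FA = ½·atan2(2u11, u20−u02)` reduced to [0, π). A 9 × 3 rectangle
therefore yields an axis ratio of exactly 3 and θ_FA = 0. The two-branch
arctangent form sometimes printed for θ_FA is algebraically the same
angle; `atan2` covers both branches and the printed axis-length formulas
(which lack the `u00` normalisation and square root) are replaced by the
standard equivalent-ellipse expressions. Binary weighting is used because
the downstream metrics are geometric; intensity weighting is a
one-line change but alters no test conclusion. Blobs with λ₁ ≈ λ₂ have no
defined orientation and are flagged (`NA`), degenerate blobs (λ₂ = 0)
report an infinite ratio.

Orientations are axial (θ and θ + 180° are the same line). All summaries
double the angles, work on the circle, and halve the result. The axial
spread uses the angular deviation `sqrt(2(1 − R))/2` (R = mean resultant
length of doubled angles) rather than `sqrt(−2 ln R)/2`: the two agree for
concentrated data (10° and 170° give ≈ 10° either way) but only the former
is bounded, approaching ≈ 40.5° for uniformly distributed orientations, so
the uniform limit is a testable property.

The cytosol mask is the cell interior farther than a Euclidean dilation
radius (default 10 px) from any adhesion pixel, computed by distance
transform. "Dilating the adhesion mask by a factor of 10" is not well
defined for a multi-blob mask; a fixed dilation radius is, and is
configurable.

## Structure tensor and co-alignment

Gradients use Scharr derivative filters (central difference combined with
3–10–3 cross-smoothing) after Gaussian pre-smoothing (σ = 1 px); plain
central differences rotate the apparent gradient of oblique
high-frequency patterns by several degrees, and the Scharr kernel is the
standard fix. The tensor components are smoothed at σ = 4 px and
eigen-decomposed in closed form. The dominant eigenvector of a structure
tensor points along the *gradient*, perpendicular to a fibre; the
default convention therefore reports the smaller-eigenvalue eigenvector
angle, so synthetic fibres are recovered at their drawn angle. The
literal larger-eigenvector convention, 90° away, is available as
`convention = "gradient"` for compatibility. Pixels with `l1` below a
relative floor (1e-3 of the maximum) have no meaningful orientation and
are masked; a constant image yields an empty mask.

Stress-fibre masks threshold `l1` (quantile of valid pixels by default,
absolute and Otsu rules available). Voronoi regions of the adhesion
centroids are computed directly on the pixel grid — every cell-interior
pixel is assigned to its nearest centroid, ties deterministically to the
lowest label — so the regions partition the cell mask exactly and all
downstream quantities (areas, densities, orientation means) are pixel
sums. Per region, SF density is the percentage of region pixels in the
fibre mask; the region orientation is the axial mean of `θ_SF` over fibre
pixels only (the region is "a region of local SFs", not of all pixels);
and `θ_Rel` is the axial distance to the adhesion's `θ_FA`, wrapped to
[0°, 90°] — a plain absolute difference of angles is unbounded and
double-counts the axial symmetry. Regions without fibre pixels have
density 0, no orientation, and are flagged and excluded from the per-cell
`θ_Rel` mean.

The scene generator plants fibres region by region at
`θ_FA + offset`, as Gaussian-profile periodic stripes whose brightest
`areaFraction` of region pixels (selected by rank, immune to grid
alignment) form the ground-truth mask. It emulates oriented, locally
parallel fibre texture with known offsets; it does not emulate fibre
crossings, curvature, varying thickness, or out-of-focus light — so
passing round trips demonstrate correctness of the estimators under the
stated model, not segmentation robustness on real micrographs.

## Statistics

Data are screened for variance homogeneity before multiple comparisons;
equal-variance data go to one-way ANOVA with Tukey HSD, unequal-variance
data to Steel–Dwass. Published descriptions name the screen ("a test for
unequal variances") but not its criterion; the package declares a
Brown–Forsythe gate (ANOVA on absolute deviations from group medians,
α = 0.05), and both downstream routes are always callable directly.

Steel–Dwass–Critchlow–Fligner is implemented from its definition: for each
pair, a midrank Wilcoxon statistic on the pooled pair with tie-corrected
variance, referred to the studentized range
(`p = 1 − ptukey(√2·|t|, k, ∞)`). For small samples an exact mode replaces
the normal tail of each pairwise statistic with its exhaustive permutation
distribution, mapped through the same studentized-range reference. Tukey
HSD and ANOVA come from base R (`aov`, `TukeyHSD`); the pairwise p-values
are cross-checked in the tests against an independent studentized-range
evaluation. Compact-letter displays use the standard insert-and-absorb
algorithm, and the tests verify the letters are reconstructible from the
adjusted p matrix at α.

Null calibration (type-I error within binomial bounds of α = 0.05 at 2000
replicates) is asserted for the t test, the ANOVA omnibus, and the
Steel–Dwass familywise rate.

## Problem sizes, determinism, limitations

Every generator is a pure function of its parameters and seed; identical
calls give identical output, and the pipeline runner reproduces its CSVs
byte for byte. The shipped analyses use sizes chosen so the full suite
runs in well under a minute per module: 128²–256² px scenes, 10 umbrella
windows × 10⁴ samples, 2000-replicate null simulations. These sizes are
the package's validation conditions, not statements about real data.

Known limitations: the WHAM error model provides no autocorrelation-based
uncertainties (samples are independent by construction here; bootstrap
over samples is the recommended route for correlated input); bleed-through
is two-coefficient, with no higher-order spectral unmixing and no
intensity-dependent `G`; adhesion segmentation is not learned and is not
expected to match expert annotation of difficult micrographs; and the DAFS
decision rule, while faithful to the published taxonomy, has thresholds
(`epsBaseline`, `deltaTrend`, the analysis window) that real applications
should sensitivity-check.
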