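# catchlink

Vinculin reinforces its grip on the actin cytoskeleton when pulled — but
only when pulled the right way. Its tail domain (Vt) forms a *directional
catch bond* with F-actin: tension applied toward the filament's pointed end
strengthens the interaction, while tension toward the barbed end or normal
to the filament does not. At the molecular scale this asymmetry is carried
by a handful of hydrogen bonds that are weak or absent at rest and are
created or reinforced under pointed-end load (directionally asymmetric
force-strengthened, **DAFS**, interactions). At the cellular scale it shows
up as loaded vinculin in focal adhesions (FAs) and as coordinated alignment
between FAs and actin stress fibers (SFs).

`catchlink` is an R package for the quantitative analyses that connect
those two scales:

* **H-bond / DAFS analysis** — geometric hydrogen-bond detection in pulling
  trajectories (donor–acceptor distance < 3.5 Å, acceptor–donor–hydrogen
  angle ≤ 30°), per-force occupancy profiles, lifetime classes
  (long ≥ 40 %, medium 20–40 %, short < 20 % occupancy), force-response
  labels (induced / strengthened / weakened / lost), and DAFS calling
  across the three pulling directions F_P, F_B, F_N.
* **WHAM / PMF** — self-consistent weighted-histogram reconstruction of a
  1-D potential of mean force from umbrella-sampling windows, binding
  energy ΔG = PMF(unbound plateau) − PMF(bound minimum), and the
  constant-force pulling protocol bookkeeping (condition enumeration,
  force quantum f = dE/dR with 1 kcal/mol/Å = 69.48 pN).
* **Sensitized-emission FRET** — the three-channel efficiency pipeline for
  molecular tension/conformation sensors: dark/shading/background
  correction and registration, binned bleed-through coefficients
  d_bt = I_f/I_d and a_bt = I_f/I_a, corrected FRET
  F_c = I_f − d_bt·I_d − a_bt·I_a, the proportionality constant
  G = −Δ(F_c/I_a)/Δ(I_d/I_a) from two fusion constructs, and pixelwise
  efficiency E = (F_c/G)/(I_d + F_c/G).
* **FA morphometrics** — watershed ("water algorithm") segmentation and
  blob analysis: central moments u_ij, equivalent-ellipse axes
  (4·sqrt(λ/u00)), axis ratio, orientation θ_FA = ½·atan2(2u11, u20−u02),
  per-cell summaries, cytosol masks.
* **SF co-alignment** — per-pixel fiber orientation from the structure
  tensor, SF masks from the dominant eigenvalue l1, axial orientation
  statistics, Voronoi regions around FA centroids, local SF density, and
  the co-alignment statistic θ_Rel = axial |θ_SF − θ_FA| ∈ [0°, 90°].
* **Group statistics** — variance screen routing to ANOVA + Tukey HSD or
  Steel–Dwass all-pairs comparisons, with compact-letter displays.
* **Synthetic data** — seeded generators for every input (occupancy
  tables, coordinate frames, umbrella samples, FRET scenes, actin scenes)
  with known ground truth, so every stage is testable end to end without
  any external data.

## Worked example

Generate a noiseless directional occupancy dataset mirroring the observed
Vt:F-actin bond composition, profile it, and call DAFS bonds:

```r
library(catchlink)

sim     <- simulateHbondOccupancy(exampleHbondScenario(), noise = FALSE, seed = 1)
profile <- occupancyProfile(sim$occupancy)
dafs    <- callDafs(profile)
dafs$counts
#>   direction n_long n_medium n_short n_total
#> 1       F_B      0        2      18      20
#> 2       F_P      5        3      26      34
#> 3       F_N      0        0      21      21
subset(dafs$calls, is_dafs)[1:4]
#>   bond_id is_dafs  response_FP lifetime_FP
#> 1     B01    TRUE strengthened        long
#> 2     B02    TRUE strengthened        long
#> 3     B03    TRUE strengthened        long
#> 4     B04    TRUE      induced        long
#> 5     B05    TRUE      induced        long
```

34 bonds are observed under pointed-end pulling (5 long-lived, 3 medium,
26 short-lived); exactly the five long-lived force-strengthened or
force-induced bonds are DAFS — strengthened only toward the pointed end.

The pulling protocol and a PMF from synthetic umbrella windows:

```r
enumeratePullingGrid()$count      # 0-150 pN x 1 pN x 3 directions x 10 reps
#> [1] 4530
forceQuantumPn(dE = 0.015, dR = 1)  # pN per 0.015 kcal/mol step over 1 A
#> [1] 1.0422

w   <- simulateUmbrellaWindows(doubleWellPotential(3),
                               centers = seq(1, 14, length.out = 10),
                               springConstant = 3, nSamples = 1e4, seed = 1)
pmf <- whamSolve(w)
pmf
#> PmfProfile: 100 bins over xi = [-1.04, 16] Angstrom
#>   unit: kT | range: 4.534 | reliable bins: 100/100
#>   WHAM: 820 iterations, residual 9.94e-08 (converged)
round(deltaG(pmf)$deltaG, 2)      # well depth 3 kT planted
#> [1] 3.1
```

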