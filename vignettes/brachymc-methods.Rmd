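---
title: "Monte Carlo dose verification for an Ir-192 HDR source: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dose verification for an Ir-192 HDR source: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`brachymc` re-implements, as a reusable pipeline, the dose-verification
workflow used to commission model-based dose calculation algorithms for
high-dose-rate (HDR) brachytherapy: a Monte Carlo model of a GammaMed Plus
style encapsulated ¹⁹²Ir source, photon transport under the kerma
approximation through voxelized heterogeneous slab phantoms and spherical
water geometry, extraction of the TG-43 U1 dosimetry parameters for
validation, and comparison of dose profiles by geometry-factor-normalised
point differences and a 1-D gamma analysis with local normalisation. This
vignette records the models, the assumptions behind them, the tunable
parameters, and the design choices that were genuinely open.

## The source model

The source is a 3.5 mm long, 0.6 mm diameter cylinder of pure iridium
(22.42 g/cm³) in which ¹⁹²Ir is uniformly distributed. It is encapsulated
in AISI 316L stainless steel (8.03 g/cm³): a hollow cylinder of 0.9 mm
outer and 0.7 mm inner diameter whose distal end is a truncated cone, and a
2 mm stub of AISI 304 drive wire (5.6 g/cm³, 0.9 mm diameter) at the
proximal end. The local frame follows the TG-43 convention: z along the
source long axis, origin at the core centre.

Dimensions not fixed by the published drawing were chosen once and are
configurable: the conical tip is a frustum of height 0.5 mm tapering to a
0.4 mm diameter flat end, the internal cavity leaves a 0.1 mm axial
clearance (filled with air), and the proximal base cap is 0.4 mm of solid
316L. Dose points of interest lie at 2 mm or more off the tip axis, where
these details are second order.

Decay photons are sampled uniformly in the core, isotropically in
direction, and from a bundled discrete line spectrum (36 lines,
7.822 keV – 1.378 MeV, 2.32 photons per decay, intensity-weighted mean
energy 0.352 MeV) compiled from the evaluated ¹⁹²Ir decay radiation:
gamma lines of the β⁻ branch to ¹⁹²Pt and the electron-capture branch to
¹⁹²Os, plus the Pt/Os K and L X-rays. Minor-line intensities are
approximate in their last digit; the file header documents this. Beta
particles are not transported: under the kerma approximation and behind
0.1 mm of steel their contribution outside the capsule is negligible.

A *history* is one emitted primary photon drawn from the
intensity-normalised spectrum. Lines below the transport cut are dropped at
sampling time — they cannot escape the capsule — but still count toward the
history total, so per-history normalisation matches a full-spectrum
definition. The dose-rate constant, a ratio of two per-history quantities,
is independent of this convention.

## Interaction physics and the bundled coefficient tables

At ¹⁹²Ir energies (≤ 1.4 MeV) the relevant photon interactions are
incoherent (Compton) scattering and photoabsorption. The engine models:

* **Compton scattering** on free electrons at rest, sampled exactly from
  the Klein–Nishina differential cross-section (composition–rejection on
  the 1/ε and ε branches). Binding effects and Doppler broadening are
  ignored. The Compton electron energy E − E′ is deposited locally (kerma
  approximation; no electron transport).
* **Photoabsorption** as full local absorption of the photon energy: no
  fluorescence or characteristic X-ray production. This is consistent with
  the 10 keV cut — the K X-rays of the phantom materials lie below it —
  though it slightly hardens the response of the steel and iridium
  hardware, whose K X-rays (6–65 keV) are not re-emitted.
* **Coherent (Rayleigh) scattering is excluded.** It transfers no energy,
  and at these energies it mainly blurs the angular distribution at small
  angles; for kerma-mode comparisons it is second order. No optional flag
  is provided because no credible atomic form-factor dataset is available
  to the package, and an uncontrolled approximation would be worse than a
  documented omission.
* **Pair production is out of scope** (threshold 1.022 MeV is barely
  exceeded by the two weakest lines; the cross-section there is
  negligible).

The per-element mass attenuation and mass energy-absorption coefficients
(10 keV – 1.4 MeV, 100-point log grid plus K-edge straddle points for Mo
and Ir) are bundled as CSV fixtures generated once by a committed script:
the incoherent part from the Klein–Nishina closed forms (verified against
quadrature to 10⁻⁹), the photoabsorption part from Cromer–Liberman
cross-sections. Because the tables are built from *exactly* the interaction
model the engine samples, the track-length kerma estimator and analog
energy deposition agree in expectation — an invariant the test suite
checks — rather than agreeing only to the extent two independent data
sources happen to match. The cost is that the tabulated attenuation runs a
few percent below standard compilations at low energies where coherent
scattering matters; this cancels in the dose-rate-constant ratio and is
part of the stated physics model, not an error term.

Mixtures use the mass-weighted sum of elemental coefficients with log–log
interpolation in energy and no extrapolation. The channel split at an
interaction is p(Compton) = μ_incoh/μ with μ_incoh the analytic
Klein–Nishina coefficient, photoabsorption taking the remainder.

The material library reproduces the published fifteen-entry composition
table (tissues, implant materials, water, air, vacuum, and the three source
alloys). Three quirks of the published table are handled explicitly:

* the titanium row (Al 6 / Ti 9 / V 4 percent — an evident Ti-6Al-4V
  misprint summing to 19 percent) is corrected to Ti 90 percent, with
  `strict = TRUE` keeping the printed row renormalised for sensitivity
  checks;
* the bone row lists potassium at 20.99 percent with no comparable calcium
  entry (a likely transposition in the source document); it is implemented
  as printed and not silently "fixed";
* compositions are renormalised to unit fraction sum on load (the
  cartilage and stainless-steel rows sum to 99.7 and 99.0 percent as
  printed).

Vacuum is a true void: the transport engine gives it an infinite mean free
path, and asking for a coefficient for it is an error rather than a zero.

## Transport and scoring

Two geometry engines share the same physics and RNG:

* **Analytic source-in-sphere engine** (`sphere_kerma()`): the capsule
  hardware is tracked on its exact surfaces (three cylinders, seven planes,
  one cone, bounding sphere); flight distances are sampled from the exact
  chord-wise optical depth across the region partition. Collisional kerma
  is scored with the track-length estimator (TLE) on (r, θ) shell sectors
  centred on the source: each flight segment credits
  E·(μ_en/ρ)·chord/V to every sector it crosses. Shell scoring matches the
  spherical symmetry of the TG-43 quantities and avoids the
  gradient-over-voxel bias of cartesian grids near a point-like source.
  TG-43 runs use a 40 cm radius water sphere, large enough that missing
  backscatter does not perturb doses at the tabulated radii.
* **Voxel engine** (`run_simulation()`): Amanatides–Woo traversal of the
  1 mm phantom grid with chord-wise optical depth. Default scoring for
  phantom comparisons is *analog* — the transferred energy is deposited at
  the interaction site, giving dose to medium under the kerma
  approximation — with TLE available; TG-43 runs default to TLE on shells.
  Woodcock (delta) tracking is available as an analog-mode flag and is
  cross-validated against ray tracing in the tests.

Photons falling below the 10 keV cut are terminated with local deposition
(their residual range in tissue is under a millimetre). TLE scores are
collisional kerma recorded as dose to medium; this is exactly the
charged-particle-equilibrium caveat of the underlying method — it is
documented, not corrected, and the comparison stage excludes the
near-source region where CPE fails.

The source hardware is carved into the phantom grid by sub-voxel
supersampling (10³ points per candidate voxel): a voxel becomes hardware
when at least half of it is occupied, taking the dominant hardware region.
A plain per-region majority would delete the 0.9 mm source from a 1 mm
grid, because the surrounding medium always wins a plurality. For TG-43
runs the hardware is instead tracked analytically, since 1 mm voxels
cannot resolve 0.9 mm hardware.

The RNG is MT19937 with an explicit uniform mapping; the contract is
bit-exact replay under a fixed (seed, configuration, phantom), which the
suite asserts for both engines.

**Statistical uncertainty** is accumulated history by history (first and
second moments of per-history scores per bin or voxel), giving the k = 1
standard error of the mean — unbiased in the presence of within-history
correlation, unlike fixed-batch estimates. Zero-score bins are flagged
rather than reported as zero uncertainty.

**Air-kerma strength** is scored in vacuo (capsule still attenuating) on a
thin transverse shell at 100 cm over a ±3° band, multiplied by the
effective squared distance; in vacuo the product is distance independent,
which the tests check at 50 vs 100 cm.

## TG-43 U1 extraction

The geometry factor uses the line-source form G_L = β/(L·r·sinθ) with β
computed as a difference of `atan2` angles, and the closed form
1/(r² − L²/4) on the axis; the two agree to 10⁻⁸ across θ → 0, and both
are verified against direct numerical integration over the active line.
The dose-rate constant is Λ = D(r₀, θ₀)/S_K, numerically in cGy h⁻¹ U⁻¹
when dose is Gy/history and S_K is Gy·cm²/history. The radial dose
function and anisotropy function follow their standard ratio definitions
and are exactly 1 at the reference point by construction — enforced, not
merely approximated, so downstream interpolation cannot drift the
normalisation. Forward evaluation interpolates g_L linearly in r and F
bilinearly in (r, θ), erroring outside the tables unless nearest-edge
clamping is requested. The radial and angular grids are the caller's
choice; nothing in the published workflow fixes them, so the examples use
modest grids (r from 0.5 to 5 cm; θ in 10–30° steps) chosen for
statistical economy.

## The comparison stage

Profiles are extracted along the slab-stacking axis through the source
centre, positions relative to the source; points with |y| ≤ 0.2 cm are
inside or very near the source, carry no clinical meaning, and are flagged
and excluded from pass rates. Doses are presented with geometry factors
extracted (D·G₀/G) so the line-source falloff does not dominate the
comparison, and per-history doses can be calibrated to clinical dose via
the f = 1.15 × 10¹² hist/s factor (0.21 % expanded uncertainty, k = 2).

The 1-D gamma index at each reference point is the minimum over candidate
positions x within the search limit of

γ(x_ref) = min √[ (x − x_ref)²/Δd² + (D_eval(x) − D_ref)²/(c·D_norm)² ]

with D_eval the piecewise-linear interpolant of the evaluated profile,
c the dose criterion, and D_norm the per-point reference dose (local
normalisation, the study's convention) or the profile maximum (global,
provided for completeness). Two details deserve a note:

* **The minimum is computed exactly**, not on a candidate grid: on each
  linear segment of the evaluated profile the squared objective is a
  quadratic in x, minimised in closed form and clamped to the segment.
  A 0.05 mm candidate grid (common practice) agrees with the exact minimum
  only to about 10⁻⁴ in γ; the exact form makes the result well defined
  and lets the test suite demand 10⁻⁶ agreement with an independent
  brute-force-plus-optimiser oracle.
* **The search limit defaults to cap·Δd** (2 mm for 2 %/1 mm with cap 2),
  reproducing the bounded-search behaviour by which the reference
  implementation capped the maximum obtainable gamma at 2: a flat
  evaluated profile at twice a flat reference yields γ = 2 at every point
  and a 0 % pass rate.

Reference-side statistical uncertainty is *not* folded into γ; it is
reported alongside, as in the original analysis. Pass rates are computed
over non-excluded points with pass ⇔ γ ≤ 1, rounded half away from zero to
two decimals, and flagged against the ≥ 99 % criterion.

## The synthetic-data generator

`generate_profile_pair()` produces a 1 mm-sampled reference profile from a
declared positive shape and an evaluated profile that is a known
perturbation — shift (mm), scale, multiplicative Gaussian noise — with the
ground truth recorded. It emulates the *structure* of a profile comparison
(two dose profiles on a common grid with spatial and dosimetric
discrepancy) and deliberately not the physics: real treatment-planning
discrepancies are spatially correlated, heteroscedastic, and concentrated
at interfaces and low-density regions, none of which a shift/scale/noise
model reproduces. Passing gamma-module tests on synthetic pairs therefore
demonstrates the correctness of the metric, not the dosimetric accuracy of
any algorithm. `generate_tg43_grid()` evaluates the TG-43 forward model on
a cartesian grid in the same container a Monte Carlo run produces,
standing in for an externally supplied (e.g. planning-system) grid in
end-to-end tests; real planning-system grids can be compared by building a
`dose_grid` from any array with spacing and origin metadata.

Slab phantoms are built deterministically (no RNG): half-open 1 mm voxel
boundaries make the 101/11 mm slabs map to whole voxel counts exactly, an
identity the tests assert for all six configurations.

## Numerical choices and degenerate inputs

* Energy interpolation is log–log with hard range errors (no
  extrapolation); sampled line energies never leave the tabulated range.
* Ray–surface intersections use midpoint classification between sorted
  crossing parameters, which is robust to tangential and repeated roots;
  voxel chords partition in-grid segments to 10⁻⁹ cm (asserted against an
  independent slab-method box intersection).
* Zero-dose voxels report `NA` uncertainty; analog deposition into a void
  voxel is banked to a separate tally and warned about, preserving the
  energy balance (emitted = deposited + escaped + void-banked to 10⁻⁹
  relative, a test invariant).
* Profile comparisons require exactly matching position grids; silently
  resampling a reference profile would blur exactly the spatial
  discrepancies the gamma index is meant to measure.
* The point-source limit of the geometry factor (L → 0) and points on the
  active segment (domain error) are handled explicitly.

## Problem sizes

The package's validation runs are chosen for desk-scale statistical
economy: the dose-rate-constant recomputation uses 10⁷ histories for the
water-sphere dose at 1 cm (≈ 0.15 % k = 1) and 10⁶ for the in-vacuo
air-kerma strength (≈ 0.5 % k = 1), giving Λ with well under 1 %
statistical uncertainty; unit tests use 10⁴–10⁶ histories per property.
The original workflow's 2.1 × 10⁹-history runs would shrink only the
statistical term; all systematic terms (physics model, geometry) are
unchanged, and uncertainties are reported with every result so the
precision claim is always the computed one.

## Known limitations

* Collisional kerma is reported as dose to medium; within ± 0.6 cm of the
  source CPE fails and the numbers there are kerma, not dose. The
  comparison stage excludes this region.
* No coherent scattering, fluorescence, electron transport, or pair
  production; no bound-Compton corrections. These are the kerma-mode
  approximations of the reference workflow, plus the documented coherent
  omission.
* The iridium K-edge (76.1 keV) is represented by straddle points on a
  smooth photoabsorption fit; sub-percent structure within a few keV of
  the edge is smoothed.
* The voxel engine's carved hardware is a 1 mm-resolution caricature of a
  0.9 mm source; phantom-mode doses within the source slab's central row
  should not be over-interpreted (they are excluded from comparisons
  anyway).
* Only photon sources between 10 keV and 1.4 MeV are supported; the
  coefficient tables end there by design.
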