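---
title: "Energy-window scatter correction for list-mode PET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-window scatter correction for list-mode PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Compton scattering in the patient (or phantom) deflects annihilation photons,
so a fraction of recorded coincidences carry lines of response (LORs) that do
not pass through the annihilation point. Left uncorrected, this scatter
component fills cold structures, depresses contrast and biases quantification.
Model-based corrections (single scatter simulation) need an attenuation map
and an activity estimate, and they miss multiple scatter and activity outside
the field of view (FOV). When detectors resolve energy well (~10% FWHM at
511 keV), the recorded energies themselves separate scattered from
unscattered photons statistically: scattered photons have lost energy, so
they populate the region below the photopeak.

`petscatter` implements the energy-window family of corrections for
list-mode data, end to end:

1. **Calibration** — on ground-truth-labeled simulated data, fit the
   coefficients `k_w` that scale auxiliary-window counts into an estimate of
   the scattered counts inside the photopeak window.
2. **Window counting and smoothing** — classify each coincidence into energy
   windows, bin it into a LOR bin (a virtual-pixel pair on a faced block
   pair), and smooth the per-window counts over LOR space with a truncated
   4-D Gaussian kernel.
3. **Scatter fraction per LOR** — `SF_i = (C_LEW,i + C_ph,scatter,i) /
   C_Total,i`, the probability that an event on LOR bin `i` is scatter.
4. **Reconstruction** — list-mode MLEM/OSEM with the scatter estimate as an
   additive term `S_i` inside the forward model:
   `n_j^(k+1) = n_j^k / sum_I a_ij * sum_M a_ij / (sum_j a_ij n_j^k + S_i)`.

Because real labeled data do not exist, the package also ships a desk-scale
Monte Carlo coincidence simulator that plays the role a general-purpose
particle-transport code (GATE) plays in practice for this method: it produces
list-mode files with per-photon phantom-scatter labels for water-cylinder,
out-of-FOV and two-rod contrast phantoms.

## The simulator: what it models and what it does not

Decays are sampled from cylindrical activity components (activities set the
mixture weights; cold regions are carved by rejection). Each decay emits an
exactly back-to-back photon pair with isotropic direction — positron range
and photon acollinearity are neglected, both below the 1.4–2 mm virtual
pixel scale of this scanner class. Photons are tracked through axis-aligned
cylinder phantoms by delta (Woodcock) tracking with the water total
attenuation as majorant, which samples free paths from
`exp(-mu_total(E) * l)` exactly, handles overlapping cylinders by point
lookup, and treats air as vacuum (its attenuation is three orders of
magnitude below water's here). At an interaction the photon Compton-scatters
with probability `mu_C/mu_total` — the angle drawn by rejection from the
Klein–Nishina differential cross-section, the energy from the Compton
formula — or is photoelectrically absorbed. `mu_C(E)` is the water electron
density (3.3428e20 mm^-3) times the analytic total Klein–Nishina cross
section; the photoelectric part uses an `E^-3` fit anchored on tabulated
water attenuation (276/E^3 mm^-1 with E in keV), negligible above 350 keV.
Tracking stops below 50 keV, far under the 350 keV acceptance cut, so the
cutoff cannot affect any output.

Detection is geometric: a photon is detected where its ray crosses the inner
face of one of the 20 blocks (50 × 50 × 20 mm, inner faces at a configurable
165 mm from the axis — a regular 20-gon of 50 mm faces would close at
157.8 mm, which contradicts the nominal 330 mm transaxial FOV, so the stated
FOV wins and small inter-block gaps are implied). The crystal absorbs the
full arrival energy at the face crossing; the deposited energy is then
blurred with a Gaussian of FWHM `0.10 * 511 * sqrt(E/511)` keV (Poisson
photostatistics scaling of the 10% resolution at 511 keV). A coincidence is
accepted when both photons land on blocks at circular separation of at least
5 and both blurred energies fall in 350–650 keV. Depth of interaction is
recorded as a chord-midpoint surrogate and carried in the data model, but
default binning ignores it.

**The main fidelity gap is deliberate and matters for interpretation.** Real
monolithic LYSO blocks often absorb only part of a photon's energy (Compton
interaction in the crystal with escape), so in a full detector simulation a
substantial share of *unscattered* photons is recorded well below the
photopeak — that is why measured low-window populations contain on the order
of 15% true events. This package's detector deposits the full energy, so its
low window is essentially pure scatter (measured 99.97% scattered on the
160 mm cylinder) and its upper window purer in a different direction.
Consequences, all observed in the validation runs: the per-window purity
table is shifted relative to a full detector simulation; the dual-window
estimator loses the systematic overestimation bias that the true-event
contamination of the low window otherwise gives it; and truth scatter
fractions differ by a few hundredths in-FOV (slightly high) and more
substantially for activity outside the axial FOV (low), where the omitted
energy-dependent detection efficiency of oblique, lower-energy photons
weighs most. The window coefficients are therefore *re-calibrated for this
physics* rather than imported, which is exactly what the method prescribes —
the estimator's internal consistency (TEW tracking its own truth to better
than 0.02 mean absolute deviation across the seven radii) is the property
the tests pin down quantitatively; agreement with the reference purity
percentages is not attainable under this detector model and is reported as
found.

## Energy windows and calibration

Windows are contiguous and half-open at interior boundaries: low (LEW)
350–430 keV, photopeak 430–650 keV (dual-window mode, DEW) or 430–550 keV
with an upper window (UEW) 550–650 keV (triple-window mode, TEW). A
photopeak event requires both photons in the photopeak; an auxiliary-window
event requires one photon in that window. When the two photons fall into
different auxiliary windows the event is assigned to the *low* window: a
photon that lost at least 81 keV has certainly scattered, so the event is
maximally scatter-like; the full 9-combination truth table is exercised in
the tests.

`k_w` is the scattered-photopeak over auxiliary-window count quotient. For
DEW the pooled global quotient is exact and self-consistent: applying it to
its own calibration set returns the true unscattered photopeak total to
machine precision (a test). For TEW the two literal quotients would each
absorb the whole scattered photopeak, double-counting it in the two-window
sum, so `(k_LEW, k_HEW)` are fit jointly by non-negative least squares of
the truth-scattered photopeak counts on the (LEW, UEW) counts across the
calibration ensemble — by default the seven cylinder radii (40–160 mm),
mirroring the practice of deriving factors from several attenuation media.
With a single calibration set the regression runs across block-pair
aggregates; per-LOR-bin counts at desk-scale occupancy are 0 or 1 and carry
no slope. Per-bin coefficient maps are supported, with a 50-event floor
below which a bin falls back to the global value.

## KDE smoothing over LOR space

A LOR bin is addressed by the 4-vector `x = (u_a, v_a, u_b, v_b)` of
face-local coordinates on its (canonically ordered) block pair. Window
counts are smoothed by a Gaussian kernel `exp(-1/2 dx' H^-1 dx)` with the
diagonal Silverman rule-of-thumb bandwidth `H_ii = (2/(3n))^(1/4) sigma_i^2`
(the d = 4 plug-in rule; `sigma_i` per window, with a pooled fallback below
100 events), truncated at the 95% kernel volume contour
(`Mahalanobis^2 <= qchisq(0.95, 4) = 9.488`). Dimensional consistency forces
the *inverse* bandwidth matrix in the exponent — `H_ii` has units of mm², a
bandwidth, so the quadratic form must be `dx' H^-1 dx`; this is a correction
of notation, not of method. Two further choices the estimator's definition
leaves open: the kernel never crosses block-pair boundaries (LORs on
different pairs traverse different image regions, so the 4-coordinate
distance is only meaningful within a faced pair), and the normalization
constant is discrete — each event's truncated, in-bounds neighborhood is
renormalized to unit mass, so per-window totals are conserved exactly
(to 1e-6 relative, tested; the truncated fast path is also tested against a
dense brute-force convolution at 1e-9).

Smoothed values are evaluated at the *occupied* bins (those holding at least
one event) — precisely the bins the reconstruction needs. The global scatter
fraction is not aggregated over that subset, which would under-represent
spatially diffuse windows; by mass conservation the count-weighted aggregate
of the per-bin fractions over the full lattice telescopes to
`(N_LEW + sum_w k_w N_w) / N_Total` in the per-window totals, and that exact
form is used (`global_sf_from_totals()`). Per-bin scatter estimates are
clamped to `[0, C_ph(b)]`; the clamp rate is logged and rises with the
scatter fraction (~20% of occupied bins at the 160 mm cylinder) because
scatter-dominated border bins legitimately saturate — a much higher rate
signals mis-calibration.

## Reconstruction and the additive term

The projector computes exact ray–voxel intersection lengths (incremental
Siddon traversal, tested against analytic chords at 1e-9); the sensitivity
image sums `a_ij` over every virtual-pixel pair of every allowed block pair
and is cached per (geometry, grid, volume). OSEM partitions block pairs
round-robin (angular interleaving); one subset reproduces MLEM bit for bit,
and the list-mode Poisson log-likelihood is asserted non-decreasing at every
MLEM iteration. Events enter at their LOR-bin center lines; the epsilon
floor in the EM denominator is 1e-12; the initial image is uniform 1.

The additive term is `S(b) = SF(b) * C_raw(b)`: the expected scatter counts
of bin `b`, with the *raw* bin count setting the magnitude (smoothing
estimates the ratio; using smoothed counts for the magnitude would
double-count kernel mass). At the bin-level LOR discretization the EM fixed
point then satisfies `forward + S = measured counts` per bin, verified by a
two-voxel fixed-point oracle that recovers a known activity to 1%.

One scaling consequence deserves emphasis, because it drove the default
settings of the contrast-phantom study (`run_utah()`). `S` is an expected
count *per LOR bin*. If the binning is so fine that nearly every measured
bin holds a single event, `S ~ SF` acts as a uniform floor of ~0.3 counts
against a signal of 1, and the maximum-likelihood image suppresses all
spatially diffuse activity — the corrected image collapses even when the
scatter-fraction map is regionally accurate (we verified this with
truth-label maps). The clinical count regime (tens of millions of events at
millimetre pixels) keeps bin multiplicities high; at the package's
desk-scale budgets (~1e5 events) the equivalent-statistics choice is a
coarser LOR binning. `run_utah()` therefore defaults to 10 mm virtual
pixels and 4 mm voxels, where bin multiplicities are comparable to the
full-statistics regime's and the correction behaves as expected: the cold-rod
residual decreases and the hot-rod contrast recovery increases when the TEW
term is enabled. The reconstruction functions themselves accept any pitch;
with full acquisition statistics the pipeline runs unchanged at 1.4–2 mm.

## Validation studies and problem sizes

The packaged studies (and the scales chosen for them):

- **Cylinder series** (`run_cylinder_series()`): seven water cylinders,
  40–160 mm radius, 60 mm tall, 5 mm × 60 mm central line source; ~3e4
  accepted coincidences per radius for testing, 5e4–2e5 in the acceptance
  script. Truth scatter fraction rises monotonically from ~0.17 to ~0.58;
  the ensemble-calibrated TEW estimate tracks truth with mean absolute
  deviation below 0.02.
- **Out-of-FOV** (`run_out_of_fov()`): 25 mm × 160 mm uniform cylindrical
  source in a 120 mm × 160 mm water cylinder on the 60 mm axial FOV; about
  27% of scattered coincidences originate outside the FOV. Coefficients are
  applied from the cylinder ensemble *without refitting* — the premise that
  predefined factors generalize.
- **Utah phantom** (`run_utah()`): 100 mm background cylinder, one cold and
  one 10:1 hot 25 mm rod at ±35 mm; uncorrected vs TEW-corrected OSEM
  (4 iterations × 3 subsets), rod ROI metrics and central profiles.

The line source is read as a 5 mm diameter, 60 mm long uniform cylinder (the
stated "5 × 60" does not disambiguate), and the axial FOV as 60 mm where the
source descriptions conflict. Timestamps are carried but unused (no randoms
model). Everything is reproducible from a configuration and a seed; all
randomness flows through R's RNG.

## Known limitations

- No detector-internal energy deposition, Rayleigh scattering, LYSO
  intrinsic background, dead time, pile-up or randoms: window purities and
  out-of-FOV scatter fractions differ from full detector simulations in the
  directions discussed above.
- Air is vacuum; phantoms are axis-aligned cylinders of water/air only.
- Attenuation and normalization factors inside `a_ij` are not applied by
  default, so the scatter term's effect is isolated; a known-phantom
  attenuation option is a natural extension.
- The per-bin coefficient mode needs count densities well above the
  desk-scale defaults to beat its 50-event floor.
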