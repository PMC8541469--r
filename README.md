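# petscatter

Energy-window scatter estimation and correction for **list-mode PET**, with a
desk-scale Monte Carlo coincidence simulator, LOR-space kernel smoothing and
list-mode MLEM/OSEM reconstruction.

## The problem and who this is for

Compton scatter in the imaged object deflects annihilation photons, so a
substantial fraction of PET coincidences are recorded on lines of response
(LORs) that miss the annihilation point, filling cold structures and biasing
quantification. Model-based corrections need an attenuation map and miss
multiple scatter and activity outside the field of view. With modern
detectors (~10% energy resolution at 511 keV) the recorded *energies* carry
the information instead: scattered photons have lost energy and populate the
spectrum below the photopeak. This package is aimed at people developing or
studying PET reconstruction and corrections who want a complete, runnable,
testable implementation of the energy-window approach on list-mode data —
from labeled simulation through calibration to corrected images.

## The method

Events are classified by photon energies into a low window (LEW,
350–430 keV), a photopeak window, and optionally an upper window (UEW,
550–650 keV). Calibration on ground-truth-labeled simulations yields the
window coefficients

```
k_w = C_ph,scatter / C_w
```

which scale auxiliary-window counts into the scattered part of the photopeak:
`C_ph,scatter,i = k_LEW C_LEW,i` (dual window, DEW) or
`k_LEW C_LEW,i + k_HEW C_HEW,i` (triple window, TEW). Per-window LOR-bin
counts are smoothed with a truncated 4-D Gaussian kernel over the LOR
coordinates `(u_a, v_a, u_b, v_b)` using the Silverman rule-of-thumb
bandwidth `H_ii = (2/(3n))^(1/4) σ_i²`, cut at the 95% kernel volume
contour. Each bin's scatter fraction

```
SF_i = (C_LEW,i + C_ph,scatter,i) / C_Total,i
```

is turned into an additive term `S_i = SF_i · C_raw,i` inside the list-mode
EM forward model:

```
n_j^(k+1) = n_j^k / Σ_{i∈I} a_ij · Σ_{i∈M} a_ij / (Σ_j a_ij n_j^k + S_i)
```

with `a_ij` exact ray–voxel intersection lengths and the sensitivity summed
over all allowed virtual-pixel LORs. The bundled simulator (Klein–Nishina
Compton transport and photoelectric absorption in cylindrical water
phantoms, geometric detection on a 20-block ring, Gaussian energy blur,
350–650 keV acceptance) generates the labeled list-mode data the calibration
needs and the validation phantoms: seven water cylinders (40–160 mm radius)
with a central line source, a source/phantom taller than the 60 mm axial
FOV, and a two-rod contrast ("Utah") phantom.

## Worked example

Simulate three of the cylinder phantoms, calibrate both window
configurations on them, and compare the estimated global scatter fraction
with the ground truth:

```r
library(petscatter)
rep <- run_cylinder_series(radii = c(40, 100, 160), min_accepted = 2e4,
                           seed = 42)
print(rep)
#> <validation_report: cylinder_series>
#>  radius n_accepted  sf_truth    sf_dew    sf_tew clamp_rate_dew clamp_rate_tew
#>      40      21573 0.1733649 0.1419959 0.1829033      0.0546305     0.05832554
#>     100      22491 0.3881553 0.3597802 0.3537292      0.1333542     0.13523434
#>     160      22316 0.5780158 0.6372516 0.5762935      0.2131694     0.21051209
print(rep$coefficients$tew)
#> <scatter_coefficients> TEW windows, global mode: k_lew = 1.1067, k_uew = 1.0225
```

Reading the table: `sf_truth` is the labeled scatter fraction of the
accepted coincidences (17% of events in the 40 mm cylinder scattered, 58% in
the 160 mm one); `sf_tew` is what the triple-energy-window estimator
reconstructs from energies alone — within ~0.01–0.03 of truth here — and
`sf_dew` the simpler dual-window estimate. The coefficients say that each
low-window count signals about 1.1 scattered photopeak counts under this
detector model. The clamp rate is the share of LOR bins whose scatter
estimate saturated at the bin's photopeak content; it grows with the overall
scatter fraction.

Downstream, `run_utah(rep$coefficients, ...)` reconstructs the contrast
phantom with and without the TEW additive term and reports the cold-rod
residual and hot-rod contrast recovery; `run_out_of_fov(rep$coefficients,
...)` quantifies scatter from activity beyond the axial FOV. A thin CLI over
the same functions lives at `inst/cli/petscatter.R`
(`simulate | calibrate | estimate | reconstruct | evaluate | fixtures`).

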