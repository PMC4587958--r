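---
title: "Monte Carlo TG-43 dosimetry of an HDR cobalt-60 source: methods and design"
author: "cobrachy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo TG-43 dosimetry of an HDR cobalt-60 source: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-dose-rate (HDR) brachytherapy delivers dose from a miniature sealed
radioactive source placed in or near a tumour. Clinical treatment-planning
systems consume a standard parameterization of the dose distribution
around a specific source model, the AAPM TG-43U1 formalism:

$$\dot D(r,\theta) \;=\; S_K \,\Lambda\,
\frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),$$

with air kerma strength $S_K$ (1 U = 1 µGy·m²·h⁻¹), dose rate constant
$\Lambda$ (cGy·h⁻¹·U⁻¹), line-source geometry factor
$G_L = \beta/(L\,r\sin\theta)$, radial dose function $g_L(r)$ normalized
to 1 at $r_0 = 1$ cm, and anisotropy function $F(r,\theta)$ normalized to
1 at $\theta_0 = 90°$. These parameters are conventionally produced by
Monte Carlo photon transport around a faithful geometric model of the
source. `cobrachy` implements that pipeline for the BEBIG Co0.A86
HDR ⁶⁰Co source: an analog photon-transport engine over the
nested-cylinder source geometry, track-length collision-kerma scoring in
air and water phantoms, and the TG-43U1 parameter extraction.

## Source and phantom model

The source is modeled as nested, coaxial finite cylinders, with the
coordinate origin at the geometric centre of the active volume and the
transverse plane at $z = 0$:

* **active core** — metallic ⁶⁰Co, length 3.5 mm, diameter 0.5 mm;
  emissions are sampled uniformly over the core volume, isotropically in
  direction, with energy 1.17 or 1.33 MeV (equal line weights by
  default, configurable). Only the photon spectrum is transported; the
  beta electrons are fully stopped by the capsule.
* **encapsulation gap** — the stated capsule wall thickness (0.15 mm),
  external diameter (1 mm) and core diameter (0.5 mm) jointly imply a
  0.1 mm annular air gap between core surface and capsule inner wall; it
  is modeled explicitly as an air region. Its dosimetric effect is small
  but the manufacturer-stated wall thickness cannot otherwise be
  honoured.
* **capsule** — stainless steel (AISI 316L), wall 0.15 mm, with flat end
  caps of the same thickness. Flat caps (rather than rounded tips) keep
  the ray tracing fully analytic; the approximation only affects
  near-axis polar angles and is visible in $F(r,\theta)$ there.
* **drive cable** — a 5 mm steel cylinder of capsule diameter abutting
  the proximal (negative-$z$) capsule end. Only the total cable length is
  specified by the source documentation; a single full-density cylinder
  is the same convention used by the published studies this package
  compares against.
* **phantom** — a cube centred on the source: 250 cm of TG-43U1
  40%-humidity air for the $S_K$ stage, 100 cm of liquid water
  (0.998 g/cm³) for the dose stage. The 100 cm cube acts as effectively
  unbounded for transverse distances up to 20 cm, although full-scatter
  conditions degrade slowly beyond ~15 cm from the source.

Region lookup resolves boundary points to the inner region; a ray
starting exactly on a surface is advanced by $10^{-8}$ cm before tracing,
which removes zero-distance loops at shared boundaries.

## Physics model and its assumptions

* **Kerma approximation.** Dose is identified with collision kerma
  everywhere and secondary electrons are not transported. For an
  encapsulated ~1.25 MeV source this is the standard justification:
  source electrons are absorbed in the capsule, and charged-particle
  equilibrium holds in water except within roughly 1 cm of the capsule,
  where secondary-electron ranges (a few mm) invalidate the
  dose = collision-kerma identity. This is the package's main documented
  limitation: the reference point of $\Lambda$ sits exactly at the edge
  of that region, and dose-scoring Monte Carlo studies report $\Lambda$
  values 1–2% above a collision-kerma calculation (see "Validation"
  below).
* **Interactions.** Photoelectric absorption, incoherent (Compton)
  scattering, coherent (Rayleigh) scattering and pair production are
  sampled from per-material branch fractions. Compton kinematics use the
  free-electron Klein–Nishina differential cross section (rejection
  sampling under a constant envelope; the sampled $\cos\theta$
  distribution matches the numerically integrated CDF to KS < 0.01).
  Binding (incoherent scattering function) corrections are *not* applied
  to the angular sampling; the branch probability still comes from the
  incoherent cross section. Rayleigh events redirect by the Thomson
  angular law $\propto 1+\cos^2\theta$ without form factors — coherent
  scattering is under 1% of interactions above 100 keV in the low-Z
  media, and the bias is noted rather than corrected. Pair events above
  1.022 MeV absorb the pair's kinetic energy locally and emit two
  antiparallel 0.511 MeV annihilation photons with isotropic
  orientation.
* **Cutoff.** Photons falling below 10 keV (the table floor) terminate
  with local energy deposition. An electron cutoff is recorded in the
  configuration for provenance only; it is inert under the kerma
  approximation.
* **Tracking.** Analog region-by-region tracking: the free path is
  sampled against the current region's linear attenuation coefficient
  and compared with the analytic distance to the next boundary. With
  only six regions this is exact, fast, and easy to test against a
  brute-force marching oracle. The only variance-reduction device is the
  track-length estimator itself; there is no splitting or roulette.

## Interaction coefficient tables

The four media (water, humid air, steel 316L, metallic cobalt) ship as
plain-text tables over 0.010–1.35 MeV (`inst/extdata/xs/`), each row
giving total $\mu/\rho$, branch fractions of the four interaction kinds,
and $\mu_{en}/\rho$. Construction (documented in each file header and
reproducible from `data-raw/make_xs_tables.py`):

* totals and $\mu_{en}/\rho$ for water, dry air and iron are anchored to
  the standard NIST/XCOM compilation values at the conventional grid
  energies; 1.17, 1.25 and 1.33 MeV are grid nodes;
* the incoherent partial is the free-electron Klein–Nishina cross
  section times electrons per gram; coherent and pair partials are
  smooth Z-scaled parameterizations; the photoelectric partial is the
  residual (at high energies ~0.1% of the total);
* humid air mixes 0.65% water vapour by mass into the dry-air anchors
  (40% relative humidity at 22 °C, a <0.1% effect on the coefficients);
* steel and cobalt, which have no compound compilation anchor here, are
  built by elemental Z-scaling from the iron anchors.

The anchors are accurate where the physics is sensitive — the water and
air totals and $\mu_{en}/\rho$ between 0.05 and 1.35 MeV, whose
water-to-air ratio (≈1.111 at 1.25 MeV) drives $\Lambda$ directly. The
residual-photoelectric construction overstates low-energy photoelectric
absorption by tens of percent *of that small partial* below ~150 keV;
this slightly suppresses the multiply-scattered photon population and is
part of the model-fidelity budget discussed under "Validation".

Lookups interpolate log-log linearly (exact at nodes, with the closed
form that the value at the geometric mean of two node energies is the
geometric mean of the node values — used as a test oracle). Branch
fractions interpolate linearly in log energy and renormalize; the pair
fraction is forced to zero below threshold. The inverse-CDF ordering is
photoelectric, compton, rayleigh, pair.

## Scoring

Kerma is scored with the linear track-length estimator over full-azimuth
ring cells $(r_1, r_2) \times (z_1, z_2)$: each track segment adds
$w\,E\,(\mu_{en}/\rho)(E)\,\ell_{cell}/V_{cell}$, with $\ell_{cell}$ the
analytic chord length inside the cell, converted to Gy by
$1.602176634\times10^{-10}$ Gy per MeV/g. Internal units are MeV and cm
throughout; conversion happens only at this reporting boundary.

* the **air stage** scores a ring 2 cm thick and 1 cm high at 100 cm on
  the transverse axis of the 250 cm air cube;
  $S_K = K_{air}(100\,\mathrm{cm})\cdot d^2$ with $d = 1$ m;
* the **water stage** scores sixteen transverse-axis ring voxels 0.1 mm
  thick and 0.1 mm high at 0.25–20 cm, and optionally a polar
  $(r,\theta)$ grid of ring cells for $F(r,\theta)$. The 0.1 mm "voxel"
  is realized as a rotationally symmetric ring rather than a cube,
  exploiting the azimuthal symmetry of the source to cut variance; this
  is the standard choice for cylindrical sources, and it matters at the
  sub-percent level only for the nearest cells.

Chord extraction is analytic (quadratic cylinder intersections minus the
inner exclusion), and is verified against a bisection-refined numerical
oracle to $10^{-6}$ relative; the estimator is exactly additive over
sub-partitions of a cell, which is also asserted bit-consistently.

## Uncertainties, random numbers, reproducibility

Histories are split into $B \ge 2$ batches (default 50). Each batch runs
on an independent xoshiro256++ stream seeded by splitmix64 from
(root seed, batch counter), so a run is bit-identical for a given
(seed, histories, batches) and batches are statistically independent.
The reported type-A uncertainty of every cell is the standard error of
the batch means divided by the grand mean, at coverage $k = 1$. Type-B
(cross-section, geometry) uncertainties are out of scope, matching the
published analysis this package parallels. The $1/\sqrt{N}$ law is
verified empirically, and is used to extrapolate desk-scale uncertainties
to the published $10^9$–$10^{10}$ history budgets.

Derived quantities: $\Lambda$ combines the two stage uncertainties in
quadrature; $g_L$ propagates the two dose-cell errors in quadrature (the
shared $D(r_0)$ entry makes neighbouring $g_L$ values correlated — they
are reported as-is, not decorrelated).

The pipeline derives per-stage child seeds as $2s+1$ (air) and $2s+2$
(water) from the root seed $s$, so the stages are independent but fully
reproducible from one integer.

## Testing modes and what they demonstrate

Three configuration switches put the engine into closed-form regimes:

* `vacuum_mode` disables all interactions: kerma must be pure (line-)
  inverse square, so $K\cdot d^2$ is distance-invariant and a
  vacuum-mode study returns $g_L \equiv 1$;
* `primary_only` terminates photons at their first collision: scored
  kerma must equal $E\,(\mu_{en}/\rho)\,e^{-\mu d}/(4\pi d^2)$;
* `point_source` ignores the capsule geometry and emits from the origin,
  isolating transport and scoring from the source model.

These modes power the property-based test suite. Passing them shows the
transport, scoring and geometry are mutually consistent and unbiased
against closed forms; it does not, by itself, validate the interaction
data or the kerma approximation against real measurements — that is what
the reference comparison (below) probes.

## Problem sizes

Desk-scale defaults are $10^6$ histories per stage for exploratory runs
and $10^7$ per stage for the reproduction script (about one minute per
stage on one CPU with the compiled engine); the published study used
$10^9$ (air) and $10^{10}$ (water). Uncertainties are always reported, so
under-budgeted runs are self-describing, and the $1/\sqrt{N}$
extrapolation connects desk-scale precision to the published budget: a
$10^7$-history water run gives ≈0.45% at the 1 cm voxel, hence ≈0.014%
at $10^{10}$, comfortably within the published "<0.5%".

## Validation and known limitations

With $10^7$ histories per stage the package obtains
$\Lambda = 1.087 \pm 0.006$ cGy·h⁻¹·U⁻¹. The published comparison values
are 1.108 ± 0.001 (a dose-scored EGSnrc study of this source),
1.1087 ± 0.0011 (Granero et al., GEANT4, electron transport) and 1.097
(Selvam & Bhola, EGSnrc). The collision-kerma value sits 1.9% below the
dose-scored references and 0.9% below the kerma-style one. The package's
own cross-checks (Klein–Nishina sampler vs quadrature, primary
transmission vs closed form, an independent single-scatter quadrature
reproducing the engine's scatter fraction at 1 cm) localize this offset
to the stated physics approximations rather than to an implementation
defect:

* at 1 cm the dose = collision-kerma identity is at the edge of
  validity for ⁶⁰Co energies (secondary-electron transport shifts
  energy deposition outward, raising true dose above collision kerma in
  a steep $1/r^2$ field) — worth ~1–2%;
* free-electron Compton sampling and the residual-photoelectric table
  construction mildly under-produce multiply-scattered dose — a few
  tenths of a percent.

The radial dose function $g_L(r)$, which divides out most of these
effects, agrees with the published consensus values within its
statistical uncertainties over 0.25–20 cm.

Other limitations: flat capsule tips bias $F(r,\theta)$ near the axis;
Thomson-law coherent redirection ignores form-factor forward peaking;
the bundled steel/cobalt tables are Z-scaled rather than
compilation-anchored (their role is filtration, which largely cancels
between the two stages of $\Lambda$); and no bremsstrahlung, Doppler
broadening or polarization.

## Worked pipeline

```{r}
library(cobrachy)

cfg <- run_config(histories = 2e6, seed = 1, batches = 50)
res <- run_full_study(cfg, output_dir = "tg43_out")

res$dataset         # S_K per history, Lambda with k=1 uncertainty, g_L
res$comparison      # percent differences to the published values
```

The same pipeline is exposed as a shell tool
(`inst/scripts/cobrachy.R`) with `simulate`, `tg43` and `compare`
subcommands, and `scripts/acceptance.R` reproduces the headline numbers
from scratch with one root seed.
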