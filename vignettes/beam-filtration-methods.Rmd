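---
title: "Methods: thermal-neutron filtration dosimetry at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-neutron filtration dosimetry at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

Accelerator-based boron neutron capture therapy (BNCT) delivers an
epithermal neutron beam to a patient carrying a ¹⁰B compound (BPA).
Thermal-neutron capture on ¹⁰B releases short-range α/⁷Li fragments, so the
tumor dose is governed by the thermal flux at the tumor and by the
tumor-to-blood boron ratio.  Low-energy neutrons in the incident beam are
captured at shallow depth, load the healthy brain, and cap the dose
deliverable to a deep tumor.  A thin ⁶LiF plate at the beam exit exploits
the 1/v capture cross section of ⁶Li (σ₀ = 940 b at 0.0253 eV) to strip
those neutrons while passing the harder epithermal component; `beamlab`
evaluates such filters end to end: Monte Carlo transport through
collimator/filter/phantom scenes, KERMA-approximation four-component
dosimetry, RBE/CBE biological weighting, beam figures of merit, gold-wire
activation analysis, and voxel-phantom DVH evaluation.

## The synthetic source (and why it exists)

The real accelerator's beam-shaping-assembly (BSA) exit spectrum is
proprietary; nothing in this package depends on it.  `make_epithermal_source()`
generates the documented stand-in: a planar disc emitting

* a Maxwellian thermal component (kT = 0.0253 eV) below the cadmium cutoff
  (0.5 eV),
* a 1/E (flat-in-lethargy) epithermal component between 0.5 eV and 10 keV,
* an evaporation-like Maxwellian fast tail above 10 keV,

with default band fractions 0.02 / 0.88 / 0.10 (particles), a gamma
contaminant line spectrum (478 keV and 2.223 MeV lines, one gamma per 100
neutrons), and a cosᵐθ angular law.  Group intensities are closed-form
integrals of those shapes, so the grouped spectrum converges to the
analytic one under refinement, and in-group sampling is uniform in
lethargy.

Free parameters were fixed once, on physical grounds:

* **Fast-tail temperature, 12 keV.**  With 10% of source particles in the
  fast band, the tail temperature sets the fast-contamination kerma per
  unit epithermal fluence.  Clinical epithermal beams are designed to the
  IAEA purity recommendation (≲ 2.9 × 10⁻¹³ Gy·cm²); T = 12 keV puts the
  synthetic beam just inside it, while MeV-scale tails (which a BSA exists
  to suppress) violate it several-fold and drown the thermal-capture
  physics the filter acts on.
* **Angular exponent m = 2** — a moderately forward-peaked exit beam.
* **Disc radius.**  The constructor defaults to the full-scale
  clinical value (150 cm), but every packaged run configuration uses a bore-matched
  7 cm disc: a 150 cm disc feeds > 99% of histories into the collimator
  walls, which at desk scale is pure waste heat.  The parameter is plain
  config.
* **Source strength 2 × 10¹¹ /s/mA** — an arbitrary reference scale chosen
  once so the unfiltered maximum treatment time lands at the clinical
  tens-of-minutes scale.  Every shipped check is a ratio or an ordering and
  is invariant to it.

What a green test on this source does *not* establish: agreement with the
clinical device's absolute AD/MTT/skin values, which are spectrum
properties.  The suite asserts orderings, closed-form arithmetic, and
estimator consistency instead.

## Transport

`run_transport()` drives an analog Monte Carlo kernel (C++): 1/v capture
plus energy-independent elastic scattering per nuclide, isotropic in the
centre of mass; free-gas target motion below 1 eV (neutrons can up-scatter
and thermalise properly); the hydrogen elastic cross section rolls off as
σ₀/(1 + E/250 keV) to follow the free-proton behaviour at fast energies.
Fluence is scored with the track-length estimator (summed track lengths /
voxel volume / histories) in the three conventional bands, alongside
1/v-folded capture-rate tallies, hydrogen-recoil kerma, and per-channel
analog capture counts — giving two independent capture estimators whose
agreement is a standing test.  Photons (source gammas and the 2.223 MeV
hydrogen-capture line) are transported as straight-line attenuation with
energy-absorption deposition; Compton angular redistribution and buildup
are deliberately out of scope, as the gamma component is secondary here.
Statistical errors come from ≥ 20 history batches, with an optional
stopping rule on the relative error at a monitor voxel (default: 15 cm
depth on axis).  Implicit capture with Russian roulette (threshold 0.01,
survival 0.1) is available for deep-voxel variance, used in the phantom
runs.  The kernel's RNG is a seeded xoshiro256++: the same seed and
configuration reproduce tallies bit for bit, which is what makes the
fixed-seed ordering tests deterministic rather than statistical coin
flips.

Geometry is priority-resolved boxes / z-cylinders / z-annuli (collimator
with 12 cm bore, filter designs A (uniform disc), B (centred square plate),
C (disc + square)), plus an optional voxel block for patient phantoms.
Surface coincidences are handled by a 10⁻⁶ cm push; `distance_to_boundary`
is exact (validated surface crossings) and is cross-checked against a 1 µm
marching oracle in the tests.

## Dosimetry and weighting

The four KERMA-approximation components (Gy/h at 1 mA): boron
(1/v-folded capture rate × 2.31 MeV branch-weighted local charged-particle
energy, proportional to the ¹⁰B concentration), nitrogen (¹⁴N(n,p), 0.626
MeV local, from the material's own nitrogen), hydrogen (elastic-recoil
energy transfer above the thermal cutoff), gamma (photon energy
absorption).  Weighted dose is the standard four-term sum
W = 1.0·D_γ + 3.0·D_N + 3.0·D_H + CBE·D_B with CBE 3.8 / 2.5 / 1.34 for
tumor / skin / normal tissue, 25 µg/g blood boron, tumor-to-blood 3.5,
skin-to-blood 1.0, and a 12.5 Gy weighted brain limit — all plain config
(`weighting_config()`, shipped as `weights_default.json`).  The source
text's appendix with its dose-composition equations is not available; this
four-term sum is the standard BNCT decomposition and is uniquely
consistent with every parameter the text does state.

Figures of merit: advantage depth (deepest crossing of the tumor curve
with the normal-tissue peak — "deepest" resolves shallow build-up
re-crossings, since AD is a penetration measure), maximum treatment time
(limit / NT peak rate, skin band excluded from the peak search), skin dose
at delivery (skin-band weighted rate × MTT, with the four-component
split), off-axis flatness (max over |x| ∈ [4,6] cm / centre, at 2 cm
depth), and inverse-current scaling.

## Activation analysis

The gold-wire reaction-rate equation is implemented as

R = λC / [εγ e^(−λT_C) (1 − e^(−λT_m)) Σᵢ (Qᵢ/Δt)(1 − e^(−λΔt}) e^(−λ(n−i)Δt)]

(reactions per target atom per unit charge).  The archived source text
lost the equation's fraction bars; this grouping is anchored to the symbol
definitions and verified to < 0.1% against RK4 integration of the
production–decay equation over randomized pulsed schedules, including the
interval-splitting invariance in the λΔt → 0 limit.  The cadmium
difference divides (R_bare − R_cd) by an effective sub-cadmium cross
section taken as the 2200 m/s value with Westcott g ≈ 1; wire
self-shielding (0.25 mm wire) is neglected.  Closing the loop, predicted
wire rates folded from a transport tally recover the tallied sub-cadmium
flux exactly.

## Voxel phantom and DVH

`make_head_phantom()` builds the synthetic stand-in for the
non-redistributable training CT: nested ellipsoids (scalp 0.5 cm, skull
0.7 cm, brain) on a 2 mm grid, vertex at z = 0 with the beam entering from
the vertex, and four 2 cm mock tumors at 4 / 6 / 8 cm depth on axis and
8 cm depth 4 cm off-axis.  Voxel centres sit on the landmark lattice
(half-voxel grid shift) so sphere voxelization errors stay ~1–5%.  A
user-supplied HU volume can be imported instead; HU → density is a
monotone piecewise-linear ramp through (−1000, air) and (0, 1.0 g/cm³)
with air / lung / adipose / soft-tissue / bone bins.

DVH percentiles use the hottest-p% convention without interpolation
(D_p = largest dose received by ≥ p% of the structure), forced by the
two-level example D₉₅ = 10, D₅ = 20 for a half-and-half structure; the
homogeneity index is D₅/D₉₅, reported at one decimal when compared with
clinical DVH tables.  Phantom runs are normalized so the brain-mask maximum
weighted dose equals 12.5 Gy; at desk-scale statistics a raw voxel maximum
is a noise order statistic, so weighted maps are box-smoothed (6 mm
kernel, `box_smooth()`) before the maximum and the percentiles are taken —
this stabilises the normalization without erasing cm-scale gradients.

## Numerical choices

Band edges 0.5 eV / 10 keV (cadmium cutoff; conventional BNCT bands),
free-gas cut 1 eV, hydrogen-recoil scoring above the thermal cutoff (the
epithermal-vs-fast attribution of recoils is unstated in the source and
exposed as config), boundary push 10⁻⁶ cm, roulette 0.01/0.1, photon
weight floor 10⁻⁴ of the emitted weight.  Tally bins default to 2 mm;
metric runs use 5 mm lateral bins with a 1 cm axial averaging column.
Configs and the constants file are JSON; tally containers are RDS with a
JSON sidecar (no HDF5/NIfTI library is guaranteed in the target
environment).

## Known limitations

* The flat-lethargy 1/E epithermal stand-in carries far more weight below
  100 eV than a real BSA leakage spectrum.  A 99%-enriched LiF filter is
  essentially black there, so filtration cuts the surface thermal flux
  ~5× (clinical measurements of such filters: ~2×) and the MTT grows
  ~3.3× (clinically: ~1.9×).  One consequence is faithfully reported as a red test: the
  delivered skin dose does *not* drop with the filter in this synthetic
  world, because the fast-hydrogen and source-gamma skin components are
  untouched by a ⁶LiF plate and their delivered dose scales with the MTT.
  Every other expected clinical ordering (thermal suppression, AD/MTT monotone in
  thickness, design C flatter than design B, deep-tumor D₅₀ gain and HI
  non-increase at equal brain dose) emerges from the same stated world.
* Scattering is isotropic in the CM frame with energy-independent cross
  sections (plus the hydrogen fast rolloff); no resonances, no ENDF/ACE
  parsing, no photonuclear physics, no coupled electron transport.
* Photon transport has no Compton angular sampling; gamma dose is
  energy-absorption along straight rays.
* ¹⁴N capture gammas are not emitted; boron's 478 keV branch is folded
  into the 2.31 MeV local KERMA constant.
* The collimator length (10 cm) and the filter-to-phantom gap (0 cm) are
  unstated upstream and are config defaults.
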