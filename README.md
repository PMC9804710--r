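# beamlab

Desk-scale evaluation of **⁶LiF thermal-neutron filters for
accelerator-based boron neutron capture therapy (BNCT)**.

In BNCT an epithermal neutron beam irradiates a patient carrying a ¹⁰B
compound; thermal capture ¹⁰B(n,α)⁷Li deposits its energy within a cell
diameter, so tumor dose tracks the thermal flux and the tumor's boron
uptake.  The low-energy part of the incident beam is captured at shallow
depth, loading the healthy brain and capping the dose deliverable to deep
tumors.  A thin ⁶LiF plate at the beam exit removes those neutrons through
the 1/v capture law, σ(E) = σ₀√(E₀/E) with σ₀ = 940 b at E₀ = 0.0253 eV.
`beamlab` is a self-contained pipeline for studying that trade-off:

* a **parametric source model** standing in for the proprietary
  accelerator spectrum (Maxwellian thermal + 1/E epithermal +
  evaporation fast tail, gamma contaminant lines, cosᵐθ disc emission);
* **analog Monte Carlo neutron/photon transport** (C++ kernel) through
  collimator / filter designs A, B, C / phantom scenes, with track-length
  fluence tallies, free-gas thermalization, and batch statistics;
* **KERMA four-component dosimetry** (boron, nitrogen, hydrogen, gamma)
  with RBE/CBE weighting (RBE 3.0/3.0/1.0; CBE 3.8 tumor, 2.5 skin,
  1.34 brain; 25 µg/g blood boron, tumor:blood 3.5);
* **beam figures of merit**: advantage depth AD (depth where the weighted
  tumor dose falls to the peak weighted normal-tissue dose), maximum
  treatment time MTT (time to deliver the 12.5 Gy weighted brain limit),
  delivered skin dose, off-axis flatness, proton-current scaling;
* **gold-wire activation analysis**: the pulsed-schedule reaction-rate
  equation and cadmium-difference thermal-flux recovery;
* **voxel-phantom DVH evaluation** with a synthetic head phantom
  (2 mm grid, four 2 cm mock tumors at 4/6/8 cm depth and 4 cm off-axis),
  D₅/D₉₈/D₅₀/D₉₅ percentiles and the homogeneity index HI = D₅/D₉₅.

## Worked example

```r
library(beamlab)
src <- make_epithermal_source(disc_radius = 7)   # desk-scale synthetic beam
scene0 <- build_scene(NULL, phantom_material = "brain_icrp")
sceneC <- build_scene(filter_design("C", disc_thickness_mm = 5,
                                    square_side_cm = 8, square_thickness_mm = 5),
                      phantom_material = "brain_icrp")
rs <- run_spec(2e5, seed = 42)
for (nm in c("no filter", "design C")) {
  sc <- if (nm == "no filter") scene0 else sceneC
  bundle <- run_transport(src, sc, rs, tally_mesh(sc, c(0.5, 0.5, 0.2)))
  met <- beam_metrics(compute_dose_components(bundle))
  cat(sprintf("%-9s  AD = %.1f cm   MTT = %.0f min   skin = %.1f Gy\n",
              nm, met$ad_cm, met$mtt_min, met$skin_dose_gy))
}
homogeneity_index(69.7, 55.4)      # 1.258... -> 1.3 at one decimal
scale_with_current(75.6, 1, 2)     # 37.8 min at 2 mA
```

prints (exactly; runs are bit-reproducible for a fixed seed)

```
no filter  AD = 9.0 cm   MTT = 39 min   skin = 13.5 Gy
design C   AD = 9.7 cm   MTT = 124 min   skin = 14.0 Gy
```

Reading: on this synthetic beam the design-C filter (5 mm full-bore disc +
5 mm central 8×8 cm square) deepens the advantage depth by ~0.7 cm —
deep tumors become treatable — at the price of a ~3× longer irradiation,
recoverable by raising the proton current (`scale_with_current`).  The AD
and MTT *orderings* are the science; their absolute values belong to the
synthetic spectrum, not to any clinical device.

## Command line

```sh
inst/exec/beamlab pipeline --config run.json --seed 7 --out results/
inst/exec/beamlab makesource --out spectrum.txt
inst/exec/beamlab activation --meas meas.csv --schedule charge.csv
```

The pipeline writes `metrics.csv` (design, AD_cm, MTT_min, skin_dose_Gy),
`profiles.csv`, `tallies.rds` and a reproducibility manifest (seed +
config hash); a design-A thickness sweep (2.5–20 mm) is one config key.

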