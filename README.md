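# loopquant

Quantitative analysis of SMC loop-extruder dynamics (Condensin, Cohesin,
CTCF) as cells rebuild interphase genome architecture after mitosis.

## The problem

After chromosome segregation, the Condensin-organized mitotic chromosome
must be converted into the Cohesin/CTCF-organized interphase genome.
Following that handover quantitatively in single cells takes a chain of
measurements, each with its own estimator:

- **Absolute copy numbers** from FCS-calibrated imaging. The fluorescence
  autocorrelation amplitude gives a particle number, `G(0) = 1/N`, in a
  known effective volume; a regression of cell intensities on FCS-derived
  concentrations converts images to concentrations and copy numbers.
- **Chromatin-bound fractions and residence times** from photobleaching.
  FRAP recovery is summarized as a normalized difference
  `D(t) = (F_ub(t) − F_b(t)) / (F_ub(0) − F_b(0))` and fitted with
  `D(t) = a + (1 − a) exp(−koff t)`: `a` is the stably bound (immobile)
  fraction, `1/koff` the residence time of the exchanging pool. A rapid
  spot-bleach assay reads the bound fraction from the depletion of a
  continuously illuminated chromatin spot,
  `100·(pre − post)/pre`, calibrated against free-GFP (0%) and H2B-GFP
  (~100%) references.
- **Per-megabase occupancy**: bound copies = copies × bound fraction,
  divided over the genome (2 × 7,900 Mb for the two early-G1 daughter
  nuclei) — the quantity that makes abundances comparable across proteins
  and cell-cycle stages.
- **STED spot analysis**: segmentation (Otsu within the nuclear mask,
  erosion/size filtering, watershed splitting), Pearson colocalization,
  labeling efficiency, and a fixed-means Gaussian-mixture estimate of the
  fraction of doubled-intensity spots (unresolvable extruder pairs).
- **Chromatin-trace analysis**: QC filtering of 3D FISH traces, median
  pairwise distance matrices, contact maps at 120 nm, difference matrices
  and scaling curves.
- **A stochastic 1D loop-extrusion simulator** (two species, CTCF
  boundary stalling, encounter-induced pairing; C++ core) that connects
  the measured rates to loop sizes (`L = v/koff`), steady-state densities
  (`loading_rate/koff`), and the encounter probability
  `1 − exp(−ρL)` that explains why extruder pairing appears only at high
  occupancy.

Every input class can be generated with known ground truth by the
`gen_*` functions, so the whole pipeline is testable without microscope
data.

## Worked example

```r
library(loopquant)

# Per-megabase occupancy from packaged copy-number / bound-fraction data
occ <- build_occupancy_table(occupancy_reference())
subset(occ, protein %in% c("CTCF", "STAG1", "STAG2"),
       select = c(protein, stage, bound_copies, per_mb))
#>    protein    stage bound_copies per_mb
#> 4     CTCF early_G1        77810   4.92
#> 6    STAG1 early_G1        33170   2.10
#> 7    STAG2 early_G1        47940   3.03
#> 11    CTCF       G1        89280   5.65
#> 13   STAG1       G1        40660   2.57
#> 14   STAG2       G1       129930   8.22

# FRAP: recover kinetics from a noisy synthetic recovery curve
crv <- gen_frap_curve(a_immobile = 0.488, koff = 1/139, noise_sd = 0.02,
                      frame_interval = 20, n_frames = 30, seed = 1)
fit_recovery(crv)
#> FRAP kinetic fit: converged
#>   immobile fraction a = 0.483, koff = 0.006842 /s (residence 146.2 s)

# Simulate STAG2-like extruders at G1 occupancy (8 complexes per Mb)
sp <- species_params("STAG2", loading_rate = 8/120, koff = 1/120,
                     speed = 1, pair_on_encounter = TRUE)
simulate_extrusion(20, sp, duration = 1200, seed = 1)
#> Loop-extrusion simulation: 20 Mb lattice, 1200 s, dt = 0.1 s
#>   150 extruders bound at end, 1514 completed loops recorded
#>   mean density (/Mb): STAG2 = 7.91
#>   paired fraction: 0.613

encounter_probability(c(3, 8), 120)
#> [1] 0.3023237 0.6171071
```

Reading the numbers: CTCF and Cohesin-STAG1 are already bound at 2–5
complexes per Mb in early G1, while STAG2 rises from ~3 to ~8 per Mb as
its import completes. At 8 extruders per Mb holding ~120 kb loops
(1 kb/s × 120 s), a majority of extruders are adjacent-stalled against a
neighbor in the simulation (paired fraction 0.61) — at 3 per Mb the same
model predicts far fewer encounters (closed form: 0.30 vs 0.62).

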