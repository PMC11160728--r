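---
title: "Quantifying loop-extruder dynamics during mitotic exit: models and methods"
author: "loopquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loop-extruder dynamics during mitotic exit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopquant)
```

# Scope

After mitosis, cells replace a Condensin-based chromosome organization with a
Cohesin-based interphase organization. Quantifying that handover requires a
chain of measurements: absolute protein copy numbers (FCS-calibrated
imaging), chromatin-bound fractions and residence times (FRAP and
spot-bleach photobleaching), per-megabase occupancy arithmetic,
super-resolution spot counting and intensity analysis (STED), and 3D
chromatin-trace statistics (distance and contact maps). `loopquant`
implements each step, together with a stochastic loop-extrusion simulator
that turns the measured rates into testable predictions about loop sizes,
extruder encounters and loop nesting. A synthetic-data module generates
every input class with known ground truth, so the full chain is testable
without microscope data.

# Models

## FRAP with an immobile fraction

Half-nucleus photobleaching is summarized as the normalized difference
between the unbleached and bleached regions,

$$D(t) = \frac{F_{ub}(t) - F_b(t)}{F_{ub}(0) - F_b(0)},$$

which starts at 1 and decays as the two pools exchange. A single
exponential with an immobile fraction,

$$D(t) = a + (1 - a)\,e^{-k_{off} t},$$

is fitted by bounded nonlinear least squares (`fit_recovery()`, using
Levenberg–Marquardt with $a \in [0, 1]$, $k_{off} > 0$). The immobile
(stably bound) fraction $a$ is the pool that does not exchange during the
observation window; $1/k_{off}$ is the residence time of the dynamically
exchanging pool. Initialization is deterministic — $a$ from the last
observed value, $k_{off} = \ln 2 / t_{1/2}$ from the time at half decay —
so fits are reproducible. Degenerate inputs are handled explicitly: a
constant curve returns $a$ at its level with $k_{off}$ pinned at the lower
bound and a note; a rising curve is flagged `fit_ok = FALSE` rather than
fitted. Only the recovery phase is fitted: frames during the bleach train
are excluded and $t = 0$ is the first post-bleach frame. Reaction–diffusion
FRAP models and bleach-spot profile corrections are out of scope; the
profile-aggregation step that produces the per-region mean series operates
on raw images upstream of this package, which accepts the region means
directly.

## Spot-bleach bound fractions

Continuous point illumination of a chromatin spot depletes the bound pool
while the unbound pool is replenished from the soluble reservoir. The raw
bound fraction is the fractional intensity loss between the first and last
500 ms of the 30 s trace,

$$\mathrm{bound\ \%} = 100 \cdot \frac{\langle I \rangle_{first\ 500ms} - \langle I \rangle_{last\ 500ms}}{\langle I \rangle_{first\ 500ms}},$$

and is calibrated against two references measured the same way — freely
diffusing monomeric GFP (defining 0%) and H2B-GFP (defining ~100%) — by the
unique affine map sending those anchors to 0 and 100
(`calibrate_bound_fraction()`, clipped to [0, 100]). The synthetic
generator (`gen_spotbleach_trace()`) records a 500 ms pre-bleach window at
the undepleted level before the exponential depletion begins, matching the
windowed estimator: the first analysis window then reads the undepleted
intensity and the noiseless estimate equals the planted bound fraction.

The complementary half-nucleus estimator
(`halfbleach_bound_fraction()`) reads the soluble fraction from the
intensity loss in the *unbleached* half after the soluble pool has been
bleached out: soluble molecules equilibrate across the nucleus and are
removed, bound molecules in the unbleached half are untouched, so
$f_{bound} = I_{ub,post}/I_{ub,pre}$. This convention (reading the loss
from the unbleached half) is this package's choice of formula for a
measurement whose goal, but not arithmetic, is standard.

## FCS calibration

The autocorrelation of photon counts from a confocal volume containing on
average $N$ freely diffusing particles is

$$G(\tau) = \frac{1}{N}\left(1 + \frac{\tau}{\tau_D}\right)^{-1}
\left(1 + \frac{\tau}{\kappa^2 \tau_D}\right)^{-1/2} + G_\infty,$$

with diffusion time $\tau_D$ and axial-to-lateral ratio $\kappa$. Because
$G(0) = 1/N$, the fit (`fit_acf()`, weighted Levenberg–Marquardt) yields an
absolute particle number. With a reference dye of known concentration the
effective volume follows as $V_{eff} = N/(C N_A)$ and, inversely, unknown
concentrations as $C = N/(V_{eff} N_A)$. A regression of measured cell
intensities on FCS-derived concentrations gives the calibration line
(`build_calibration_line()`): its slope inverse is the calibration factor
(nM per background-corrected intensity unit) and its intercept the imaging
background. `image_to_numbers()` then converts masked voxel intensities to
concentrations, clipping negative background-corrected values at zero
(copy numbers are nonnegative), and integrates to total copies.

Modelling choices: no triplet/blinking term is included (the fit target is
$N$, and the synthetic curves use the same model); $\kappa$ is fixed to 5
by default — a typical confocal value — and can be overridden or fitted.
Absolute effective-volume values are instrument-specific (reference-dye
choice alone shifts them by tens of percent), so only the arithmetic, not
any particular volume, is meaningful here.

## Per-megabase occupancy

Chromatin-bound copies are `nuclear_copies * bound_fraction`, and densities
are expressed per megabase assuming an equal distribution over the genome.
The divisor is $7{,}900\ \mathrm{Mb} \times 2 = 15{,}800$ Mb — the HeLa
genome per nucleus times the two daughter nuclei present in early G1.
Two conventions in the published summary tables are reproduced deliberately
rather than resolved:

* the stated "7.9 Mb" HeLa genome is read as 7.9 **Gb** (7,900 Mb), which
  is the only reading consistent with the printed densities;
* the G1-stage table (a single nucleus) uses the *same* 15,800 Mb divisor
  as the early-G1 table, as its printed densities imply.

`build_occupancy_table()` therefore applies one configurable divisor
(default `genome_model()`), and prefers the FRAP bound fraction over the
spot-bleach one when both exist — the fallback matters for proteins whose
FRAP fit fails (weak recovery), for which the spot-bleach estimate is used.
Derived columns are kept unrounded; `round_half_up()` reproduces printed
table precision (half-up, not banker's rounding).

Two closed forms accompany the table: the expected loop size
$L = v \cdot \tau_{res}$ for an extruder growing its loop at total speed
$v$ during a residence time $\tau_{res}$ (1 kb/s for 120 s gives 120 kb),
and the encounter probability under Poisson extruder placement at density
$\rho$ per Mb,

$$P_{enc} = 1 - e^{-\rho L},$$

the probability that an extruder's loop interval overlaps at least one
neighbor. At 120 kb loops this gives 0.302 at 3 complexes/Mb and 0.617 at
8/Mb — the quantitative core of the claim that encounter-driven pairing
becomes likely only once Cohesin-STAG2 is fully imported.

## The loop-extrusion simulator

`simulate_extrusion()` runs fixed-timestep stochastic dynamics on a 1D
lattice of 1 kb sites (engine in C++). Per step and species: loading at a
uniform random unoccupied site with probability
`loading_rate * lattice_mb * dt`; symmetric two-arm growth at `speed/2`
kb/s per arm; permanent stalling at CTCF sites whose orientation faces the
arm (`+` stalls left-moving arms, `-` right-moving ones, so a convergent
`+ ... -` pair captures loops); collision blocking at adjacent sites
(anchors never cross, which enforces that loop intervals are always nested
or disjoint — the planarity the trace analysis assumes); and unloading
with probability `koff * dt`, recording the completed loop size.

Design choices, each of which the tests exercise:

* **Fixed `dt` (default 0.1 s), not event-driven.** At these rates the
  discretization error is negligible and the scheme stays simple; the
  stability precondition `dt * max(speed) <= 1 kb` is enforced.
* **`speed` is the total loop-growth rate**, split across the two arms, so
  the loop-size arithmetic `120 s x 1 kb/s = 120 kb` carries over directly:
  in the sparse CTCF-free limit the mean completed loop size is
  `speed/koff` and the steady-state density `loading_rate/koff` per Mb —
  both verified against long runs to within a few percent.
* **CTCF stalling is permanent** for the extruder's remaining lifetime and
  one-directional per site orientation — the simplest reading of
  convergent-site stalling.
* **Encounters stall but do not unload.** Whether paired complexes continue
  extruding as a unit is biologically open; pairing is therefore a flag
  (`pair_on_encounter`) that marks both partners without changing their
  dynamics. The reported `paired_fraction` counts extruders ever marked
  paired or currently adjacent-stalled.
* **Loading is uniform** (no sequence bias) and ties are broken
  deterministically by extruder id, so runs are bit-reproducible per seed.

`nesting_stats()` summarizes a configuration (containment depths, paired
fraction; crossing intervals are an invariant violation and raise).
`loops_to_distance_map()` bridges the simulator to trace-style matrices:
each kb covered by $d$ nested loops contributes $c^d$ kb of effective
contour (compaction $c = 0.25$ by default), and distances follow
ideal-chain scaling $\propto \sqrt{\mathrm{contour}}$. Nesting a loop
inside an existing loop therefore compacts its interior further — the
qualitative signature the trace difference matrices detect. 3D polymer
dynamics, Hi-C map generation and sister-chromatid cohesion are out of
scope.

## STED spot analysis

`segment_spots()` follows the standard operator sequence: optional
morphological-opening background subtraction (the rolling-ball analogue,
radius 50 px, off by default because the synthetic images have flat
background), mild Gaussian blur (sigma 1), Otsu threshold computed from
the pixels inside the nuclear mask, binary erosion (disc radius 1) with
removal of objects under `min_size` (4 px), dilation, and
watershed-by-intensity splitting of clustered spots with a minimum peak
separation (4 px). Otsu-within-mask is computed on the masked histogram
directly, since the library routine thresholds whole images; by default
the threshold is per-image, with a `threshold` argument to share one value
across the images of an experiment. A contrast guard returns an empty
table when the Otsu split separates the two classes by less than three
background standard deviations — on an image with no real foreground Otsu
otherwise happily splits the noise itself. The numeric values of erosion
radius, `min_size` and peak distance are package defaults for the stated
operator sequence, not measured constants.

Per-spot intensities are background-corrected by the median intensity of
masked non-spot pixels, which matters for ratio statistics:
`dimer_fraction()` models test intensities as a two-component Gaussian
mixture with means fixed at the monomer level $\mu$ (the reference median)
and $2\mu$ and equal variances (the reference sd), estimating only the
mixing weight by EM. Fixing the means keeps the model identifiable on
small samples and encodes the interpretation that pairs of complexes too
close to resolve (~60 nm STED precision vs ~50 nm complex size) appear as
single spots of doubled intensity. `pearson_colocalization()` is the plain
Pearson correlation over masked pixels, flagged undefined for constant
channels; `spot_density()` and `labeling_efficiency()` convert 2D counts
to volumetric densities (assuming a ~500 nm optical section) and compare
them to the density expected from calibrated live imaging.

## Chromatin-trace analysis

`qc_filter()` applies per-point thresholds (signal-to-background, fit sd,
barcode distance — numeric defaults are package conventions, as published
pipelines do not fix them) and then removes traces with fewer than 20
surviving points. `median_distance_matrix()` and `contact_map()` (120 nm
threshold) aggregate within-trace pairwise 3D distances per bin pair;
cells without samples are `NA` and per-cell sample counts are attached.
`difference_matrix()` subtracts condition maps with `NA` propagation;
`scaling_curve()`/`scaling_exponent()` produce the distance-versus-
separation data and its log–log slope. `contact_enrichment_block()`
recovers loop domains by maximizing the *summed* contact enrichment over
the per-separation expectation inside a candidate interval (excluding the
two nearest diagonals); the sum, unlike the mean, is maximized by the full
loop interval rather than by a small intense sub-block.

# The synthetic-data generators

The generators define the conditions under which the pipeline is tested:

* `gen_frap_curve()`: the exact FRAP model plus additive Gaussian noise.
  Test conditions follow the measurement protocol — 30 frames at 20 s
  intervals, noise sd 0.02 on the normalized difference — and parameter
  grids bracket the measured kinetics (immobile fractions ~0.1–0.5,
  residence times ~60–280 s).
* `gen_spotbleach_trace()`: pre-bleach window plus exponential depletion to
  the unbound-fraction plateau.
* `gen_fcs_acf()`: the diffusion ACF with relative Gaussian noise.
* `gen_sted_image()`: single-pixel impulses at uniform random positions in
  a 750 px field (200 µm² at 18.88 nm pixels), blurred with a Gaussian of
  sd 2.6 px whose kernel is normalized to unit peak so the planted peak
  stays `intensity_gain`-fold (default 6) above the constant noisy
  background; the background level is a free parameter of the simulation
  (default 10 with noise sd 1). Dimers are planted as single impulses of
  doubled amplitude — not two offset impulses — matching their appearance
  as unresolvable single spots. A second channel can share a chosen
  fraction of positions for colocalization nulls and positives.
* `gen_traces()`: a Gaussian-chain backbone (per-axis step sd 60 nm per
  12 kb bin, chosen to give adjacent-bin distances of ~90 nm and
  megabase-scale extents under a micrometer, typical of chromatin tracing
  at this resolution) with per-loop step compaction, 20 nm localization
  noise, random dropout, and QC columns drawn from passing or failing
  distributions. Loop geometry is validated up front: intervals must be
  nested or disjoint.

All generators take explicit seeds, never touch the caller's RNG state,
and are bit-reproducible. What they deliberately do **not** emulate:
realistic optical PSFs and camera noise physics, 3D image stacks, full
polymer dynamics (the trace backbone is an ideal chain, so its scaling
exponent is exactly 0.5 rather than the flatter exponents of crumpled
chromatin), or drift/aberration artifacts (the trace analysis starts from
corrected coordinate tables). Passing tests therefore demonstrate that the
estimators are correct and stable under their stated models — not that the
models capture every property of real microscope data.

# Numerical conventions and problem sizes

* Printed-table comparisons use half-up rounding at each column's printed
  precision (`round_half_up()`).
* Nonlinear fits use `minpack.lm` with bounded parameters and deterministic
  moment-based starts; optimizer failure is reported via `fit_ok`, never an
  exception.
* The simulator's closed-form checks use a 100 Mb lattice at density
  0.1/Mb run for 130,000 s (~10,000 unload events), giving a ~1% standard
  error on the mean loop size; pairing comparisons use 50 Mb lattices at
  3 vs 8 complexes/Mb for 1,200 s (10 residence times), 50 seed pairs.
* Trace analyses use 500 traces of 100 bins; STED checks use 50 planted
  spots (recall) and 300-spot channel pairs (colocalization) in the full
  750 px field. These sizes keep every Monte-Carlo estimate's sampling
  error well below the tolerance it is compared at.

# Known limitations

* The occupancy divisor intentionally mirrors the published convention for
  both cell-cycle stages; biologically one might argue the G1 divisor
  should be halved (one nucleus), which would double the G1 densities.
  The divisor is configurable where that matters.
* The encounter model is a closed-form Poisson-overlap approximation; the
  simulator is the quantitative reference for pairing behavior.
* The mixture model for dimers fixes component means at exactly 2:1; real
  labeling stoichiometry and partial maturation would blur this ratio.
* `halfbleach_bound_fraction()` assumes complete soluble-pool bleaching
  and instant mixing; incomplete bleaching biases the bound fraction up.
* The simulator has no loading-site bias, no sister cohesion, and no
  mitosis-specific features; Condensin-like parameterizations run on the
  same engine but get no dedicated physics.
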