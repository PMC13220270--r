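---
title: "Proton pathways in antiporter modules: channel detection, hydration profiling and transport kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton pathways in antiporter modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonpath)
```

## Scope and model

The antiporter-like membrane subunits of respiratory Complex I (Nqo12,
Nqo13 and their homologues) are thought to conduct protons across the
membrane through a buried, discontinuously hydrated channel whose wetting
is gated by bulky nonpolar residues. `protonpath` implements the
computational side of characterising such channels and the biochemical side
of quantifying proton transport in reconstituted proteoliposomes:

1. **Channel detection** (`build_grid()`, `find_channel()`) — the protein
   is approximated as a set of van der Waals spheres (heavy atoms only;
   solvent and a configurable set of excluded residues are not obstacles).
   On a voxel grid, each voxel's *clearance* is the radius of the largest
   probe sphere centred there. The channel from a seed residue (the central
   lysine of an antiporter module) to bulk solvent on each membrane side is
   the path maximising the minimum clearance (maximin / widest path), with
   ties broken by arc length. Both half-paths are concatenated into a
   single N-side-to-P-side path whose arc length is the channel coordinate
   R (0 at the N-side terminus).
2. **Hydration and field profiling** (`water_occupancy()`,
   `electric_field()`, `aggregate_replicas()`) — along R, the water
   occupancy is the fraction of trajectory frames with a water oxygen
   within a capture radius (default 2 Å) of the coordinate, and the
   electric field is a direct vacuum Coulomb sum over non-solvent partial
   charges outside an exclusion radius (default 2 Å), in V/Å.
3. **Transport kinetics** (`ph_trace()`, `extract_delta_ph()`,
   `psi_trace()`, `initial_rate()`, `proton_flux()`) — pyranine (HPTS)
   ratiometric fluorescence is converted to pH via
   `pH = a·log10(I460/I405) + b`; oxonol VI differential absorbance is
   converted to membrane potential via a linear calibration anchored in
   valinomycin/K⁺ Nernst potentials; dΨ/dt is converted to a per-liposome
   proton flux through the membrane capacitance.
4. **Respiration assays** (`linear_rate()`, `fecn_activity()`,
   `normalize_respiration()`, `gfp_level()`) — oxygraph slopes normalised
   by total protein and by NADH-dehydrogenase (FeCN) activity, reported as
   a percentage of a reference construct.

## Channel search: algorithm and numerical choices

The clearance grid uses spacing 0.8 Å by default — finer than the 0.9 Å
probe it must resolve — with a 26-connected voxel neighbourhood and
Euclidean edge lengths. Clearance is capped (default 6 Å): values at the
cap mean "at least this open", which is ample since bottlenecks of interest
are ~1–3 Å. The maximin bottleneck is computed exactly by bisection over
the sorted voxel clearance levels with flood-fill connectivity; the
shortest path at the bottleneck level is then found by Dijkstra with
Euclidean weights (via igraph). On grids up to 20³ the result is checked,
exactly, against an independent union-find insertion oracle in the test
suite.

Two design points were genuinely open and are resolved as follows:

* **No wrap-around through the far solvent.** While searching toward one
  membrane side, the opposite side's bulk slab is out of bounds. Without
  this rule the widest path from a blocked channel happily exits the near
  side and circles the outside of the protein to the far slab — a route the
  surrounding lipid would forbid but which a finite grid cannot otherwise
  exclude.
* **Path objective.** We maximise the bottleneck clearance and tie-break by
  arc length, rather than minimising a tunable cost functional; only the
  probe radius is a published parameter, and the maximin objective is the
  one the probe radius directly constrains.

The raw voxel centreline is smoothed by a centred 3-point moving average
(termini anchored) and local radii are re-evaluated exactly against the
obstacle spheres on the smoothed centreline, so the reported
`bottleneck_radius` is a geometric quantity, not a grid artefact; the
pre-smoothing grid bottleneck is kept as `search_bottleneck`.
`extend_to_bulk()` automates the manual step of continuing a tunnel out to
bulk solvent; its distance cap applies to the *appended arc length*, so a
sealed terminus is flagged rather than "reached" by a detour.

For the lining profile, residues are classified titratable (Asp, Glu, His,
Lys, Arg, Tyr, Cys), polar (Ser, Thr, Asn, Gln) or nonpolar; the channel
radius is additionally reported with titratable residues removed from the
obstacle set, since protonatable side chains line the conducting lumen
rather than bounding it.

## Hydration and field profiles

Occupancy at a coordinate is the frame ratio with ≥ 1 water oxygen within
the capture radius (hydrogens are ignored; water identity is keyed on the
oxygen). Replica aggregation reports the mean and *population* SD
(divisor n) across replicas; optional normalisation rescales the mean
profile by its maximum (per-profile maximum, not a bulk-water expectation).
The field is reported as the magnitude of the frame-averaged vector —
averaging magnitudes instead is available (`average = "magnitude"`), and
the two differ exactly when the field direction fluctuates. Sources closer
than the exclusion radius are omitted to avoid near-singular contributions;
the complementary reading (keep only near sources) is available as
`exclusion_mode = "include_within"`. No dielectric screening is applied
(vacuum permittivity, k·e = 14.3996 V·Å); 1 V/Å = 100 MV/cm
(`field_to_mv_cm()`). Minimum-image distances are used when a periodic box
is present. Trajectories must be superposed onto the reference frame first
(`superpose()`, least-squares Kabsch on a residue selection), since a fixed
channel axis is meaningful only in a common frame.

## Kinetics: calibrations, fits, flux

`extract_delta_ph()` takes the initial pH as the baseline mean over the
minute before the triggering ATP addition and the final pH as the plateau
of a single-exponential fit `pH∞ + (pH₀ − pH∞)·exp(−k(t−event))`;
ΔpH = initial − final. Initialisation: plateau from the last decile,
amplitude from the first post-event point, k from a log-linearised early
decay. A trace whose early/late level difference is indistinguishable from
noise (averaged over ~10 early and the last-decile points, 3σ) is flagged
`"flat"` with k reported as NA rather than fitted; a fitted negative k is
flagged `"negative_rate"`. The event time comes from trace metadata, not
auto-detection.

The oxonol calibration is assumed linear in ΔA over the calibrated range,
with known potentials set by K⁺ gradients: Δψ = (RT/F)·ln(K_out/K_in)
(computed as a log difference, which is exactly antisymmetric under
inversion). Initial rates are least-squares slopes over the first second
(2 ms sampling ⇒ ~500 points).

`proton_flux()` converts dΨ/dt to H⁺ s⁻¹ per liposome:
flux = C_m·π·d²·(dΨ/dt)/e, with C_m in µF cm⁻², d in nm, rate in mV s⁻¹.
Defaults d = 100 nm (the extrusion pore diameter) and C_m = 0.9 µF cm⁻² (a
typical bilayer value) give 211.8 H⁺ s⁻¹ at 120 mV s⁻¹. Fluxes are
reported raw; an optional orientation correction divides by the fraction of
transporters facing N-side-in (default 0.75, off by default).

## Respiration assays

The "linear range" of an oxygraph or FeCN trace is defined operationally:
the longest contiguous run where a 10-point running local slope stays
within 10% of its median; an explicit window always overrides. O₂
consumption is reported positive. Normalised activity is
100·(rate/protein/FeCN) relative to the reference construct (exactly 100
for the reference by construction), with first-order error propagation
(relative variances add); reported ± values are treated as SDs. sfGFP
expression is the 510 nm emission peak (nearest sample, or a three-point
quadratic interpolation around the local maximum) per mg mL⁻¹ protein.

## What the synthetic data emulate — and what they do not

`make_channel_structure()` builds a solid block of uncharged 1.7 Å
pseudo-atoms with a tube of stated lumen radius bored along a straight,
L-bent or S-curved centreline; rings of wall atoms placed exactly at
`lumen + 1.7 Å` pin the on-axis clearance to the stated lumen, so the
bottleneck ground truth is analytic. Blocker discs narrow the lumen at a
stated coordinate. Wall atoms are grouped into ~3 Å pseudo-residues named
after the requested lining classes. `make_water_trajectory()` places one
water slot per channel grid point i.i.d. across frames with the target
probability; slots are spaced 5 Å — wider than the 2 Å capture radius — so
each coordinate's realized occupancy is an independent Bernoulli fraction
that converges to its target at the binomial rate. `make_pyranine_trace()`
/ `make_oxonol_trace()` invert known kinetics through the calibrations at
the instrument resolutions (0.6 s and 2 ms) with Gaussian noise; the oxonol
rise is strictly linear for 2 s before saturating, so the 1 s initial-rate
window sees a truly linear signal. Defaults: ΔpH event at 60 s in a 7 min
assay, k = 0.01 s⁻¹, noise 0.002 pH; oxonol plateau 150 mV, noise 1 mV.

These fixtures deliberately omit: temporal autocorrelation of channel
wetting (occupancy is a per-frame ratio, so i.i.d. placement has the same
expectation), water hydrogens, lipids, conformational dynamics of gating
side chains, dye-binding kinetics, buffering capacity and pmf partitioning.
Passing the recovery tests therefore demonstrates that the *analysis* is
correct and well-calibrated under the stated noise models — not that the
generators reproduce real trajectories or real assay noise.

## Problem sizes and determinism

Test and acceptance runs use desk-scale problems chosen as the smallest
sizes at which each property is decisive: channel fixtures 16–40 Å long
(~2,000–3,000 pseudo-atoms, grids ≲ 80³), 25 random ≤ 20³ cavities for the
oracle equivalence, 2,000-frame trajectories for binomial occupancy
recovery, 100 random charge systems for the field oracle, and ~100 seeded
replicates per kinetics recovery study. Every stochastic step is seeded;
generators are bit-reproducible given their seed, and pipeline reports are
byte-identical across reruns of the same config (numbers are written with
17 significant digits).

## Known limitations

* Single reference-structure channel: tunnels are not recomputed per frame,
  matching the fixed coordinate axis the profiles assume; time-resolved
  tunnels and multi-tunnel ranking/clustering are out of scope.
* The bulk definition is a pair of axis-aligned slabs; oblique membranes
  would need a rotated frame.
* Vacuum electrostatics only; no reaction-field/PME and no free-energy
  estimates of wetting.
* The grid search is exact for the maximin objective but its path geometry
  is voxel-limited; local radii are re-evaluated exactly, arc lengths carry
  O(spacing) error per bend.
* Whether field profiles should plot the axial projection or the magnitude
  is ambiguous in the source material; the magnitude is primary and the
  full vector is always retained.
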