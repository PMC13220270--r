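# protonpath

Channel detection, hydration/electric-field profiling and proton-transport
kinetics for membrane antiporter modules — the analysis stack for studying
how bulky nonpolar "gating" residues control proton conduction through the
antiporter-like subunits of respiratory Complex I, in R.

## What it computes

**Channel detection.** Heavy atoms become van der Waals spheres; a voxel
grid stores the clearance (largest probe radius) at every point. The
channel from a seed residue (the central lysine of an antiporter module) to
bulk solvent on both membrane sides is the *widest path*: it maximises the
bottleneck clearance

    b(P) = min over voxels v in P of clearance(v),

ties broken by arc length, computed exactly by bisection over clearance
levels plus flood fill, and verified in the tests against an independent
union-find maximin oracle. The concatenated N-side→P-side path is
parameterised by arc length R (Å), the channel coordinate.

**Profiles along R.** Water occupancy = fraction of trajectory frames with
a water oxygen within 2 Å of the coordinate; electric field = direct
vacuum Coulomb sum E = k·Σ qᵢ·r̂ᵢ/rᵢ² (V/Å) over non-solvent partial
charges beyond a 2 Å exclusion radius; replica aggregation with
mean ± population SD and optional peak normalisation.

**Proteoliposome kinetics.** Pyranine (HPTS) ratiometric pH,
pH = a·log₁₀(I⁴⁶⁰/I⁴⁰⁵) + b; ΔpH from a baseline average and a
single-exponential plateau fit. Oxonol VI membrane potential via a linear
ΔA₅₈₈₋₆₂₅ calibration anchored in K⁺/valinomycin Nernst potentials,
Δψ = (RT/F)·ln([K⁺]out/[K⁺]in); initial rates over the first second; and
per-liposome proton flux from the membrane capacitance,

    flux = C_m · π d² · (dΨ/dt) / e .

**Respiration assays.** Oxygraph and FeCN linear rates with automatic
linear-range detection, normalised per protein and NADH-dehydrogenase
activity as % of a reference construct, and sfGFP 510 nm expression levels.

A synthetic-data module generates every fixture with analytic ground truth:
channel-bearing pseudo-structures, water trajectories with known occupancy,
point-charge systems with closed-form fields, and assay traces with known
ΔpH/rates — so the full pipeline is testable without any external data.

## Worked example

```r
library(protonpath)

## a 40 A channel of 3 A lumen through a pseudo-atom wall
fx   <- make_channel_structure(length = 40, lumen_radius = 3)
spec <- search_spec(fx$seed_selector, probe_radius = 0.9, bulk = fx$bulk)
grid <- build_grid(fx$structure, spec)          # 0.8 A voxels
path <- find_channel(grid, spec)
path
#> TunnelPath: 52 points, arc length 40.8 A, bottleneck 3.00 A

## water occupancy along the channel from a 2000-frame trajectory
wt  <- make_water_trajectory(fx, c(0.05, 0.3, 0.5, 0.8, 0.95, 0.6, 0.15),
                             n_frames = 2000, seed = 1)
occ <- water_occupancy(wt$trajectory, wt$structure, fx$path, step = 5)
round(occ$occupancy, 3)   # targets recycled along the 9-point R grid
#> [1] 0.056 0.294 0.510 0.810 0.952 0.595 0.154 0.056 0.297

## pyranine trace -> delta-pH, with the printed calibration a=1.931, b=7.926
cal <- pyranine_calibration(1.931, 7.926)
tr  <- make_pyranine_trace(0.081, noise_sd = 0.002, seed = 4)
res <- extract_delta_ph(ph_trace(tr, cal), event_time = 60)
res$delta_pH
#> [1] 0.08122180

## membrane-potential slope -> protons per liposome per second
as.numeric(proton_flux(120, liposome_spec(diameter = 100,
                                          specific_capacitance = 0.9)))
#> [1] 211.7694
```

The bottleneck equals the fixture's analytic lumen radius, the occupancies
recover their generating targets within binomial error, the ΔpH fit
recovers the generating 0.081 within its standard error, and a 120 mV s⁻¹
potential buildup on a 100 nm liposome corresponds to ~212 H⁺ s⁻¹.

A thin command-line front end wraps the same functions
(`exec/protonpath channel|kinetics|respiration|run|simulate|...`), driven
by a single JSON config with an embedded seed; reports are byte-identical
across reruns.

## Layout

```
R/                    implementation (structure/trace IO, grid, channel
                      search, hydration & field, kinetics, respiration,
                      synthetic data, pipelines)
exec/protonpath       command-line front end
tests/testthat/       unit, property and acceptance tests (oracle code in
                      helper-oracles.R)
scripts/acceptance.R  headline-quantity reproduction
vignettes/            methods vignette
```
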