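# ionbindr

Transient ion–protein binding, rotational relaxation and solvation analysis
for molecular dynamics trajectories.

## The scientific problem

Cryptochrome 4, the flavoprotein implicated in avian magnetoreception, is
re-oxidised by molecular oxygen, transiently generating the superoxide
radical anion (O₂•⁻). Superoxide-containing radical pairs have repeatedly
been proposed as magnetosensors, but free superoxide tumbles in about a
picosecond, and its orbitally degenerate ground state couples spin to that
tumbling so strongly that spin coherence is destroyed long before the
geomagnetic field can act. The proposal stands or falls on whether the
protein can *bind and rotationally immobilise* the anion.

`ionbindr` implements the trajectory-analysis pipeline with which that
question is assessed from all-atom MD data, for users studying transient
anion binding to proteins generally:

- **Binding-event kinetics** — minimum ion–protein heavy-atom distance
  series (closest-atom convention for diatomic ions), binding events
  defined as runs of consecutive frames below a 4 Å cutoff (two-frame
  minimum), residence-time summaries by site and duration threshold,
  survival curves with constrained bi-exponential fits, hit rates, and
  escape-termination rules (3 Å site-local / 10 Å far-field).
- **Occupancy mapping** — Kabsch superposition, RMSD/RMSF, voxelised ion
  occupancy grids (1 Å voxels, probability-per-voxel-per-frame semantics),
  26-connected hotspot extraction with residue annotation, OpenDX export.
- **Rotational relaxation** — the P2 orientational autocorrelation
  C(τ) = ⟨P₂(û(t)·û(t+τ))⟩ of the O–O bond vector, its correlation time τ₂
  (mono-exponential fit and ACF-integral estimators), and the
  spin-rotational feasibility arithmetic: with g-anisotropy
  Δg² = Σᵢ(gᵢᵢ − gₑ)², the relaxation time is **T = 9 τ₂ / Δg²**, compared
  against the Larmor timescale τₛ = 2π / (|γₑ| B).
- **Solvation** — ion-state-resolved (bound ≤ 3 Å / bulk ≥ 10 Å) radial
  distribution functions of water, solvation-shell boundaries from g(r)
  minima, per-shell water counts and shed-water differences.
- **Synthetic ground truth** — generators for Markovian site binding with
  exponential residence times, isotropic rotational Brownian motion with
  known τ₂ = 1/(6 D_r), shell-structured pseudo-water, and decoy proteins,
  so every stage is validated by parameter recovery without MD data.

## Worked example

```r
library(ionbindr)

# Synthetic trajectory: 2 ions binding at 2 arginine-anchored sites
sites <- data.frame(site_id = 1:2, x = c(15, 45), y = 30, z = 30,
                    jitter_sigma = 0.5, k_on = 0.5, k_off = 1)
spec <- binding_kinetics_spec(sites, box = c(60, 60, 60), n_ions = 2,
                              duration = 400, dt = 0.2, seed = 42)
sim <- simulate_markov_binding(spec)

series <- min_distance_series(sim$trajectory, sim$ions[[1]])
events <- detect_binding_events(series, cutoff = 4.0)
events <- assign_site(events, sim$trajectory, sim$ions[[1]], sim$sites)
binding_time_summary(events)
#>    site total ge_1ns ge_10ns ge_100ns pct_ge_1ns pct_ge_10ns pct_ge_100ns
#> 1 site1    67     35       0        0       52.2           0            0
#> 2 site2    79     50       0        0       63.3           0            0
#> 3   all   146     85       0        0       58.2           0            0
mean_binding_time(events)
#> [1] 1.31   # ns; the exponential-rate MLE (ground truth 1/k_off = 1 ns)

# Rotational immobilisation and spin-relaxation feasibility
u <- simulate_rotational_diffusion(
  rotational_diffusion_spec(D_r = 1 / (6 * 100), dt = 1, n_steps = 2e5,
                            seed = 1))
tau2 <- estimate_tau2(p2_autocorrelation(u, max_lag = 600))$tau2  # 98.7 ps
feasibility_assessment(tau2, delta_g_squared(clcry4_reference()$g), 50e-6)
#> <spin_feasibility> tau2 = 98.7 ps, dg2 = 0.01162 -> T = 76.42 ns;
#>   B = 5e-05 T -> tau_s = 713.6 ns
#>   tau_s / T = 9.34: marginal
```

The summary table reads: each site trapped the ion 67 / 79 times; 52–63 %
of those encounters lasted at least 1 ns, none reached 10 ns. The
feasibility verdict compares spin relaxation (T) against spin precession
(τₛ): a hundredfold rotational slow-down lifts T from 0.8 ns (free
superoxide) to 76 ns, within an order of magnitude of the geomagnetic
Larmor timescale — marginal rather than hopeless.

A full pipeline (`simulate → binding → rotation → solvation → occupancy →
report`) runs from one YAML config:

```r
run_pipeline(list(seed = 3, outdir = "run1"))
```

and writes per-stage CSV/JSON/OpenDX outputs plus a `manifest.json` with a
config hash for reproducibility. A thin CLI wrapper with subcommands
(`run`, `simulate`, `analyze-binding`, `analyze-rotation`,
`analyze-solvation`, `map-occupancy`, `report`) ships in
`inst/cli/ionbindr.R`.

## File formats

**Native trajectory CSV** (plain text so fixtures diff):

| column | meaning |
|---|---|
| `frame` | 1-based frame index |
| `time_ps` | frame time (ps) |
| `atom_id` | atom id, or `0` for the per-frame box row |
| `x`, `y`, `z` | coordinates (Å), or box lengths on the box row |

**PDB** is read through `read_structure()` (ATOM/HETATM records; elements
from the element column or a leading-letter heuristic). Reports are CSV
(flat tables, 6 significant digits) or JSON (nested records, full
precision); occupancy grids are OpenDX scalar fields loadable in VMD.

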