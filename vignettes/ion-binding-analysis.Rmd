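---
title: "Transient anion binding, rotational relaxation and solvation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient anion binding, rotational relaxation and solvation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbindr)
```

`ionbindr` analyses transient binding of small anions — chiefly the
superoxide radical O₂•⁻, with chloride as the natural comparison ion — to
protein surfaces from molecular dynamics trajectories, and carries that
analysis through to the question that motivates it: can binding slow the
anion's rotational tumbling enough for a radical pair containing it to
retain spin coherence on the timescale of geomagnetic spin precession?
This vignette documents the models, the conventions, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## Binding-event model

The elementary observable is the per-frame minimum distance between any
atom of the ion and any *heavy* atom of the protein
(`min_distance_series()`). For the diatomic superoxide the distance is
taken from whichever oxygen is closer; hydrogens are excluded on the
protein side. When the trajectory carries a periodic box, distances use
the minimum-image convention by default — the source data never state
whether periodic images were folded into contact distances, so the
convention is exposed as a flag (`minimum_image`), on whenever a box is
present, and verified in tests against an explicit periodic-image search.

A **binding event** is a maximal run of consecutive frames with minimum
distance below 4 Å, lasting at least two frames (`detect_binding_events()`,
`cutoff = 4`, `min_duration = 2*dt`). Two conventions deserve explicit
statement:

- **Duration.** A run of *k* frames is reported as lasting *k·dt*, not
  (k−1)·dt: at 0.2 ns sampling the shortest admissible event spans 0.4 ns.
  This frame-count convention matches how binding-time tables in the MD
  literature on this system are tabulated, and is what the residence-time
  recovery tests assume.
- **Gaps.** A single frame above the cutoff ends the event (`gap = 0`).
  A gap tolerance is available but off by default: "consecutive frames"
  is taken literally.

Events are assigned to named binding sites (sets of residues, 3 Å bound
cutoff) by a majority-frame tally: the site whose residues' heavy atoms
are within cutoff for the largest number of event frames wins, with ties
broken by smaller mean distance (`assign_site()`). The tally rule is our
choice — nothing in the source material says how an event straddling two
sites should be attributed — and it degrades gracefully to "nearest site"
for single-frame contests.

Residence-time statistics follow the exponential unbinding picture: the
arithmetic mean of event durations is the maximum-likelihood estimate of
the inverse decay rate (`mean_binding_time()`). The survival curve
f(t) = #{t_b ≥ t}/N (`bound_fraction_curve()`) is fit with
f(t) ≈ a·exp(−t/τ_fast) + (1−a)·exp(−t/τ_slow), amplitudes constrained to
sum to one so f(0) = 1 by construction (`fit_biexponential()`). The
optimiser is Levenberg–Marquardt with box constraints (0 ≤ a ≤ 1, τ > 0),
started deterministically from a decade-spaced grid of (τ_fast, τ_slow)
pairs; the best residual wins and near-ties go to the smaller τ_slow. On a
mono-exponential input the two components legitimately collapse
(τ_fast ≈ τ_slow, or a → 0/1); the fit is then still well-defined as a
predictor even though the individual parameters are not identifiable.

Hydrogen bonds to the ion (relevant because binding is mediated by
arginine guanidino groups acting as donors) use a standard geometric
criterion: donor–acceptor distance ≤ 3.5 Å and donor–H···acceptor angle
≥ 120°, both configurable. These thresholds are the field's usual
defaults; the source material states none.

## Occupancy maps and hotspots

Trajectories are superposed by the Kabsch algorithm (SVD of the
cross-covariance with a determinant correction, so the rotation is always
proper). The alignment selection defaults to backbone heavy atoms — the
stable choice for a protein whose loops move. `occupancy_grid()` then
voxelises ion positions at 1 Å (default): a voxel's value is the fraction
of frames in which at least one ion's reference point lies inside it, i.e.
the probability the voxel contains an ion at any given frame. The
reference point of a diatomic ion is its bond midpoint (per-atom weighting
available). No Gaussian smearing is applied — the value is an honest
per-voxel probability, which is what the iso-level thresholds are read
against. Hotspots are 26-connected components above an iso-level:
diagonal-adjacent density blobs are one physical site, so vertex
connectivity is the right notion. Iso-levels are parameters, not
constants, since the informative contour depends on concentration and
sampling; values around 0.0066 and 0.015 are the working range for maps of
this kind.

## Rotational correlation and spin-rotational relaxation

τ₂ is the characteristic decay time of
C(τ) = ⟨P₂(û(t)·û(t+τ))⟩, the second-rank orientational autocorrelation of
the O–O bond vector, averaged over all time origins
(`p2_autocorrelation()`, compiled kernel). Two estimators are always
computed (`estimate_tau2()`): a mono-exponential least-squares fit
restricted to lags where C > e⁻² (the early decay, where the
single-exponential model is meaningful), and the trapezoidal integral of C
to its first zero crossing. The fit is the headline value by default; for
a genuinely mono-exponential decay the two agree, and their disagreement
is itself a useful diagnostic of non-exponential reorientation. A flat ACF
(no decay below 1/e within the window) is an error, not a number.

The feasibility arithmetic takes the g-tensor principal values as inputs
(they come from quantum chemistry, not from this package) and computes

- Δg² = Σᵢ (gᵢᵢ − gₑ)², with gₑ = 2.00231930;
- the spin-rotational relaxation time **T = 9 τ₂ / Δg²** (the relaxation
  *rate* is Δg²/(9 τ₂); this is the reading of the rate expression that is
  dimensionally consistent and reproduces the published T values, e.g.
  T = 0.8 ns at τ₂ = 1 ps with Δg² = 0.0116);
- the Larmor timescale τₛ = 2π/(|γₑ|·B), γₑ = 1.7608596×10¹¹ rad s⁻¹ T⁻¹,
  giving 713.6 ns at the geomagnetic 50 μT;
- the verdict from the ratio τₛ/T: suppressed above 10, feasible below 1,
  marginal between. The thresholds are order-of-magnitude conventions and
  configurable.

`viscosity_scaling()` applies the first-order Stokes–Einstein–Debye
projection τ₂′ = η·τ₂, t_b′ = η·t_b for a viscosity multiplier η — a
deliberately crude model for asking how the feasibility verdict shifts in
a crowded cellular environment, and documented as such.

## Solvation analysis

Frames are classified by the ion–protein distance: bound at ≤ 3 Å, bulk at
≥ 10 Å, intermediate otherwise and excluded from both state-resolved
averages. `rdf_profile()` is the standard pair-distribution estimator —
distance histogram normalised by 4πr²Δr and a reference density — with the
closest-oxygen convention for the diatomic ion, mirroring the contact
analysis (midpoint available as a flag). The cumulative count n(r) is the
running per-frame total of histogram counts, so n(r_max) equals the mean
number of waters within r_max exactly; integrating ρ·g·4πr²dr would give
the identical number by construction and the direct sum avoids quadrature
error. The reference density defaults to the measured density of the
supplied data (box volume when a box is given, the r_max sphere
otherwise), because the appropriate normalisation density of a simulation
box is a property of that box; a textbook value (0.0334 Å⁻³) can be passed
explicitly.

Shell boundaries are local minima of g(r) after moving-average smoothing
(default window 5 bins of 0.05 Å — enough to suppress bin noise while
resolving first-shell minima near 2.5 Å), plateau-aware so a flat valley
yields its midpoint. Per-shell water counts difference n(r) at the
boundaries; the shed-water number is the bulk-minus-bound difference,
reported at one decimal as such tables are printed.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

- `simulate_markov_binding()`: each ion is an independent
  continuous-time Markov chain (free ↔ each site), discretised at the
  frame interval with per-step probabilities 1 − exp(−k·dt), simulated by
  geometric run lengths (statistically identical to stepping the chain,
  and fast). Residence times are exponential with mean 1/k_off. Bound ions
  sit at the site centre plus isotropic Gaussian jitter (σ = 0.5 Å
  default); free ions are placed uniformly outside 6 Å exclusion spheres,
  so the 4 Å / 3 Å geometric criteria recover the latent state exactly.
  dt defaults to 0.2 ns, the coarse sampling of the long production runs
  this mimics. Per-ion random substreams derive from the global seed, so
  adding an ion never perturbs existing ones.
- `simulate_rotational_diffusion()`: isotropic rotational Brownian motion.
  Each step rotates the vector about a random perpendicular axis by a
  Gaussian angle of variance **4 D_r dt**. The factor is 4, not 2: a
  single-axis step must carry both perpendicular diffusive degrees of
  freedom (2 D_r dt each) for the second-rank correlation to decay as
  exp(−6 D_r t) and hence τ₂ = 1/(6 D_r); with variance 2 D_r dt the decay
  would be exp(−3 D_r t) and every recovery test would be off by a factor
  of two. The step must satisfy D_r·dt < 0.01 rad².
- `generate_solvation_points()`: homogeneous Poisson bulk (excluded core
  r < 1.5 Å, the ion's hard sphere) plus Gaussian radial shells with exact
  per-shell counts.
- `generate_decoy_protein()`: one Cα pseudo-atom per residue on a
  Fibonacci sphere, designated residues labelled ARG and returned as site
  anchors.

What the generators deliberately do *not* emulate: force-field energetics,
water dynamics, correlated ion motion, conformational change of the
protein, or non-exponential unbinding. Passing the recovery tests
therefore demonstrates that the *estimators* are correct under their own
model assumptions — unbiased residence times, τ₂ within 10% at 10⁶ steps,
shell counts to the generator's ground truth — not that real MD data obey
those assumptions.

## Numerical choices and degenerate inputs

Problem sizes in the default test and acceptance runs were chosen so the
statistical tolerances are comfortably resolved: ≥ 2000 binding events for
the 5% residence-time check (four ions, 1200–1500 ns at 0.01 ns frames),
10⁶ steps for the 10% τ₂ check, 40–150 independent frames for RDF
recovery. Degenerate inputs fail loudly rather than silently: collinear
Kabsch selections, non-uniform frame spacing, flat ACFs, monotone g(r),
empty event lists where a mean is requested, transition probabilities
above one per step. Exact mono-exponential ACFs are handled by the
log-linear fit when the nonlinear optimiser (rightly) rejects a
zero-residual problem.

## Limitations

Binding-site assignment assumes sites are defined a priori (from hotspot
maps or prior knowledge); no clustering of events into de-novo sites is
attempted. The bi-exponential fit reports amplitudes and time constants
without confidence intervals. The spin model is the isotropic
spin-rotational mechanism only — no dipolar coupling, no explicit
singlet–triplet dynamics, no multi-radical effects; the verdict is a
timescale comparison, not a yield calculation. The viscosity projection is
linear. The trajectory reader targets the package's plain-text format and
PDB; binary MD formats are expected to be converted upstream (the reader
contract is deliberately format-agnostic so adapters can be added behind
it).
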