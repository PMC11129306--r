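---
title: "Thickness-gradient membranes and mismatch-driven peptide sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thickness-gradient membranes and mismatch-driven peptide sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memgrad)
library(dplyr)
```

## The problem

Hydrophobic mismatch — the difference between the hydrophobic length of a
transmembrane (TM) helix and the hydrophobic thickness of its host bilayer —
carries an energetic penalty, and membranes of different organelles differ in
thickness. A membrane built with a *lateral thickness gradient* turns this
penalty into a position-dependent force: a peptide diffusing along the
gradient axis experiences a restoring drift toward the position where its
mismatch vanishes, and its lateral position becomes a thickness reaction
coordinate. `memgrad` implements the full desk-scale toolkit around this
idea: blueprint construction for gradient membranes, a stochastic surrogate
of the sorting dynamics, estimators for thickness and peptide-orientation
observables, relaxation and diffusion kinetics, and umbrella-sampling free
energy machinery.

Throughout the package, lengths are nm, times ns, energies kJ/mol, and free
energies are reported in units of thermal energy `kBT()` (2.494 kJ/mol at the
default 300 K). The gradient runs along x, the membrane normal is z, and
intervals are half-open `[lo, hi)`.

## Gradient blueprints

A blueprint is an ordered set of lipid patches. Each lipid type anchors the
thickness of its pure patch at the thickness of the corresponding
single-component membrane; adjacent patches share an overlap region where
lipids mix. `layout_patches()` orders the lipids thin-to-thick along +x and
assigns equal-width pure intervals after subtracting the requested overlaps.
The expected thickness profile (`predict_thickness_profile()`) is the
simplest model consistent with a smooth realized gradient: constant in pure
patches and linear across each overlap.

```{r blueprint}
lip <- lipid_specs(c("DYPC", "DOPC", "DGPC", "DNPC"),
                   c(3.34, 4.11, 4.56, 4.95))
lay <- optimize_overlap(lip, box_length_x = 40,
                        target = thickness_target(0.05, c(8, 32)),
                        candidate_overlaps = seq(0, 10, by = 1))
attr(lay, "objective")
fit <- fit_linear_region(predict_thickness_profile(lay, 0.25), c(8, 32))
glance(fit)
```

Two honest caveats about this model. First, the blueprint profile can never
leave the interval spanned by the anchor thicknesses, so with these four
anchors (3.34–4.95 nm) the *model* gradient over a 24 nm linear region tops
out near 0.05 nm/nm; realized coarse-grained gradients are steeper (around
0.077 nm/nm, a maximum difference of ≈ 1.85 nm over 24 nm) because the
assembled membrane's thin end thins and thick end thickens beyond the pure
anchors. The blueprint is the design tool; `fit_linear_region()` on a
*measured* profile is what quantifies the realized gradient. Second, larger
overlaps always smooth the model profile (the objective above decreases
monotonically in the candidate width), but in a real membrane wide mixed
regions cost lipid demixing entropy and show boundary biases, so the
candidate list should stop where the practitioner's patience with mixing
does.

The overlap width is *optimized*, not prescribed: for each candidate width
the predicted profile is scored by its maximum absolute deviation from the
best-fit line over the linear region, and the flattest-residual candidate
wins (ties toward smaller overlap, which mixes fewer lipids). The criterion
is deliberately a max-deviation rather than an RMS: a single kink in the
gradient produces a localized force artifact on a sorting peptide, so the
worst point, not the average, is what matters.

Each lipid type is confined to its interval by a flat-bottom positional
restraint: zero potential inside the interval (pure patch plus shared
overlaps), a harmonic wall `0.5 k (excess)^2` outside. The wall stiffness
default of 1000 kJ mol⁻¹ nm⁻² makes thermal excursions beyond ~0.1 nm past
the wall negligible at 300 K while remaining soft enough for stable MD
integration. `write_flat_bottom_restraints()` serializes these records in a
GROMACS-style include dialect; the format round-trips losslessly and is
bit-stable, so blueprints can be diffed.

## The sorting surrogate

The package's stochastic model of sorting is an overdamped Langevin equation
for the peptide centre of mass along the gradient,

$$\mathrm{d}x = -\frac{x - x_\mathrm{eq}}{\tau}\,\mathrm{d}t +
  \sqrt{2D}\,\mathrm{d}W,$$

an Ornstein–Uhlenbeck (OU) process. The linear drift encodes the empirical
observation that sorting velocity is proportional to the distance from the
equilibrium position — equivalently, in an overdamped medium, that the
mismatch force is harmonic. The closed forms (mean relaxation
`x_eq + (x0 - x_eq) e^{-t/\tau}`, stationary variance `D·τ`) make every
downstream estimator testable against ground truth.

Integration is Euler–Maruyama with fixed `dt` (default `τ/100`); for an OU
process this is accurate to `O(dt/τ)` in the relaxation constant, which at
the default is a 0.5% bias — far below sampling error at any realistic
replica count. A `dt ≥ τ/10` warns; `dt ≥ τ` errors. An umbrella bias
`0.5 k_b (x - x_c)^2` adds drift `-(k_b/γ)(x - x_c)` with the mobility fixed
by fluctuation–dissipation, `γ = kBT/D`, so biased runs have a well-defined
temperature.

```{r surrogate}
p <- sorting_params(x_eq = 20, tau = 2800, diffusion = 0.002, x0 = 28,
                    n_steps = 1000, n_replicas = 100, seed = 1)
mp <- ensemble_mean_path(simulate_sorting_ensemble(p))
glance(fit_relaxation(mp$time, mp$mean_x))
```

A caution that matters for interpreting recovery experiments: with the
literature-scale parameters `τ = 2800` ns and lateral `D = 0.02` nm²/ns, the
OU stationary variance is `D·τ = 56` nm² — a per-replica spread comparable to
the 8 nm relaxation amplitude itself. A 100-replica ensemble mean then
carries ~0.75 nm of noise with correlation time τ, and the fitted τ
fluctuates by ~20% between realizations while the mean-path R² sits around
0.85–0.95. Real coarse-grained sorting dynamics fluctuate far less in x
(the thermal width of the mismatch well is a few tenths of a nm), so the
combination of a microsecond relaxation constant with free-diffusion-scale
noise is pessimistic: treat τ and D as independent dials, and recovery
precision as a function of `sqrt(D·τ)/A`. The chunk above uses `D = 0.002`
to illustrate the estimator in a well-conditioned regime.

`synthesize_membrane_trajectory()` generates the bead-level counterpart:
phosphate markers at `z = ±d(x)/2` plus Gaussian placement noise, and a
rigid-rod peptide whose tilt and azimuth are drawn independently per frame
from user-supplied samplers. Independence across frames is a deliberate
simplification — the analyses here consume marginal distributions only, so
orientational autocorrelation would add cost without adding test power. The
generator does *not* emulate lipid packing, acyl-chain conformations,
membrane undulations, or peptide flexibility; green tests on synthetic
frames therefore validate the estimators' correctness, not their robustness
to CG artifacts such as undulation broadening of the apparent thickness.

## Thickness estimation

Thickness is the interleaflet phosphate distance: per x-bin (or per
peptide-centred (x, y) cell), the mean upper-leaflet z minus the mean
lower-leaflet z, pooled over frames. Defaults — 0.5 nm bins, `min_count` 10
per leaflet — resolve a 0.077 nm/nm gradient with sub-0.05 nm error at
typical bead densities; bins failing `min_count` are reported `NA` and
propagate, never silently imputed. The leaflet-mean estimator (rather than
nearest-neighbour phosphate pairing) is robust at coarse-grained densities
and is unbiased under symmetric placement noise.

Peptide-centred maps (`thickness_map_2d()`) rebin beads relative to the
peptide's in-plane centre of mass (minimum image in y; x is not wrapped
inside the linear region) and also accumulate the unperturbed reference
field at the beads' absolute positions, so `thickness - reference` isolates
the peptide-induced perturbation. `perturbation_at_peptide()` averages the
central 3×3 cells (1.5 × 1.5 nm at the default cell size) — small enough to
stay inside a typical perturbation footprint, large enough to keep counting
noise at the few-hundredths-of-a-nm level. The neighbourhood half-width is
an argument; note that a perturbation narrower than the neighbourhood is
attenuated by the averaging.

## Orientation observables

The peptide axis is the principal axis of the backbone bead coordinates
(largest singular vector), not the termini vector — for a coarse-grained
helix the principal axis is insensitive to end-bead noise. Tilt θ is folded
to [0°, 90°] (the axis sign is physically meaningless), azimuth φ is
measured from the gradient axis in [0°, 360°) with the axis oriented toward
+z, and φ is `NaN` for an exactly untilted rod. The projected length is
`l_proj = l_TM cos θ` with `l_TM = 0.15 nm` per leucine for the polyleucine
reference peptides (`polyleucine_table()`).

Mismatch is reported as `l_mis = l_proj - d`: negative when the peptide is
shorter than its local membrane. The opposite convention (`d - l_proj`)
is selectable by flag; the default was chosen to agree with the signs in
the reference table, whose seven peptides all carry ≈ −1 nm of realized
mismatch at equilibrium.

Tilt histograms are raw marginal densities by default — no division by the
sin θ solid-angle Jacobian — matching how tilt distributions are usually
presented in this literature; `jacobian = TRUE` gives the corrected
profile. Equilibrium statistics use the last half of the trajectory by
default, the standard discard-the-transient convention. The azimuth
uniformity check is a one-sample Kolmogorov–Smirnov test of φ/360 against
the standard uniform; its type-I error calibration is part of the test
suite (1000 null replicates, 3σ binomial band around 5%).

## Kinetics

`fit_relaxation()` fits `x(t) = x0 - A(1 - e^{-t/τ})` by Levenberg–Marquardt
with documented initialisation (`x0` = first point, `A` = first − last, τ =
time to cover half of A); the fit is exactly equivariant under time
rescaling, and `A` changes sign for relaxation from below without changing
τ — the mismatch force is symmetric around zero. R² is computed on the
ensemble-mean curve, not per replica: the mean path is what the exponential
model describes. Non-convergence raises a classed error carrying the
starting values; there are no silent fallbacks.

`estimate_diffusion()` computes MSD with overlapping time origins, capped at
a maximum lag of 10% of the trajectory to bound the correlation between
origin pairs, and takes `D = slope/(2·dim)` over a fit window defaulting to
the first half of available lags. Wrapped coordinates (single-step jumps
exceeding half a box length) are detected and rejected rather than silently
producing a near-zero D.

## Free energies

`boltzmann_invert_density()` is the elementary `-ln(ρ/ρ_max)`.
`wham_1d()` implements the standard weighted-histogram self-consistent
iteration over umbrella windows, converging the per-window free-energy
constants to 1e-8 kBT (cap 1e5 iterations); with a single unbiased window it
reduces *exactly* to Boltzmann inversion, which the test suite asserts, and
on biased-OU synthetic windows it recovers the known quadratic well to
better than 0.2 kBT. Adjacent windows with no shared histogram support are
an error (the gap is reported); overlap below 5% warns. The reweighting
estimator is the package's own choice — standard WHAM, the field's default
when a protocol specifies only "umbrella sampling"; the umbrella bias
stiffness and spacing are likewise free parameters, not claimed to match
any particular study.

Per-window tilt free energies are `-kBT ln(P(θ)/P(θ₀))` with θ₀ the modal
bin, zero there by construction. The 2D surface is the *additive*
composition `ΔF(d, θ) ≈ ΔF(d) + ΔF(θ | window at d)` — an approximation
that neglects d–θ correlation within a window — with window positions
carried from x into thickness through the monotone linear map fitted on the
gradient's linear region (`thickness_mapping()`). The composed surface is
re-referenced to a zero minimum and masked above 10 kBT.

Accessible regions at 1, 2, 5 and 10 kBT are the 4-connected components of
`{ΔF ≤ threshold}`, each projected onto d and θ at bin-edge resolution;
disjoint minima yield multiple intervals per threshold, and components are
ordered by their minimum free energy so the first always contains the global
minimum. For a quadratic well `0.5 κ_d (d - d^*)^2` the 1 kBT interval width
is the closed form `2\sqrt{2/κ_d}`, the primary oracle for this extraction.

```{r regions}
surf <- tidyr::expand_grid(d = seq(3.6, 4.4, 0.005), theta = seq(0, 50, 0.5))
surf$delta_F <- 0.5 * 200 * (surf$d - 4)^2 + 0.5 * 0.02 * (surf$theta - 25)^2
format_accessible_regions(accessible_regions(surf))
```

## Numerical choices and problem sizes

The package's tests and worked examples run on deliberately small problems:
synthetic membranes of a few thousand beads over ≤ 10 frames, OU ensembles
of 100 replicas × 1000 steps, umbrella sets of 5 windows × ~300k samples,
and 2×10⁵-draw tilt ensembles. These sizes were chosen so that Monte-Carlo
error sits comfortably below each assertion's tolerance while the whole
suite completes in about a minute; all estimators are plain vectorised R
and scale linearly if pushed to production-size trajectories.

Tie-breaking and degenerate-input rules, collected: overlap optimization
breaks ties toward smaller overlap; the tilt mode takes the first maximal
histogram bin; untilted rods report `NaN` azimuth with θ = 0; zero-density
and under-counted bins are `NA` everywhere; masking at 10 kBT can never
remove a surface's minimum (it is 0 by construction).

## Known limitations

* The surrogate's single-τ OU drift is the simplest model consistent with
  velocity ∝ mismatch; it cannot express position-dependent mobility or
  anharmonic wells, and parameter recovery degrades sharply when
  `sqrt(D·τ)` approaches the relaxation amplitude (see the caution above).
* The additive 2D surface inherits the missing d–θ coupling; a joint 2D
  reweighting is out of scope.
* Thickness estimators assume the phosphate planes are well separated;
  membranes near rupture or with interdigitation would need a density-based
  definition.
* The blueprint's piecewise-linear thickness model idealizes overlap mixing;
  real mixed patches can show a small repulsive bias at patch boundaries
  that the blueprint does not model.
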