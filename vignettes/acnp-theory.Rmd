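---
title: "A molecular theory of antigen capture on crowded nanoparticle surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A molecular theory of antigen capture on crowded nanoparticle surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acnp)
```

## The physical problem

An antibody-conjugated nanoparticle (AcNP) captures antigen from solution
with an effective affinity that depends strongly on how densely the surface
is decorated. Antibodies are large (an IgG is roughly 150 nm^3 of protein),
and each bound antigen adds more volume; on a crowded surface the entropic
cost of accommodating those volumes competes with the chemical free energy
of binding. The package computes that competition explicitly for a
spherical particle, for two conjugation chemistries:

* **covalent**: a fixed number of antibodies is permanently grafted
  (optionally through a flexible spacer); only the antigens exchange with
  solution;
* **streptavidin–biotin**: the surface carries punctual streptavidin sites
  of zero volume, and every biotinylated solution species (free antibody,
  1-antigen and 2-antigen complex) adsorbs reversibly; sites may remain
  empty.

## Molecular model

Every molecule is a rigid set of beads of diameter 0.6 nm, one per residue
(or per ethylene-glycol monomer of the spacer). For user-supplied PDB
structures, `read_alpha_carbon_beads()` places one bead on each residue's
alpha carbon. The built-in stand-ins are deterministic: `toy_igg()` builds
a three-lobe Y of ~1320 beads (the molecular volume and ~12 nm span of an
IgG), `toy_globule(480)` a compact antigen of gp120-like volume, and
`toy_antibody()` / `toy_antigen()` are small stick-and-cluster models used
in fast unit tests. The toy bound pose extends the antigen outward from
the Fab tip along the arm axis; with crystallographic input the pose comes
from the complex structure itself.

The spacer is a rotational-isomeric-state (RIS) chain: fixed 0.6 nm bonds
(tangent beads; the monomer bond length is not an observable of the theory
and is configurable), tetrahedral valence angle, dihedrals drawn from
trans/gauche+/gauche- with equal weights by default (the observables here
are dominated by excluded volume, not torsional energetics; the weights
are parameters). Chains with hard-sphere overlaps between beads separated
by two or more bonds are rejected. With bond length equal to the bead
diameter even the gauche+/gauche- pair is sterically clean (1–5 distance
0.98 nm), so rejection rates stay modest.

Tethered-species ensembles are assembled by joining the rigid body to the
spacer free end through a ball joint (one bond length, random direction),
rotating it uniformly (quaternion sampling), rejecting conformations that
penetrate the particle, and reducing each survivor to its per-shell
occupied volume. The whole bead volume is assigned to the shell containing
the bead center: with the default shell thickness (0.5 nm) comparable to
the bead diameter, exact spherical-cap splitting would change profiles by
less than the conformer-sampling noise, while the center rule conserves
volume exactly — which the tests assert to 1e-9.

## Free energy and its minimization

With species i ∈ {A, Aa, Aaa} bound to N_s surface sites (plus empty sites
S in the streptavidin scheme), conformers α with probabilities P_i(α), and
solution species j ∈ {a, A, Aa, Aaa} plus water w, the free energy per
particle collects the water translational entropy, the solution species'
translational entropy and self-energy, the bound species' conformational
entropy, and the surface mixing entropy and self-energies. All attractions
are folded into dissociation constants; the only repulsion is excluded
volume, enforced as *local incompressibility*: in every radial shell the
volume fractions sum to one.

Minimizing with a Lagrange-multiplier field — the local osmotic pressure
βπ(r) — gives closed forms in terms of that single field:

* conformer weights `exp(-Σ_r βπ(r) v(α; r))` and partition functions
  `q_i` (prior-weighted ensemble averages, computed by log-sum-exp so
  deeply crowded states cannot underflow);
* surface fractions by mass action: covalently,
  `f_A : f_Aa : f_Aaa = q_A : q_Aa g(c_a/Kd) : q_Aaa g(c_a/Kd) · c_a/(g Kd ρ_av)`
  with the statistical factor g = 2 for two equivalent Fab sites and the
  avidity ratio ρ_av = Kd2/Kd1 weakening the second ligation; for
  streptavidin, `f_j/f_S = q_j c_j / Kd_biotin` over the pre-equilibrated
  solution concentrations. One convention is used consistently on the
  surface and in solution (the second ligation carries the compensating
  1/g), so the two equilibria are thermodynamically coherent;
* dilute solution species depleted as `ρ_j(r) = ρ_j^bulk exp(-βπ(r) v_j)`
  through their total molecular volume in their own shell. At the pM–nM
  concentrations of interest the solutes' volume fractions are ~1e-7, so a
  radially smeared footprint would change nothing measurable; the local
  form keeps the packing equation separable per shell;
* water `ρ_w(r) v_w = ρ_w^bulk v_w exp(-βπ(r) v_w)` with
  v_w = 0.03 nm^3, the conventional solvent site volume for aqueous
  mean-field theories.

The solver iterates: from the field compute P, f and the bound volume
profile; solve each shell's packing equation exactly for the field that
would fill it (guarded Newton from a water-dominated closed form); mix
with Anderson acceleration (history 5, adaptive damping); if acceleration
stalls, switch to a damped Newton iteration on the full residual with a
forward-difference Jacobian. Convergence is a max-norm packing residual
below 1e-8; probability and fraction normalizations hold to 1e-12 by
construction and are asserted on every converged state.

The reported free energy is the excess semi-grand potential relative to
the uniform bulk (zero for a bare particle in pure solvent): the bound
species' conformational entropy appears as the Kullback–Leibler divergence
of P from the sampling prior, the mixing term carries the effective
binding constants (standard state 1 M), and the solvent contribution is
the per-shell osmotic insertion work obtained by eliminating water and
solutes at fixed chemical potential.

**Why the solution is trustworthy.** In joint occupancy coordinates
`y[i, α] = f_i P_i(α)` the functional is convex: entropy becomes
`Σ y ln y` plus linear terms, the bound volume profile is linear in y, and
the per-shell solvent work is convex and increasing. `brute_force_minimum()`
exploits this: it enumerates the occupancy simplex exhaustively at step
0.1 and refines by pairwise-exchange pattern search with halved steps —
sound for a convex objective — solving the packing equation by bisection.
It shares no numerics with the field solver beyond the functional itself,
and the two agree to a relative 1e-6 over randomized tiny systems.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `kd` | 1e-9 M | per-site antibody–antigen dissociation constant (typical high-affinity range 1e-8–1e-11 M) |
| `avidity_ratio` | 100 | Kd2/Kd1 of the second ligation; >1 means the second antigen binds more weakly. Not directly measurable from the model inputs; treat as a required experimental input |
| `kd_biotin` | 1e-14 M | streptavidin–biotin dissociation constant |
| `g_stat` | 2 | two-equivalent-site statistical factors; 1 disables them |
| `r_np` | 50 nm | particle radius |
| `spacer` | 50 | spacer monomers (0.6 nm beads); 0 = direct anchoring |
| `dr` | 0.5 nm | radial shell thickness |
| `r_max_offset` | 60 nm | grid extent beyond the surface; the field decays to <1e-8 well inside it, and doubling the box moves captured antigen by <0.1% |
| coverage σ | 1e-4–1e-2 /nm² | antibodies (or sites) per nm²; N_s = σ·4πR² |

Bulk conditions mirror the two regimes of interest: serum-like 20 pM
antigen, and an in-vitro 100 nM antigen (covalent) or a 200 nM antigen /
100 nM antibody mixture (streptavidin, split into species by
`solve_bulk_equilibrium()`, a safeguarded 1-D root-find on free antigen
whose mass balances close to 1e-10).

## Sampling design

Conformational ensembles are Monte Carlo samples, and two features keep
the self-consistent solutions stable:

* **Common random numbers.** The unbound antibody and both complexes are
  assembled from the same spacer chains, rigid rotations and joint
  directions, so the sampling noise of rare conformations largely cancels
  in the partition-function ratios that set the surface fractions.
* **Stratified stretch sampling.** Crowded layers are dominated by
  strongly stretched spacers whose probability under plain RIS sampling is
  exponentially small. `spacer_conformations()` therefore samples several
  strata with the trans state up-weighted (default bias 1, 4, 16, 64) and
  attaches to every chain the exact log importance weight of the target
  RIS statistics; partition functions, free energies and the oracle all
  honor these priors, so the estimator stays unbiased while the stretched
  tail is densely populated.

The default sweeps use ~2000–6000 conformations per species. The regime a
sample of size n resolves is bounded by its entropy, ln n: once the
osmotic field demands conformations rarer than ~e^(-ln n), the probability
collapses onto a handful of sampled chains and observables become
sample-dependent. For the toy system this bounds the trustworthy window to
coverages up to a few 1e-3 /nm² at 100 nM and Kd = 1e-9; tests and the
acceptance script stay inside it, and the affinity contrast that can be
resolved between two Kd values is likewise bounded by ln n.

## What the toy system does and does not show

The built-in structures reproduce the volumes that drive crowding, and the
solved equilibria show the expected phenomenology: capture per antibody
falls with coverage; the two-antigen complex, the bulkiest species,
vanishes beyond a finite number of antibodies while unbound antibodies
accumulate; the bound complexes undergo a collapsed-to-stretched
transition (visible as a jump in their mean center-of-mass radius) while
unbound antibodies stay collapsed; a spacer increases capture; small
particles bind almost linearly in coverage and are more efficient per unit
area; and the streptavidin surface self-limits — the antibody load
plateaus with site coverage, almost independently of bulk concentration,
with most sites left empty despite the femtomolar biotin affinity, and
capture stays near one antigen per bound antibody.

One feature of the real system is *not* robust in the toy: an interior
maximum of total captured antigen versus coverage in the covalent scheme
at high antigen concentration. With the toy pose the bound antigen extends
outward from the Fab tip, so a complex on a stretched spacer can always
carry its antigen to the uncrowded outer frontier of the layer; the
marginal cost of binding then grows too slowly for the total capture to
turn over within the physically sensible coverage window (verified across
seeds, sample sizes up to 2.4e4, and alternative poses). Whether a real
antibody–antigen pair shows the turnover depends on the coarse-grained
geometry of the complex — which is exactly why the package accepts
crystallographic structures as input.

## Numerical corner cases

* Zero concentrations are exact: terms with zero density contribute zero
  (no log-of-zero paths), `c_a = 0` gives pure unbound surfaces, an empty
  biotinylated mixture returns all-empty sites with a warning.
* `avidity_ratio = Inf` switches the second ligation off exactly.
* N_s = 0 in pure solvent converges in one iteration to a zero field and
  zero excess free energy.
* Binding-maximum location uses parabolic interpolation through the three
  points bracketing the discrete argmax; boundary maxima are flagged
  rather than interpolated, and ties break toward the lowest coverage.
* All sampling is seeded; identical inputs give bit-identical ensembles,
  curves and output files.

## Limitations

Equilibrium only (no kinetics); no electrostatics, van der Waals
attractions, pH or charge regulation — every attraction lives inside a
dissociation constant; the antibody is rigid; antibody–spacer and
antigen–antibody overlaps within one molecule are not re-checked (the
mean field handles intermolecular packing); monodisperse particles; the
avidity ratio must be supplied, not predicted.
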