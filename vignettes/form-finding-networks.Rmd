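---
title: "Form-finding models of cross-linked actin networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form-finding models of cross-linked actin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actinform)
```

## The model

The actin cytoskeleton is a random network of semiflexible filaments tied
together by cross-linking proteins such as filamin.  `actinform` builds a
two-dimensional structural model of such a network and measures its
effective elasticity:

1. **Generation.** Straight filaments are placed sequentially on a
   rectangular domain (default 10 µm × 10 µm × 1 µm).  Each filament draws
   its length from a truncated Gaussian (default 5 ± 2 µm; non-positive
   draws, and draws too long to fit the domain, are rejected), its centroid
   uniformly over the domain, and its orientation uniformly on [0, 2π).  A
   filament protruding past an edge is rigidly translated inside by the
   minimal axis-aligned shift, which preserves its length and angle.
   Placement stops when the filament volume fraction (cylinders of 7 nm
   diameter per unit domain volume) first reaches the target relative
   density (default 0.2%); the filament that crosses the threshold is kept.
2. **Binding sites.** Each filament is divided into segments of
   0.3 ± 0.06 µm (truncated Gaussian; a final remainder shorter than half
   the mean merges into the previous segment so no sliver elements arise).
   Segment ends, including the filament tips, are nodes of the finite
   element mesh and binding sites for cross-linkers.
3. **Cross-linking.** Candidate connections are all pairs of binding sites
   on distinct filaments separated by strictly less than 0.3 µm and
   strictly more than `min_crosslinker_length` (default 0.05 µm — a
   cross-linking protein has a finite physical size, and the translation
   rule otherwise stacks coincident endpoints in domain corners).  Each
   binding site hosts at most one cross-linker (`site_capacity = 1`);
   available pairs bind closest-first.  This matching keeps individual
   filaments at realistic connection counts — a 0.6 µm filament ends up
   with one or two cross-linkers, a 6 µm filament with ten or more —
   whereas connecting *every* candidate pair (available via
   `site_capacity = Inf`) gives tens of connections per site and an
   affinely deforming truss two orders of magnitude stiffer.  A
   `crosslink_fraction` below one then keeps each cross-linker
   independently at random, emulating reduced cross-linker expression.
4. **Form-finding.** Cross-linkers are cables with a tensile pre-stress
   (default 3 pN, about 5% of the 60 pN cross-linker yield force), and the
   network is solved to its stable self-equilibrated configuration.
5. **Stretching.** The form-found network is extended uniaxially under
   displacement control and the effective Young's modulus is read off as
   `E = (σx² − σy²)/(σx εx − σy εy)`, which reduces to `σx/εx` because the
   lateral edges are traction-free (σy = 0).  `σx` is the summed reaction
   on the displaced edge over the undeformed domain cross-section
   (10 µm × 1 µm), so with the internal µm–nN unit system stresses are
   natively in kPa.

Monte-Carlo drivers (`run_ensemble()`) repeat the pipeline over seeded
realisations and sweep density, filament length, cross-linker fraction,
domain size, or pre-stress.

## Elements and materials

Filament segments are two-node corotational Euler–Bernoulli beams (three
degrees of freedom per node: two translations and a rotation).  The
corotational decomposition removes the rigid chord motion; the local law is
linear: `N = EA (l − l₀)/l₀`, end moments from the standard 4-2-2-4
bending stiffness.  With E = 1.4 GPa and d = 7 nm, `EA = 53.88 nN` and
`EI = 1.65·10⁻⁴ nN µm²`; the slenderness d/l ≈ 0.007/0.3 makes the
small-strain/large-rotation corotational formulation the natural choice.
Yield forces (0.25 nN for filaments, 60 pN for cross-linkers) are used for
exceedance *flagging* only — the analysis stays elastic.

Cross-linkers are tension-only cables on the translational DOF.  Two laws
are implemented:

* **elastic** (default): `T = max(0, P + k (l − l₀)/l₀)` with the
  pre-stress offset `P` and an axial stiffness `k` (default 0.6 nN per
  unit strain, which reaches the 60 pN yield force at 10% strain — the
  stiffness of the cross-linker during stretching is not an experimentally
  pinned quantity, so it is exposed in `material_table()` and
  `prestress_sensitivity()` quantifies its influence);
* **constant_force**: `T = P` at any length (smoothly regularised to zero
  below 5 nm separation so a fully reeled-in cable reaches an equilibrium
  instead of a singularity).

Form-finding defaults to the elastic law with the pre-stress *offset* held
constant: each cable relaxes after shortening by about `P l₀/k` (~1 nm),
giving a mildly rearranged self-equilibrated state in which tensions sit
at or below the pre-stress.  Under the literal constant-total-force
reading the cable web never relaxes and reels the network into a large
collapse; that behaviour remains available (`cable_mode =
"constant_force"`) and is exercised on small networks in the test suite,
but as the default it contradicts the mild rearrangement, the weak
pre-stress sensitivity, and the ensemble sizes that motivated this model
class.  The tension-only hinge of the elastic law is C¹-smoothed over a
band of 0.5 P (tension error at most 0.75 pN, confined to near-slack
cables) because Newton iterations otherwise chatter on the slack set.

## Boundary conditions

Form-finding pins, per connected component, both translations of the node
nearest the component centroid and, at the farthest node, the translation
most perpendicular to the line joining the two (robust when a component is
one straight filament).  Tiny anchor springs (10⁻⁶ nN/µm translations,
10⁻⁸ nN µm rotations, anchored at the stage-start configuration) suppress
floating mechanisms; at the default pre-stress they carry forces about
10⁴ times smaller than the cable forces.

Stretching fixes `u_x` of all nodes whose *reference* x-coordinate lies
within 2% of the domain width of the left edge, prescribes `u_x` on the
right-edge band to the target strain times the domain width, and leaves
`u_y` and rotations free everywhere (the σy = 0 plane-stress condition);
one left-band node is pinned in y and carries no load at equilibrium
because the net lateral force vanishes.  Homogenisation is over the whole
domain only.

## The nonlinear solver

Equilibria solve `r(q) = 0` by damped Newton iteration with sparse
Cholesky factorisation.  Numerical choices that matter:

* **Ordering.**  The coupling graph is geometric (chains plus sub-0.3 µm
  cross-links), and generic fill-reducing orderings fill catastrophically
  on it; the package computes its own nested-dissection ordering by
  recursive coordinate bisection with separators taken from the endpoints
  of cut-crossing edges, and hands CHOLMOD the permuted matrix.
* **Stabilised tangent.**  The matrix actually factorised omits the
  sign-indefinite geometric terms (compressive softening and the
  moment–chord coupling), making it positive definite by construction;
  the residual stays exact, so converged equilibria are unchanged and only
  the iteration path is that of a modified Newton method.  Verification
  solves (`tangent_update = "every_iteration"`) use the exact consistent
  tangent and show the quadratic tail.
* **Globalisation.**  Steps are clipped componentwise to `max_step`
  (0.5 µm/rad), accepted by an Armijo test on the total potential (the
  system is conservative) while its predicted decrease is representable in
  double precision and by residual decrease below that; Levenberg damping
  proportional to |diag| escalates on failures and decays on clean steps.
  Load is applied incrementally with a secant predictor between
  increments, and the stretch stages are seeded with the affine
  displacement field of a uniform extension.
* **Tolerance.**  Convergence is declared at a residual norm below
  `rtol` (default 2·10⁻³) times the larger of the peak element force and
  the increment's driving residual.  Networks in the study regime contain
  filaments held by only one or two near-slack cross-linkers; these sit on
  the boundary of the tension-only contact set, are marginally
  constrained, and pin the attainable residual at a small multiple of the
  tolerance.  When progress stalls inside ten times the tolerance (thirty
  times after a failed line search or an exhausted iteration budget), the
  state is accepted and flagged (`state$stalled`).  The positions of those
  marginal filaments are therefore determined only to ~0.1 µm; network
  observables — reactions, modulus, orientation statistics — are affected
  at the fraction-of-a-percent level, far below the ensemble spread.
* **Form-finding ramps** the pre-stress over the increments in
  constant-force mode (continuation); the elastic mode needs no ramp.
  Large solves in constant-force mode use matrix-free conjugate gradients
  preconditioned by the beams-plus-cable-diagonal matrix, whose chain
  structure factors in linear time.

## What the generator does and does not emulate

The generator reproduces the stated construction: uniformly random
Mikado-style filament placement at a prescribed volume fraction, periodic
binding sites, proximity cross-linking, pre-stressed cross-linkers.  It
does not model filament polymerisation dynamics, bundle formation,
cross-linker binding kinetics, viscoelasticity, three-dimensional
arrangement, or the biological feedback that can produce perpendicular
re-orientation under cyclic stretch.  Passing tests therefore say that the
*mechanical* pipeline is faithful to the stated construction, not that the
construction captures those features of living networks.

## Reproduction of the reference statistics

The package's own ensembles reproduce the reference study's *qualitative*
structure: stiffness rises roughly linearly with filament density
(doubling density from 0.15% to 0.30% raises the mean modulus by a factor
of about 2.4), rises with filament length and cross-linker fraction, is
insensitive to doubling the domain size, segments re-orient monotonically
toward the stretch axis, and the axial fraction of per-filament strain
energy has its mode in the lowest bin (bending-dominated deformation).

The *absolute* moduli do not reproduce: at 0.2% density this implementation
measures means of order 50–100 kPa against a reported 4.38 kPa.  The gap
survives every reading of the under-specified ingredients that we tested
(cross-linker stretching stiffness over four orders of magnitude;
all-pairs versus matched cross-linking; constant-force versus elastic
stretching; density re-scalings), and no single reading reconciles the
modulus scale, the ~5% pre-stress insensitivity, the strong
cross-linker-fraction dependence, and the stated geometry at the same
time — at the stated density a 10 µm domain holds ≈1040 filaments of 5 µm,
whose 0.02 µm pore scale is also inconsistent with binding sites "matching
the pore size" at 0.3 µm.  The acceptance machinery reports what this
implementation computes, and the test file marks the absolute-value checks
accordingly.

## Problem sizes used by tests and the acceptance script

A default-density network on the 10 µm domain has ≈1040 filaments,
≈18 000 nodes and ≈9 000 cross-linkers; one generate–form-find–stretch
pipeline takes one to a few minutes on one CPU.  The acceptance script
therefore runs scaled-down ensembles (one to a few samples per study
condition, reported with each value) under a wall-clock budget,
cheapest conditions first, writing each result as soon as it is
available.  Unit tests use 4 µm domains with 1.6 ± 0.3 µm filaments
(≈500–800 nodes) plus hand-built chains, ladders and spanning filaments
with closed-form answers.

## Known limitations

* Ensemble means carry large sampling error at the scaled-down sizes; the
  per-sample spread at fixed parameters is itself large (the modulus of a
  ~9 000-cross-linker realisation is percolation-sensitive).
* Post-buckling equilibria are not unique; the secant modulus at finite
  strain depends mildly on the loading path (increment size), as expected
  for path-following on a nonconvex energy.
* The marginal-filament positional uncertainty described above means
  "re-solving" a form-found network can move individual weakly-held
  filaments by ~0.1 µm even though the network-scale configuration is
  unchanged.
* Stress normalisation uses the literal 1 µm domain thickness throughout.
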