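---
title: "Enumerating backbone conformations under distance constraints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating backbone conformations under distance constraints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibpenum)
```

## The problem

NMR spectroscopy and cross-linking experiments yield inter-atomic
*distance intervals* rather than coordinates. The Distance Geometry
Problem (DGP) asks for all sets of 3-D coordinates realizing a given set
of exact and interval distances. Standard structure-determination
pipelines (simulated annealing against a penalty function) return one
optimized structure and tolerate small violations; `ibpenum` instead
treats every constraint strictly and *enumerates* the feasible
conformational space of a protein backbone by a discrete tree search,
the interval Branch-and-Prune (iBP).

The decisive structural property is discretizability: if the atoms can
be ordered so that each one is tied by known distances to three
predecessors, the continuous search space collapses to a tree. With
exact distances each new atom lies on the intersection of three spheres
— generically two points, a binary branching. An interval distance to
the third predecessor is uniformly discretized into `b` samples
(`d = l + (t-1)(u-l)/b`, `t = 1..b`; the lower endpoint is sampled, the
upper is not), giving at most `2b` candidates. The number of tree nodes
at any level is bounded by `3 + 2^l b^k`, with `l` the number of
2-branching and `k` the number of b-branching levels.

## The atom order

Backbone atoms are embedded in a *repetition order*: some atoms appear
twice so that every vertex `v > 3` has exact `{v,v-1}` and `{v,v-2}`
distances (bonds and bond angles) and a `{v,v-3}` distance that is
either exact or a torsion-dependent interval. This package uses, per
residue,

```
N, H, CA, N*, HA, CA*, C          (* = repeated atom)
```

closed by two trailing duplicates `HA(n)*, CA(n)**`, for `7n + 2`
vertices in total. The third-predecessor edge of each vertex then
carries a clean meaning:

| vertex | `{v, v-3}` partner | determined by |
|--------|--------------------|----------------|
| `N(i)`  | `HA(i-1)` | psi(i-1) (interval, discretized) |
| `H(i)`  | `CA(i-1)` | peptide planarity (exact) |
| `CA(i)` | `C(i-1)`  | bond angle (exact) |
| `N(i)*` | `N(i)`    | repetition (distance 0) |
| `HA(i)` | `H(i)`    | phi(i) (interval, discretized) |
| `CA(i)*`| `CA(i)`   | repetition (distance 0) |
| `C(i)`  | `N(i)*`   | bond angle (exact); the branch sign is the chirality improper |

The trailing duplicates re-anchor the C-terminal Calpha/Halpha frame
after the final branching, so the last residue's geometry is defined by
freshly re-embedded coordinates; they also close the vertex count at
`7n + 2`. Because the search tree branches on torsions that differ from
phi/psi by constant covalent-geometry offsets, the package measures
those offsets once per covalent table on a reference construction and
transports the user-facing phi/psi windows onto the branch torsions.

Carbonyl oxygens and C-beta atoms are *not* part of the order. Each O is
fixed uniquely by its peptide plane (three sphere equations plus
coplanarity reduce to a 3x3 linear solve) as soon as C(i), N(i+1) and
H(i+1) are embedded; each C-beta by four exact distances to CA, HA, N, C
(three sphere differences, again linear). Performing these placements
*during* the search — not at the leaves — is what allows the chirality
and helix devices to prune early. The C-terminal residue has no
following peptide plane, so its carbonyl oxygen is not modelled; an
`n`-residue chain therefore has `5n` ordered atoms plus `n - 1` oxygens
plus one C-beta per non-glycine residue. Glycine keeps a single
representative HA and has no C-beta (hence no chirality check); proline
is rejected, because its ring couples phi to the covalent geometry in a
way the order does not represent.

## Branching: recursion matrices

Candidate positions are generated by accumulated 4x4 transforms
(`Q_k = Q_{k-1} B_k`), which in our experience too is the most stable of
the standard sphere-intersection formulations. `B_k` is built from the
distance `d(k,k-1)`, the planar angle `theta2` at `k-1` (law of cosines
from the exact predecessor distances) and the torsion magnitude
`omega3` over `{k, k-1, k-2, k-3}`, recovered from the sampled
`d(k,k-3)` by inverting the torsion-distance relation

```
d_il(xi)^2 = d_ij^2 + d_lj^2 - 2 (cos(xi) sqrt(ef) + bc) d_ij d_lj .
```

A `|cos omega3| > 1` signals an empty sphere intersection and the sample
is skipped. Two conventions could realize the second root: flipping the
sign of the `sin(theta2)` terms of `B_k`, or negating `omega3`. Only the
torsion negation reproduces the mirror root through the predecessor
plane — the sign-flip variant preserves `d(k,k-1)` but not the second
and third predecessor distances — so the engine branches over
`±omega3` (the `sigma = +1` branch is visited first, samples in
ascending order; the search is fully deterministic). For the same
reason the `(2,4)` entry of the initialization matrix `B3` carries
`sin(theta3)`: the distance contract `||x3 - x2|| = d32` is what the
recursion requires. The matrices depend only on instance distances,
never on the partial embedding, so they are precomputed once per vertex
and sample; at most `2 |order| b` of them are ever built. The full
product `Q_k` is formed lazily, only after a candidate position (the
fourth column of `Q_{k-1} B_k`) survives all devices.

Numerical guards: the two roots are `2 d sin(theta2) sin(omega3)` apart
and are collapsed to one candidate when that separation falls below
1e-5 Angstrom (planar peptide torsions, duplicates); near-singular
linear systems in the O/C-beta solves (reciprocal condition below
1e-10) and residuals above 1e-6 Angstrom discard the candidate.

A repeated atom is re-embedded with the same machinery; of its branch
candidates the one nearest the original coordinates is kept, and the
node is pruned when even that one drifts by more than `eps_dup`
(default 0.1 Angstrom). The first embedding remains authoritative for
the stored coordinates; the re-embedding only refreshes the transform
chain.

## Pruning devices

* **Distance feasibility (DDF).** Every constrained distance from the
  new atom to the embedded ones must lie within
  `[l - eps_x, u + eps_x]` (inclusive; `eps_x` defaults to 0.2
  Angstrom). The bound set combines covalent exact values, steric lower
  bounds, hydrogen-bond windows, torsion-derived 1-4 intervals and user
  restraints, with upper bounds tightened by shortest-path smoothing
  (below).
* **Torsion-angle feasibility (TAF).** The signed branch torsion must
  lie in its domain — a union of closed intervals and singletons in
  `(-pi, pi]` — widened by `eps_t` (default 2 degrees). The sign is
  respected; a mirror-image angle is rejected even if its magnitude
  fits. Default Ramachandran windows: helical residues
  `phi in [-90, -30]`, `psi in [-77, -17]`; other residues
  `phi in [-180, -30]`,
  `psi in [-90, -10] u [50, 180] u [-180, -170]` (a modeling default of
  this package, overridable per residue). Peptide-planarity torsions
  are singleton domains; the chirality improper at `C(i)` is the
  sign-symmetric pair `{-tau, +tau}`, so both mirror forms are explored
  until the chirality device can see a C-beta.
* **Shortest-path bounds (DSP).** In the graph weighted by upper
  bounds, the shortest path between two atoms over-estimates their
  distance in any feasible realization. Upper bounds are refined once
  per instance by the Floyd-Warshall algorithm; an embedding of `k` is
  pruned when `||x_i - x_j|| - d_ik > u+(j,k)` (strict) for embedded
  `i, j`. Since the refined bounds are valid for *every* feasible
  realization, the engine also checks realized distances against them
  inside DDF; this changes prune order and speed, never the solution
  set.
* **Chirality (CHI).** The CORN rule as a signed torsion: the L-form
  requires `dihedral(C, N, CB, HA) > 0`, checked the moment a C-beta is
  placed. Glycine passes trivially.
* **Alpha-helix device.** For each residue pair `(i-4, i)` inside a
  declared helix: (i) `d(O(i-4), H(i))` in `[1.9, 3.0]` Angstrom;
  (ii) the DSSP-style electrostatic energy
  `q1 q2 (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) f < -0.5` with
  `q1 = 0.42`, `q2 = 0.2`, `f = 332`; (iii) helical phi/psi windows
  (enforced by TAF at branching); (iv) three directionality angles
  within `[0, 70]`, `[0, 90]` and `[110, 180]` degrees. The angle
  definitions are an assumption of this package: `theta` between the
  `C->O` and `O->H` vectors, `theta'` between `N->H` and `H->O`, and
  `theta''` the angle at H in `O..H-N`; on an ideal helix they measure
  about 24, 15 and 165 degrees, comfortably inside the windows, and
  each window is configurable.

Steric lower bounds `sigma_vdw (r_i + r_j)` (radii O 1.4, H 1.0, C 1.7,
N 1.5 Angstrom; `sigma_vdw = 0.85`) apply to pairs at least three
covalent bonds apart. They are a fallback: a pair already holding a
lower bound at least as large keeps it, and a pair under an explicit
NMR or hydrogen-bond constraint receives no steric bound at all —
hydrogen-bonded atoms are precisely the ones allowed closer than the
scaled radius sum (the 2.04 Angstrom H..O floor would otherwise
contradict the 1.9 Angstrom end of the hydrogen-bond window).

Device order per candidate is TAF, DDF, then the incremental O/C-beta
placements with CHI, then the helix criteria, with the
position-independent DSP test applied per vertex and sample; the order
affects speed only, never the solution set.

## Solutions, counters, stopping

Each completed embedding increments the generated-conformation counter.
A conformation is stored only if its backbone (N, CA, C) RMSD to the
*previously stored* one exceeds the filter threshold (default 1.5
Angstrom; the first is always stored), and the search stops after
`max_saved` stored conformations (default 10000). The RMSD filter
compares to the last stored conformation, not to all of them — the
literal reading of filtering "between two successively stored
conformations"; the filter can be disabled (`rmsd_filter = NULL`) for
exact enumeration, which the theory tests use. RMSD is computed by
Kabsch superposition with the proper-rotation correction, so mirror
images do not superpose; round-trip tests compare against both the
reference and its mirror because the global mirror image survives until
the first chirality check.

## Covalent geometry

Default bond lengths (Angstrom): N-H 1.01, N-CA 1.458, CA-C 1.525,
C-N 1.329, C=O 1.231, CA-HA 1.090, CA-CB 1.521. Default angles
(degrees): C-N-CA 121.7, N-CA-C 111.2, CA-C-N 116.2, CA-C-O 120.8,
H-N-CA 118.2, N-CA-HA 108.0, C-CA-HA 109.3, N-CA-CB 110.4,
C-CA-CB 110.5; the sp2 closures C-N-H and O-C-N follow from the others.
These are standard small-molecule crystallographic values, all
overridable through `covalent_geometry()`. The HA..CB distance used by
the C-beta solve is measured on the consistent tetrahedral C-alpha
frame rather than taken from an (over-determined) sixth angle. The
peptide torsion omega is fixed at 180 degrees (trans) or 0 (cis, per
bond on request); residue 1, which has no preceding plane, places its
amide hydrogen by the same torsion convention the other residues
follow, so a uniform-helix fixture is exactly self-consistent.

## The synthetic-data generator

`build_ideal_helix()` constructs an exact alpha-helical backbone
(default `phi = -57`, `psi = -47`, `omega = 180`) from the covalent
table, including H, HA, C-beta and carbonyl O atoms.
`derive_instance()` then *measures* every order-edge distance on that
conformation: `{v,v-1}` and `{v,v-2}` edges become exact constraints,
the phi/psi-dependent `{v,v-3}` edges become intervals of width `w`
centered on the measured value (exact when `w = 0`, the default),
fixed-torsion domains become singletons at the measured torsion, and
the helix hydrogen-bond windows, steric bounds, torsion-derived 1-4
intervals and optionally `n_long` random long-range CA-CA intervals
(total width 1.0 Angstrom by default, seeded pair choice with the seed
recorded in the spec) complete the pruning set. Every constraint
contains its measured value by construction, so the generator is
sound: the truth is never pruned, which the test suite asserts device
by device. The interval width is applied only to the genuinely
torsional edges; repetition and planarity edges stay exact, since the
uncertainty being emulated is conformational, not covalent.

`degrade_inputs()` implements the robustness protocol: each declared
helix shrinks by one residue at both ends (ranges shorter than three
residues are dropped with a warning) and every long-range (NMR-tagged)
interval widens by 0.5 Angstrom on each side, floored at zero.

What the generator does *not* emulate: NOE calibration noise and
spin-diffusion bias, ambiguous assignments, side chains beyond C-beta,
multi-helix tertiary packing beyond the chosen long-range pairs, and
inconsistent constraint sets. Passing the round-trip tests therefore
demonstrates correctness of the enumeration machinery on consistent
inputs, not robustness to the contradictions typical of deposited
experimental restraint lists — inputs must be pre-processed to be
geometrically consistent, or the strict search prunes everything, by
design.

## Problem sizes and test design

The test suite runs fixtures of 5-10 residues (37-72 vertices), exact
and with `w = 0.4, b = 4`, abstract random chains of 5-9 vertices
checked against an exhaustive sign-vector oracle, 50 random pruned
chains for the power-of-two solution-count property, and 1000-case
oracle equivalences (recursion matrices vs. sphere intersection,
torsion distances vs. coordinates, Floyd-Warshall vs. independent
shortest paths). These sizes keep the full enumeration trees small
enough to compare against brute force while exercising every branching
and pruning code path; the engine itself is pure R and handles the
15-51-residue orders (107-359 vertices) that motivated the vertex-count
checks.

## Known limitations

Pure-R depth-first search: exhaustive enumeration at tens of residues
with coarse pruning is out of reach (the tree, not the code, is
exponential); `max_saved` and the RMSD filter are the practical
controls. One chain, no beta-sheet or 3-10-helix devices, no proline,
no side chains beyond C-beta, no ambiguous or weighted restraints. The
C-terminal carbonyl oxygen is not placed. Solution counts on interval
instances depend on the discretization factor `b`: too small may miss
every feasible sample (an empty result on a feasible instance), larger
values widen the tree.
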