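---
title: "Methods: confined ring and linear polymers by crankshaft Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confined ring and linear polymers by crankshaft Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmix)
```

## The model

`ringmix` simulates two long polymers co-confined in a spherocylindrical
container — the situation of two topological domains of freshly replicated
bacterial chromosomes sharing a cell. Each polymer is a pearl-necklace chain:
`N` hard spheres of radius `r` with the distance between consecutive bead
centres fixed at `2r` (tangent spheres, freely jointed). A chain is either
*circular* (an intact, closed topological domain) or *linear* (a domain
carrying a double-strand break). There are no attractive forces, no bending
or torsional stiffness, and no supercoiling: the only interactions are hard —
bead–bead excluded volume and the container wall. All observed behaviour is
therefore purely entropic.

Reduced units: the container diameter defines the length unit (`D = 1`). The
container is a cylinder with hemispherical caps of total tip-to-tip length
`L = 4D`, the aspect ratio of a typical *E. coli* cell. Bead size is not set
directly: the total bead volume is fixed at a volume fraction `phi = 0.05` of
the container, the concentration implied by two chromosome equivalents of DNA
in a bacterial cell, and `solve_bead_radius()` returns the `r` that achieves
it. Making the chains longer at fixed `phi` therefore makes them thinner: the
ratio of container diameter to bead diameter, `D/d`, grows as `N^(1/3)`,
from about 11 at `N = 200` beads per chain to about 22 at `N = 1400`.

With this convention — `L` counted tip to tip including the caps — the
closed-form `D/d` reproduces the printed values 11 and 22 for 400 and 2800
total beads. A cylinder-body-only convention does not, which is why the
tip-to-tip definition is fixed throughout the package and `lambda/L` is
normalised by the same `L`.

## Monte Carlo algorithm

Equilibrium averages are produced by Metropolis Monte Carlo over crankshaft
moves. Because all potentials are hard (energies 0 or infinity), no
temperature or Boltzmann factor appears: a proposed move is accepted exactly
when it violates no constraint, which satisfies detailed balance with respect
to the uniform measure on valid configurations provided the proposal is
symmetric.

One iteration is one attempted move:

1. choose one of the two chains uniformly;
2. choose a pivot bead `i` uniformly and a segment length `s` uniform on
   `[1, s_max]`;
3. for a circular chain, the beads strictly between pivots `i` and
   `i + s (mod N)` rotate rigidly about the axis through the two pivot beads
   by `theta ~ Uniform(-theta_max, theta_max)`;
4. for a linear chain the segment extends in a direction chosen by a fair
   coin; if it stays within the chain the move is the same interior
   crankshaft, and if it runs past either end it becomes a *terminal* move:
   all beads beyond the single interior pivot (the reflection of the
   out-of-range pivot index at that end) rotate about a uniformly random
   axis through the pivot.

The coin flip in step 4 is a deliberate design choice: with forward-only
segments the first bead of a linear chain would never move and the sampler
would not be ergodic. The symmetric variant keeps the proposal distribution
symmetric (each move and its reverse are equally likely) and gives both chain
ends identical mobility.

Defaults are `s_max = min(N/2, 60)` and `theta_max = pi`. An unrestricted
angle maximises configurational change per accepted move; `s_max` caps the
cost of the swept-path test. Both are exposed in `mc_config()`. The move set
contains no whole-chain translations or reptation moves; equilibrium
averages do not depend on the move set, only on its ergodicity.

The schedule follows the standard practice for these systems: the first
`2000 N` iterations are discarded and observables are measured every `20 N`
iterations. All randomness — in R and in the compiled engine — flows from
R's generator, so `set.seed()` (the `seed` field of every config) makes runs
exactly reproducible.

## Preventing chain crossing

Hard beads at bond length `2r` form an impenetrable tube, so physical chains
cannot pass through one another; discrete crankshaft jumps, however, could.
For circular chains that would corrupt the conserved topology (knotting of a
ring, catenation of the two rings), which is precisely the degree of freedom
the model studies. Crossings are excluded by construction:

* **Swept-path substeps (per move).** The proposed rotation is subdivided
  into the smallest number of equal angular substeps such that the largest
  bead displacement per substep is below one bead radius (chord bound
  `2 R_max sin(dtheta/2) < r`, with `R_max` the largest distance of a moved
  bead from the rotation axis), and the excluded-volume condition is checked
  at every intermediate configuration. A strand passage forces a hard-core
  overlap somewhere along the sweep wider than a bead radius, so
  displacement-bounded substeps cannot step over it. The test is symmetric
  under move reversal, so acceptance remains detailed-balanced.
* **Periodic audits (defence in depth).** Every `audit_interval` samples the
  run recomputes exact topological invariants — the Gauss linking number of
  the two rings (must be 0) and the Alexander determinant of every ring
  (must be 1) — and aborts with a state dump if either fails.

The sweep test is applied for every topology pair. For linear chains it is
not needed to define the model (their configuration space is connected, so
forbidding crossing moves leaves the stationary distribution unchanged); it
is kept uniform because it is cheap after candidate pruning and because it
keeps the dynamics physical.

Intermediate configurations are tested only against excluded volume, not
against the wall: a transient wall violation cannot change topology (the
other chain is inside the container) and endpoint states are always fully
validated, so the equilibrium measure is unaffected.

## Topological invariants

`linking_number()` evaluates the discrete Gauss double sum exactly, as the
signed solid angle subtended by each pair of segments, and rounds to the
nearest integer; a residual above 0.2 or nearly touching loops raise errors
rather than returning a doubtful value.

`knot_check()` computes the knot determinant `|Delta(-1)|` (the Alexander
polynomial at -1) from the crossing data of a generic planar projection,
via the underpass presentation: at `t = -1` each crossing contributes a row
with -1 at the incoming and outgoing arcs and +2 at the overpass arc, and
the determinant of any maximal minor is taken — computed exactly modulo two
large primes and lifted. The value is 1 for the unknot, 3 for the trefoil,
5 for the figure-eight knot; it separates the unknot from every knot
reachable by a rare undetected crossing in practice, but it is not a
complete invariant (a documented limitation). Projections are drawn from a
seeded generator; lattice-built rings contain many collinear edges, so a
vertex jitter far below the bead radius (1e-3 of the shortest edge, which
cannot change the knot type of a chain whose non-bonded beads are at least
`2r` apart) is applied before projecting, and degenerate projections are
re-drawn a bounded number of times.

## Initial configurations

The builders are deterministic. Chains are laid out on a cubic lattice of
spacing `2r`, so every bond is an axis-aligned lattice step of exactly one
bond length and all non-bonded pairs are at least `2r` apart by construction.
Linear chains follow a boustrophedon space-filling path; circular chains
follow a closed lattice cycle (a perimeter cycle in the layer/row plane whose
cells carry paired x-sweeps), which is manifestly unknotted, and the two
chains are placed either in disjoint axial halves (*segregated* start,
negative overlap length) or on interleaved lattice layers spanning the same
axial interval (*overlapping* start, the control used to show that rings
segregate even from a fully mixed state). Odd-length rings cannot close on a
lattice and fall back to a regular polygon when it fits.

The synthetic starts emulate only the constraint structure of the model
(bonds, excluded volume, confinement, topology) — not any feature of real
chromosome conformations. Equilibrium averages are start-independent (the
package tests the segregated/overlapping control); what the passing tests do
*not* show is anything about kinetics in physical time, since Monte Carlo
iterations have no time mapping.

## Observables

* **Overlap length** `lambda`: the length of the axial interval shared by
  the two chains' bead centres, `min(zmax1, zmax2) - max(zmin1, zmin2)`;
  negative when a gap separates the chains, normalised by the container
  length `L` when reported as `lambda/L`.
* **Contact probabilities** at cutoff `3r` (strictly less than; the boundary
  case is measure zero and the strict convention is fixed for bit-exact
  reproducibility): inter-chain over all `N1 N2` cross pairs; intra-chain
  over all non-consecutive same-chain pairs (`N(N-3)/2` for a ring,
  `(N-1)(N-2)/2` for a linear chain).
* **End-bead contact probabilities** for linear chains: each terminal bead
  is tested against every bead of the other chain (inter) and against the
  *internal* beads of its own chain — both terminal beads excluded — that
  are non-consecutive to it, giving `N - 3` eligible partners per end
  (intra). Both ends contribute and are averaged. Excluding the opposite
  terminal bead is the stricter reading of "internal"; the choice is
  isolated in one place and its effect is a single pair out of `N - 3`.
* **Fold boost**: `(p_end_inter / p_end_intra)` of a linear chain divided by
  `(p_inter / p_intra)` of the circular-circular reference system — how much
  more a broken end mixes than an average ring bead does.

Production contact counting runs through an axial cell list with cell edge
at least `3r` (serving both the `2r` overlap test and the `3r` contact
test); the test suite pins it against an exhaustive double-loop oracle.

## Error analysis

Error bars come from the blocking method: iterated pairwise block averaging,
recording the naive standard error of the block means at each level. The
plateau is selected automatically — the first level whose estimate agrees
with the next level's within its own statistical uncertainty, among levels
retaining at least 32 blocks; when no plateau emerges the larger of the last
eligible and final estimates is reported with a flag. The integrated
autocorrelation time `tau_int = 1/2 + sum rho(t)` is summed under an
automatic window (`W >= 6 tau_int(W)`); the convention (`tau_int = 1/2` for
iid data) is attached to every result to avoid the factor-of-two ambiguity.
Ratios of means (contact ratios, fold boosts) carry first-order propagated
errors.

## Problem sizes and numerical choices

The package's desk-scale benchmark runs use `N = 200` beads per chain
(`D/d ~ 11`): a circular+circular run of `4.5x10^7` attempted moves and
circular+linear / linear+linear runs of `2.5x10^7` after the `2000 N`
discard, sampling every `20 N` iterations (6000–7500 samples). At these
lengths the slowest observable (the overlap length, with `tau_int` up to
~100 samples for two linear chains) accumulates tens to a few hundred
correlation times — enough to resolve the segregation ordering and contact
ratios outside blocking error bars, which is the package's reproducibility
bar. Longer-chain claims (`N = 1400`) are catalogued in
`reference_claims()` with `desk_scale = FALSE` and are only meaningful in
much longer runs.

Tolerances: bond lengths are preserved by exact rotation matrices and only
checked (drift over `10^6` moves is orders of magnitude below the `1e-9 r`
validator tolerance; no re-projection is needed). The excluded-volume test
uses a relative slack of `1e-9` so that lattice-built states whose
non-bonded pairs sit at exactly `2r` are not spuriously rejected, and the
wall test includes its boundary. Containers are closed sets; all boundary
ties favour acceptance, affecting only measure-zero configurations.

## Limitations

* No supercoiling, bending stiffness, nucleoid-associated proteins or
  osmotic compaction: the model isolates the generic entropic effect of
  topology under confinement.
* Monte Carlo iterations carry no physical time; only equilibrium
  quantities are meaningful.
* The knot detector is the Alexander determinant, not a complete invariant.
* `D/d` up to ~22 remains far below the ~150 of real cells; the package
  reproduces the trend with `D/d`, not absolute cellular values.
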