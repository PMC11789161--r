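---
title: "Deciding when two crystal structures are the same: the methods behind cspmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding when two crystal structures are the same}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspmatch)
```

Crystal structure prediction (CSP) produces landscapes of hundreds to
thousands of putative crystal packings for a molecule. Whether a prediction
"matches" an experimentally determined form — and whether two groups'
landscapes contain the same structures — is not a trivial question: the same
packing can be submitted in a different unit-cell setting, with missed
symmetry, at a different effective temperature (so with slightly different
cell volumes), or with atoms jittered by the optimizer. cspmatch implements
the standard decision pipeline used to assess such predictions, together
with the synthetic fixtures needed to validate every stage against ground
truth.

## The crystal data model

A structure is a unit cell (lengths in ångström, angles in degrees), a set
of symmetry operators acting on fractional coordinates, and the
asymmetric-unit atom sites with occupancies and optional disorder-group
tags. The orthogonalization convention is fixed package-wide: **a** along
x, **b** in the xy-plane, right-handed. Symmetry can come from an explicit
operator loop in a CIF, or from a Hermann–Mauguin symbol resolved against an
internal table of the common molecular space groups; the operator set is
always closed under composition before use, and expanding the asymmetric
unit collapses special-position duplicates within a 0.3 Å Cartesian merge
tolerance — larger than numerical noise, smaller than any bond.

Molecules are perceived by covalent-distance bonding under periodic boundary
conditions: two atoms bond when their distance is below the sum of their
covalent radii (Cordero single-bond values, versioned in the package) plus a
0.4 Å margin, the standard crystallographic criterion. Connected components
are unwrapped across cell boundaries into contiguous Cartesian molecules; a
component that bonds to its own lattice image is reported as a non-molecular
solid rather than silently truncated. Z′ per chemical species is the number
of molecules of that species in the cell divided by the symmetry-operator
count, which correctly yields fractional values for molecules on special
positions.

Disordered structures carry per-site disorder tags. Splitting produces one
fully ordered structure per component (shared atoms present in each,
occupancies reset to 1); a component whose molecular content differs from
its siblings is rejected as chemically incomplete. CIFs with untagged
partial occupancies are grouped by occupancy value with a warning — a
heuristic, flagged as such.

## Packing similarity

The packing comparison asks: around corresponding central molecules, can an
n-molecule coordination shell of the reference be overlaid on the probe?
The declared geometric descriptors are:

* all pairwise centroid–centroid distances within the cluster, compared
  relatively within `dist_tol` (default 0.35);
* all angles between inter-centroid vectors, compared within `angle_tol`
  (default 35°);
* per-molecule orientation descriptors: the folded angles (in [0°, 90°])
  between each molecule's inertial principal axes and (a) its centroid
  direction from the central molecule and (b) the central molecule's axes,
  rank-matched by eigenvalue. Folding makes the descriptors blind to proper
  vs improper overlays, matching the default `allow_inversion = TRUE`; a
  chirality-sensitive mode restricts the final overlay to proper rotations.
  Axes whose inertial eigenvalues are nearly degenerate (relative gap below
  1e-3) are excluded from the checks rather than trusted.

Molecules must be bond-graph isomorphic (element-labelled, hydrogens
excluded by default) to correspond at all; "molecular differences not
allowed" is interpreted as exactly this isomorphism requirement.

The correspondence search is exact, not heuristic: a compiled
forward-checking depth-first search enumerates, over every central-molecule
pair on both sides, the assignments satisfying all descriptor constraints,
minimizing the number of unmatched reference molecules (binary search on the
skip budget, fail-first variable ordering, a Hall-type bound on the union of
remaining candidate sets, and an incumbent bound shared across central
pairs). Every candidate assignment costs one "trial"; when the trial budget
(default 10⁶, configurable) is exhausted the comparison stops with an
explicit error — never a silent zero, since a silently truncated comparison
is indistinguishable from a genuine mismatch. Both unit-cell molecules of
both structures are tried as centrals: symmetry images can receive
genuinely different tie-broken cluster memberships, so none can be skipped
a priori. Cluster construction itself is deterministic: ties in centroid
distance are broken by a canonical molecule hash, then by the lattice image
vector, so results are reproducible across platforms.

The reported RMSD is a single rigid least-squares (SVD) superposition over
all matched non-hydrogen atoms jointly — not a per-molecule average — with
the atom correspondence chosen per molecule among the available graph
isomorphisms under the current transform, refined for two passes. Among all
maximal correspondences (up to a configurable enumeration cap of 256), the
minimum RMSD is reported.

## Powder patterns and the de Gelder similarity

Reflection intensities are computed by direct summation of the structure
factor over the expanded unit cell with the standard four-Gaussian atomic
scattering factors (table versioned in the package), so systematic absences
emerge from the phase sum rather than from space-group tables. The
Lorentz–polarization factor is applied and symmetry-equivalent reflections
are merged by (d, |F|²) with a multiplicity count. Patterns are the
reflections convolved with a pseudo-Voigt profile (default FWHM 0.1° 2θ,
Gaussian fraction 0.5) on a uniform grid (default 3–40° 2θ, step 0.017°,
Cu Kα₁ = 1.54056 Å), normalized to unit maximum. The isotropic displacement
parameter defaults to B = 0: the package's comparisons are
simulation-vs-simulation, where consistency matters more than thermal
realism.

Two patterns are compared with the de Gelder cross-correlation similarity: a
normalized, triangular-windowed integral of the cross-correlation over 2θ
shifts. The window half-width `l` defaults to 1.5° 2θ and is exposed as a
parameter, because the downstream 70% protocol gate depends on it and no
canonical value exists. S(f, f) = 1 exactly, and S is invariant to positive
scaling of either pattern.

`refine_cell` maximizes this similarity against a target pattern by
derivative-free (Nelder–Mead) adjustment of the cell parameters the crystal
system leaves free (detected from the symmetry operators, e.g. a, b, c, β
for monoclinic), holding fractional coordinates fixed — the variable-cell
pattern-matching idea used to bridge thermal expansion between simulated
and experimental patterns. Acceptance is monotone: if the optimizer cannot
improve on the starting similarity, the input structure is returned
unchanged. March–Dollase preferred-orientation corrections are available
for reflection intensities, averaged over symmetry-equivalent reflections.

## PDD fingerprints and the Earth Mover's Distance

The pointwise distance distribution (PDD) of a crystal is the weighted
matrix whose rows are, for each atom in the unit cell, the ordered distances
to its k nearest neighbours in the infinite crystal (the neighbour search
supercell is enlarged until the k-th distance is provably inside the
complete search radius). Identical rows — within 1e-4 Å in the L∞ sense,
below CIF coordinate precision — are collapsed with summed weights, which
makes the fingerprint independent of the unit-cell setting. Rows are
computed over all atoms by default, hydrogens included; a heavy-atom mode is
provided because some submitted CIFs omit hydrogens, and verdicts are
consistent provided both structures are treated the same way.

Two PDDs are compared by the Earth Mover's Distance with L∞ ground cost
between rows, solved exactly by a successive-shortest-path transportation
solver (Dijkstra with node potentials). Weights are rationalized onto an
exact integer grid first — PDD weights are occurrence counts over the cell,
so this is lossless — which eliminates the degenerate fractional
augmentations that plague floating-point min-cost-flow solvers. Before
comparison the reference cell is expanded isotropically to the probe's
volume (cube-root length scaling), removing the dominant thermal-expansion
effect; the match verdict uses k = 100 and a 0.225 Å cutoff. The PDD metric
is chemically blind by construction; an element-partitioned variant
(separate transport per element class) is available as an option, off by
default.

## The staged matching protocol

`assess_match` runs the three-stage decision: (a) simulate both powder
patterns with identical settings — so the gate tests geometry, not profile
choices — and require de Gelder similarity ≥ 0.70; (b) packing comparison
with a 30-molecule shell at 35%/35° tolerances, hydrogens excluded,
molecular differences disallowed; (c) verdict "match" when all 30 molecules
overlay with RMSD < 1.0 Å. Disordered experimental forms are split and each
ordered component assessed separately. A trial-cap abort surfaces as the
distinct verdict "limit-error". For landscape scans the protocol-stage
search only needs the full-shell existence question, which is much cheaper
than maximizing partial overlap and is exact for the verdict.
`core_only_assess` strips a selector (e.g. flexible substituents) from both
structures and skips the gate, since the pattern of a stripped structure is
not physical.

Landscape-vs-landscape overlap matrices count, for each query structure of
one group (top-100 by submitted rank), whether any structure of another
group's target set (top-100, or the full set) is a PDD match; percentages
use the actual query-set size for groups submitting fewer than 100.
Deduplication is single-linkage under either metric, with lowest-energy
representatives when energies are present.

## The cocrystal stoichiometry hull

For a two-component system, each candidate stoichiometry AxBy contributes
its minimum-energy structure as a point (composition y/(x+y), normalized
formation energy (E − x·E_A − y·E_B)/(x+y) in kJ/mol per molecule), with
the pure components as zero endpoints. Lattice energies stand in for free
energies. The thermodynamically stable set is the lower convex hull
(computed by a monotone-chain construction; minimum-energy point per
composition; every point also gets its energy above the hull, zero exactly
for stable points). The simpler literature criteria — the cocrystal
formation energy against the stoichiometric sum of pure components — are
provided as one-formula helpers on the same data.

## What the synthetic generators emulate — and what they do not

All validation runs on generated fixtures with known ground truth, under
fixed seeds with one named RNG substream per generator (adding a generator
never shifts another's output).

* `make_toy_crystal` places hard-coded idealized rigid molecules (6–20
  atoms, chosen asymmetric so bond graphs have no automorphisms and
  inertial axes are well resolved) in common space groups, verifying a
  2.0 Å minimum intermolecular contact.
* `perturb` applies lattice strain and Gaussian atomic jitter, reporting
  the maximum displacement for continuity assertions.
* `make_polytypes` builds two P1 structures from byte-identical molecular
  layers: a one-layer uniform stacking and an m-layer cell with every m-th
  layer given a half-turn about the **a** axis. The molecule is oriented
  with its in-plane inertial axes along the xy diagonals, so the half-turn
  rotates both axes by 90° and inverted-layer molecules are cleanly
  distinguishable at any sensible angle tolerance; the in-layer spacing
  (6.5 Å) and layer spacing (3.5 Å) are chosen so a 20-molecule shell fits
  between inverted layers of the m = 6 polytype while a 70-molecule shell
  cannot avoid them. This reproduces the qualitative polytype trap: full
  packing match at small shells, partial at large ones. The corresponding
  diffraction difference is concentrated in weak superlattice reflections
  (l not divisible by m, about 1% relative intensity for the default
  molecule), so the two patterns are distinguishable but very similar —
  the de Gelder similarity stays around 0.999 at the default window.
* `make_disorder_pair` superimposes two substituent conformations as tagged
  disorder groups; splitting recovers the planted components atom-for-atom.
* `make_landscape` plants a configurable number of true matches (perturbed
  copies of a designated "experimental" packing), duplicate clusters, and
  decoy packings with randomized cells and orientations, with ranks and
  pseudo-energies; the truth table is the reference for all recovery
  statistics.
* `make_hull_dataset` plants a stable stoichiometry set with a convexified
  margin and higher-energy decoys.

These fixtures deliberately idealize: molecules are rigid, energies are
synthetic labels, decoys are generated by re-packing the same molecule
rather than by energy minimization, and thermal effects are reduced to
isotropic strain plus jitter. Passing tests therefore demonstrate that the
algorithms are correct with respect to their definitions and robust to
geometric perturbations of the size encountered between refinements — not
that the default tolerances are optimal for any particular real landscape.

## Numerical choices and problem sizes

Tolerances and caps that matter: special-position merge 0.3 Å; bond margin
0.4 Å; PDD row collapse 1e-4 Å; packing trial cap 10⁶ (raised explicitly to
2×10⁷ for the 70-molecule polytype scans); RMSD enumeration cap 256
correspondences; de Gelder window 1.5° 2θ; EMD weight rationalization up to
denominator 10⁶ with float fallback. The validation suite uses 4-molecule
clusters against the exhaustive correspondence oracle, k ≤ 26 PDDs against
5³-supercell enumeration, ≤ 6-row EMD instances against an exact
linear-programming solve, 100-structure landscapes over 20 seeds for the
protocol recovery statistics, and 50 random hull datasets — sizes chosen so
each check isolates one algorithmic property while the whole suite stays
routinely runnable.

## Known limitations

The CIF reader covers the core-dictionary subset (no multi-line text
fields, no anisotropic displacement parameters); the space-group table
covers the common molecular groups, with explicit operator loops always
taking precedence. The packing search is exact but worst-case exponential:
pathological near-symmetric landscapes can exhaust the trial cap, which is
reported loudly. Verdicts at tolerance boundaries are as sharp as the
inputs: a structure exactly at a cutoff can flip under 1e-9-level noise.
Polymeric and framework solids are out of scope by design.
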