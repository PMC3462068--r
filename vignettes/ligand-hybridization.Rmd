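---
title: "Geometric common substructures and 3D ligand hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric common substructures and 3D ligand hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmerge)
```

## The problem

Ligand-based design often starts from several known binders of one
receptor. If two of them share a rigid core — a ring system, a conserved
scaffold — in similar poses, new candidates can be proposed by swapping the
substituents decorating that core. `ligmerge` automates this for pairs of
3D, PDB-formatted small-molecule models, entirely from ligand geometry: no
receptor structure, force field, or chemical database is consulted. The
output is a set of heavy-atom hybrid models intended for downstream
protonation, minimization, and docking.

Because the comparison is purely geometric, the method is conformation
sensitive: it matches atoms in the poses given. Rigid shared segments
(aromatic rings and fused systems) match robustly; flexible chains only
match if supplied in compatible conformations. Users with flexible ligands
should supply one PDB file per conformation and let the batch mode try all
pairs.

## The model of a molecule

A molecule is a list of heavy atoms (element symbol, 3D coordinates in Å)
plus an undirected bond graph. Bond orders, formal charges, aromaticity,
and chirality are deliberately not modeled: PDB files do not carry reliable
order information and no step of the algorithm needs it; merged products
are heavy-atom skeletons. Hydrogens are stripped before any analysis.
Connectivity comes from CONECT records when present, unioned with
distance-based perception: atoms \(i, j\) are bonded iff
\(d_{ij} \le r_i + r_j + s\), with \(r\) the single-bond covalent radius
(Cordero consensus values; H, B, C, N, O, F, Si, P, S, Cl, As, Se, Br, I)
and slack \(s = 0.45\) Å, the standard heuristic for distance-based
perception. A disconnected input triggers a warning and the search uses the
largest connected component, since a common substructure defined along
bonded stretches cannot cross components.

## Finding the maximum common substructure

Candidates are **stretches**: simple paths in the bond graph, at least
three atoms long (single atoms and bonded pairs are not distinctive). Every
stretch is labeled with an orientation-independent element key (the
lexicographic minimum of the forward and reversed element sequences);
stretches with equal keys in both molecules are candidate common fragments
regardless of geometry.

Geometry is screened with the **distance fingerprint**: the sorted vector
of all \(\binom{n}{2}\) pairwise distances in a stretch. It is invariant
under rigid motion and atom permutation, and two fragments are accepted as
geometrically identical when fingerprints agree element-wise within a
tolerance. Because sorting discards correspondence, a fingerprint match is
necessary but not sufficient; an explicit mapping (forward or reversed
path orientation) must additionally preserve elements positionwise and
every *unsorted* pairwise distance within the same tolerance. This
two-stage test keeps the cheap invariant filter while making the final
acceptance exact.

The search descends from the largest conceivable size,
\(\min(n_A, n_B)\), and stops at the first size with a verified pair — so
the result is maximal by construction. All verified pairs at that size are
retained (deduplicated by atom sets); merge generation later runs over
every candidate. Keys and path pairs are processed in lexicographic order,
making the search deterministic.

**Symmetry.** A symmetric MCS admits several equally good overlays — a
toluene-shaped substructure admits exactly two (the ring flip about the
methyl–phenyl axis), an ideal \(n\)-cycle of identical atoms \(2n\). These
are enumerated exactly, by backtracking over element-preserving bijections
with incremental distance checks, and each one drives its own
superposition and merge round (or one is chosen by seed when
`all_symmetry_relations = FALSE`).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tolerance` | 0.1 Å | per-distance agreement for geometric identity |
| `min_mcs_size` | 3 atoms | smallest admissible common substructure |
| `bond_slack` | 0.45 Å | distance-perception slack |
| `clash_cutoff` | 2.0 Å | minimum allowed inter-fragment contact |

The 0.1 Å tolerance is this package's choice: tight enough to distinguish
ring geometries (adjacent vs meta distances differ by ~1 Å), loose enough
to absorb coordinate jitter from independent minimizations. The 2.0 Å
clash cutoff sits just above typical covalent bond lengths and well below
nonbonded contact distances; both are user-configurable. The three-atom
floor can be raised for more distinctive overlays (ten or more atoms give
the most unambiguous superpositions); requests below three are raised to
three with a warning.

### The simple-path reading and its limits

A "stretch" is read as a linear sequence — a simple path. The MCS atom set
is the atom set of the best-matching path pair, so any reported MCS must be
traceable by one simple path in both molecules. Chains and rings qualify;
a star-branched common substructure not coverable by a single path would
be missed. The fixture generator only emits path-traceable scaffolds, and
the test suite checks the path search against a brute-force geometric
common-connected-subgraph oracle on such cases; the limitation is
documented rather than papered over, since branched-but-unpathable shared
cores are rare among rigid scaffolds.

Path enumeration is depth-first with a visited set; `max_path_len` can cap
the stretch length (with a warning) on pathological dense graphs, at the
cost of missing larger substructures.

## Superposition

For each symmetry assignment, the optimal rigid transform is the Kabsch
solution: subtract centroids, form the \(3 \times 3\) covariance, take its
SVD, and correct the sign of the smallest singular direction so the
determinant is +1. Improper transforms (reflections) are refused — a
reflected overlay would silently invert chirality. The transform is
computed on MCS atoms only but applied to the whole of molecule B; parent
A's frame is the fixed output frame for every product. Collinear MCS atom
sets leave rotation about the line undetermined; the solution returned is
still RMSD-optimal and a warning is issued.

## Fragment merging

Non-MCS atoms split into connected fragments; each records its anchor
bonds into the MCS. MCS atoms with at least one fragment in either parent
are **handle atoms**. A merge plan assigns each handle to parent A or
parent B and inherits that parent's full substituent set there; a handle
whose chosen parent is bare stays an implicit open valence for downstream
protonation. This per-handle *parent* choice (rather than per-fragment
choice) keeps "mixing and matching" well-defined when a parent carries
zero or several fragments at one handle; a "neither parent" option is
deliberately not offered. Fragments anchored at two or more distinct
handles force the same choice at all of them; inconsistent plans are never
generated. Plans selecting identical content (e.g. bare/bare) collapse;
products are additionally deduplicated across symmetry assignments and MCS
candidates by their fragment-content signature in the A frame.

A combination is skipped when any two atoms of *different* chosen
fragments come closer than `clash_cutoff`; contacts involving MCS atoms or
within one fragment are exempt (anchor bonds are legitimately short). With
`all_substituent_combinations = FALSE` a single consistent plan is drawn
uniformly per overlay; the generator is seeded (default 0) so default runs
are reproducible.

## Synthetic fixtures and what they do (not) show

The fixture module builds molecule pairs whose ground truth is known
analytically: scaffolds (evenly spaced chains; regular polygons; a ring
plus one exocyclic atom, the toluene shape) decorated with payloads
(single atoms, two-atom chains, three-atom branches, and two-handle
bridges) placed at ideal bond length — radially outward from the ring
centroid, or along ±x beyond chain termini, directions chosen so
inter-substituent distances stay analytically computable for clash tests.
Expected MCS size, symmetry count (dihedral operations preserving the
element sequence, with the exocyclic atom pinned for the toluene shape),
handle count, and consistent plan count are computed combinatorially from
the specs, never by the pipeline under test. Shared jitter (drawn once,
applied to the scaffold before decoration) emulates coordinate noise while
keeping the common core exactly common; randomized pairs draw substituent
elements from disjoint pools (A: F/Cl/Br; B: I/P/Si) so the MCS is the
scaffold by construction.

These fixtures exercise every pipeline stage with exact expectations, but
they are idealized: real ligand pairs have *approximately* shared cores
(independent minimizations), realistic valences, and flexible linkers.
Passing tests demonstrate algorithmic correctness on geometrically exact
inputs and robustness to small shared jitter — not recall on sloppily
aligned conformers, which is governed by the user's choice of `tolerance`
and input poses.

Problem sizes throughout the suite (≤ 14 heavy atoms for
oracle-checked cases, 50 randomized pairs, 1000-sample Monte-Carlo
optimality checks) were chosen so the brute-force oracles remain exact
while the whole suite runs in well under a minute.

## Numerical and degenerate-input choices

- Distance comparisons use absolute thresholds in Å; no relative scaling.
- Path deduplication keeps the orientation with the lexicographically
  smaller atom-index sequence; ties cannot occur for simple paths.
- Equal-size MCS candidates are all retained and merged over; output
  filenames encode the candidate index.
- Elements are stored uppercase (`"CL"`); comparisons are
  case-insensitive at the boundary.
- Collinear Kabsch inputs warn (see above); fewer than three matched atoms
  are an error.
- A molecule left empty by hydrogen stripping, or a PDB file with no atom
  records, is an "empty model" error; a pair with no common three-atom
  stretch raises a distinct "no MCS found" condition that batch mode logs
  and survives.

## Known limitations

- Conformation sensitivity (by design; supply conformers as extra files).
- Simple-path MCS (see above).
- No chemical sanity repair: merged products can have unusual valences at
  bare handles and must be protonated/minimized downstream.
- The sorted fingerprint is only a pre-filter; its false positives are
  eliminated by mapping verification, at some enumeration cost on highly
  symmetric graphs.
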