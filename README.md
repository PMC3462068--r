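# ligmerge

Generate novel hybrid small molecules from pairs of known 3D ligand models.

When many ligands of a receptor are already known — from crystallography,
docking, or prior screening — new candidate binders can be proposed by
recombining the substituents of known actives around their shared core.
`ligmerge` does this purely from ligand geometry, with no receptor structure
required: given two PDB-formatted compound models it

1. finds their **maximum geometric common substructure (MCS)** — the largest
   set of heavy atoms occurring in both molecules with the same element
   sequence along the bond graph and the same 3D geometry within a distance
   tolerance;
2. **superimposes** the two molecules on that substructure with the Kabsch
   least-squares rigid-body fit, under *every* symmetry-consistent
   atom-to-atom assignment (a ring, for instance, admits several overlays);
3. **mixes and matches** the substituent fragments attached at each shared
   "handle" atom, skipping combinations with steric clashes, and writes each
   clash-free hybrid as a PDB file.

The intended users are computational chemists assembling custom virtual
screening libraries from sets of known or putative binders.

## Method sketch

Candidate common substructures are *stretches* — simple paths in the
heavy-atom bond graph — grouped by element sequence (e.g. `C-C-N`); the
shortest stretch considered is three atoms. Geometry is compared with a
*distance fingerprint*: the sorted vector of all pairwise interatomic
distances within a stretch, invariant under rigid motion and atom
permutation. Two stretches match when their fingerprints agree element-wise
within a tolerance (default 0.1 Å) *and* an explicit atom-to-atom mapping
preserving elements and all unsorted pairwise distances exists. The search
proceeds from the largest candidate size downward and stops at the first
size with a verified match.

All element- and distance-preserving bijections between the matched atom
sets (ring flips, rotations) are then enumerated by backtracking. For each
such assignment the Kabsch transform computed on the MCS atoms is applied to
the whole of molecule B, placing it in molecule A's frame. Fragments — the
connected components of non-MCS atoms — are swapped per handle atom: each
handle takes either parent A's or parent B's substituent set, with fragments
spanning several handles ("multiple-handle fragments") forcing a consistent
choice at all their handles. Combinations placing atoms of two different
fragments closer than a cutoff (default 2.0 Å) are skipped.

## Worked example

Two ligands sharing an asymmetric six-membered ring, each carrying its own
substituents at ring positions 1 and 4:

```r
library(ligmerge)

ring <- scaffold_spec("ring", 6, c("C", "C", "C", "C", "N", "O"))
fx <- build_pair(ring,
                 list(substituent_spec(1, "atom", "F"),
                      substituent_spec(4, "atom", "CL")),
                 list(substituent_spec(1, "atom", "BR"),
                      substituent_spec(4, "atom", "I")))

res <- merge_pair(fx$mol_a, fx$mol_b)
res
#> <ligand merge: MCS 6 atoms (1 candidate(s), 1 mapping(s)); 4 plan(s), 0 clash-skipped; 4 merged molecule(s)>

res$merged[[2]]
#> <merged molecule: 8 atoms (6 MCS), fragments [A2;B1]>
```

The MCS is the shared ring (6 atoms). With two handles and one substituent
per parent per handle there are 2 × 2 = 4 consistent combinations: the two
parent patterns (F/Cl and Br/I) plus the two novel hybrids (F/I and Br/Cl).
`write_merged(res, "out/")` writes each product as a PDB file.

The same pipeline runs from a shell, over one pair or over all pairs of PDB
files in a directory:

```sh
Rscript inst/scripts/ligmerge.R --ligand-a A.pdb --ligand-b B.pdb --out outdir
Rscript inst/scripts/ligmerge.R --ligands-dir ligands/ --out outdir --output-mcs
```

Batch mode writes a `summary.tsv` with per-pair MCS size, mapping count,
plans enumerated, clash-skipped plans, and files written.

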