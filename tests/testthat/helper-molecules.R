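# Small molecules built in code for the tests.

# C-C-O chain, linear, ideal 1.5 A spacing
linear_cco <- function() {
  molecule(c("C", "C", "O"),
           rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0)),
           bonds = rbind(c(1L, 2L), c(2L, 3L)), name = "cco_linear")
}

# C-C-O chain bent 90 degrees at the middle atom, same bond lengths
bent_cco <- function() {
  molecule(c("C", "C", "O"),
           rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0)),
           bonds = rbind(c(1L, 2L), c(2L, 3L)), name = "cco_bent")
}

benzene <- function(bond = 1.39) {
  scaffold_molecule(scaffold_spec("ring", 6, bond_length = bond),
                    name = "benzene")
}

toluene <- function() {
  scaffold_molecule(scaffold_spec("ring_plus_methyl", 7), name = "toluene")
}

random_rigid_transform <- function() {
  # uniform-ish random proper rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  structure(list(rotation = q, translation = stats::rnorm(3, sd = 5)),
            class = "rigid_transform")
}

rigidly_move <- function(mol, seed = 1) {
  tr <- ligmerge:::with_seed(seed, random_rigid_transform())
  apply_transform(mol, tr)
}

# Asymmetric 6-ring (symmetry count 1) used by merge fixtures
asym_ring_spec <- function() {
  scaffold_spec("ring", 6, c("C", "C", "C", "C", "N", "O"))
}
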