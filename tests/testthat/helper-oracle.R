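# Independent brute-force oracle: maximum geometric common connected
# subgraph of two molecules. Backtracking over all element-preserving
# partial maps that stay connected in BOTH bond graphs and whose pairwise
# distances agree within tolerance. Deliberately independent of the
# package's path-based search.

oracle_mcs_size <- function(mol_a, mol_b, tol = 0.1) {
  na <- n_atoms(mol_a); nb <- n_atoms(mol_b)
  adj_a <- lapply(seq_len(na), function(i) integer(0))
  for (k in seq_len(nrow(mol_a$bonds))) {
    a <- mol_a$bonds[k, 1]; b <- mol_a$bonds[k, 2]
    adj_a[[a]] <- c(adj_a[[a]], b); adj_a[[b]] <- c(adj_a[[b]], a)
  }
  adj_b <- lapply(seq_len(nb), function(i) integer(0))
  for (k in seq_len(nrow(mol_b$bonds))) {
    a <- mol_b$bonds[k, 1]; b <- mol_b$bonds[k, 2]
    adj_b[[a]] <- c(adj_b[[a]], b); adj_b[[b]] <- c(adj_b[[b]], a)
  }
  da <- as.matrix(stats::dist(mol_a$coords))
  db <- as.matrix(stats::dist(mol_b$coords))

  best <- 0L
  map_a <- integer(0); map_b <- integer(0)

  extend <- function() {
    k <- length(map_a)
    if (k > best) best <<- k
    # candidate A atoms: adjacent to the mapped A set (any atom if empty)
    cand_a <- if (k == 0L) seq_len(na) else {
      setdiff(sort(unique(unlist(adj_a[map_a]))), map_a)
    }
    for (ai in cand_a) {
      cand_b <- if (k == 0L) seq_len(nb) else {
        setdiff(sort(unique(unlist(adj_b[map_b]))), map_b)
      }
      for (bi in cand_b) {
        if (mol_a$elements[ai] != mol_b$elements[bi]) next
        ok <- k == 0L || all(abs(da[ai, map_a] - db[bi, map_b]) <= tol)
        if (!ok) next
        map_a <<- c(map_a, ai); map_b <<- c(map_b, bi)
        extend()
        map_a <<- map_a[-length(map_a)]; map_b <<- map_b[-length(map_b)]
      }
    }
  }
  extend()
  best
}
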