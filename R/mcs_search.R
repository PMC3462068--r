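# Maximum geometric common substructure search.
#
# Candidate common substructures are "stretches" -- simple paths in the bond
# graph -- grouped by their element sequence. Geometric identity is tested
# with a sorted pairwise-distance fingerprint (a cheap rigid-motion- and
# permutation-invariant pre-filter) and then confirmed by an explicit
# atom-to-atom mapping whose unsorted pairwise distances must agree within
# tolerance. The search runs from the largest candidate size downward and
# stops at the first size with a verified match.

element_key <- function(elements) {
  fwd <- paste(elements, collapse = "-")
  bwd <- paste(rev(elements), collapse = "-")
  if (fwd <= bwd) fwd else bwd
}

#' Enumerate element-sequence stretches (simple paths)
#'
#' Finds all simple paths in the bond graph with lengths in
#' `[min_len, max_len]` atoms. A path and its reversal count once; the
#' retained orientation is the one whose atom-index sequence is
#' lexicographically smaller. Each path carries an orientation-independent
#' element key (the lexicographic minimum of the forward and reversed
#' element sequences, joined by "-").
#'
#' @param mol A `molecule` with a bond graph.
#' @param min_len Minimum path length in atoms (>= 3).
#' @param max_len Maximum path length in atoms.
#' @return A list of records, each with `atoms` (integer vector) and `key`.
#' @export
enumerate_paths <- function(mol, min_len = 3L, max_len = n_atoms(mol)) {
  stopifnot(inherits(mol, "molecule"))
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 3L) stop("min_len must be >= 3 (shortest stretch is 3 atoms)")
  if (max_len < min_len) stop("max_len must be >= min_len")
  adj <- adjacency_list(mol)
  n <- n_atoms(mol)
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 256L)
  acc$count <- 0L
  visited <- logical(n)

  record <- function(path) {
    # keep one orientation per undirected path
    if (vec_lex_less(path, rev(path))) {
      acc$count <- acc$count + 1L
      if (acc$count > length(acc$paths)) {
        acc$paths <- c(acc$paths, vector("list", length(acc$paths)))
      }
      acc$paths[[acc$count]] <- path
    }
  }

  dfs <- function(path) {
    L <- length(path)
    if (L >= min_len) record(path)
    if (L == max_len) return(invisible())
    for (nb in adj[[path[L]]]) {
      if (!visited[nb]) {
        visited[nb] <<- TRUE
        dfs(c(path, nb))
        visited[nb] <<- FALSE
      }
    }
  }

  for (s in seq_len(n)) {
    visited[s] <- TRUE
    dfs(s)
    visited[s] <- FALSE
  }

  paths <- acc$paths[seq_len(acc$count)]
  lapply(paths, function(p) list(atoms = p, key = element_key(mol$elements[p])))
}

#' Sorted pairwise-distance fingerprint
#'
#' The non-decreasing list of all pairwise Euclidean distances within an atom
#' set: a geometric signature invariant under rigid motion and under
#' permutation of the atoms.
#'
#' @param mol A `molecule`.
#' @param atom_set Integer vector of distinct atom indices (>= 2).
#' @return Sorted numeric vector of length `n*(n-1)/2` (Angstrom).
#' @export
fingerprint <- function(mol, atom_set) {
  atom_set <- as.integer(atom_set)
  if (anyDuplicated(atom_set)) stop("atom_set contains duplicate indices")
  if (length(atom_set) < 2L) stop("fingerprint needs >= 2 atoms")
  sort(as.numeric(stats::dist(mol$coords[atom_set, , drop = FALSE])))
}

#' Compare two distance fingerprints
#'
#' @param fa,fb Sorted distance fingerprints.
#' @param tol Per-distance tolerance in Angstrom (>= 0).
#' @return TRUE iff the fingerprints have equal length and agree element-wise
#'   within `tol`.
#' @export
fingerprints_match <- function(fa, fb, tol) {
  if (tol < 0) stop("tol must be >= 0")
  length(fa) == length(fb) && all(abs(fa - fb) <= tol)
}

#' Verify atom-to-atom mappings between two matched stretches
#'
#' The sorted fingerprint discards atom correspondence; this recovers it.
#' The two path orientations (forward and reversed) are tested: a mapping is
#' returned iff it is element-preserving and every corresponding unsorted
#' pairwise distance agrees within `tol`.
#'
#' @param mol_a,mol_b Parent molecules.
#' @param path_a,path_b Integer atom-index vectors of equal length (the two
#'   stretches).
#' @param tol Distance tolerance in Angstrom.
#' @return A list of verified mappings; each mapping is an integer vector `m`
#'   with `m[k]` the atom of `mol_b` matched to `path_a[k]`.
#' @export
verify_mappings <- function(mol_a, path_a, mol_b, path_b, tol) {
  path_a <- as.integer(path_a); path_b <- as.integer(path_b)
  if (length(path_a) != length(path_b)) stop("paths must have equal length")
  ea <- mol_a$elements[path_a]
  ca <- mol_a$coords[path_a, , drop = FALSE]
  da <- as.matrix(stats::dist(ca))
  out <- list()
  for (pb in list(path_b, rev(path_b))) {
    if (!all(ea == mol_b$elements[pb])) next
    db <- as.matrix(stats::dist(mol_b$coords[pb, , drop = FALSE]))
    if (all(abs(da - db) <= tol)) out[[length(out) + 1L]] <- pb
    if (identical(path_b, rev(path_b))) break
  }
  # drop an exact duplicate (possible only for palindromic degenerate cases)
  if (length(out) == 2L && identical(out[[1L]], out[[2L]])) out <- out[1L]
  out
}

# Re-express a mapping aligned to `path` as a mapping aligned to the sorted
# atom set `ref` (ref is a permutation of path).
align_mapping <- function(ref, path, map) map[match(ref, path)]

#' Find the maximum geometric common substructure of two molecules
#'
#' Searches descending candidate sizes from `min(n_A, n_B)` down to
#' `min_size`. At each size, stretches with a shared element key are compared
#' by sorted-distance fingerprint and confirmed by explicit mapping
#' verification; the first size with any verified pair defines the MCS. All
#' verified pairs at that size are collected and deduplicated by their atom
#' sets; each retained candidate carries every verified mapping found for it.
#' Candidate keys and path pairs are processed in lexicographic order, so the
#' result is deterministic.
#'
#' Molecules should be hydrogen-stripped and carry bond graphs. A
#' disconnected molecule triggers a warning and the search is restricted to
#' its largest connected component (atom indices still refer to the input).
#'
#' @param mol_a,mol_b Heavy-atom `molecule`s with bonds.
#' @param min_size Smallest admissible common substructure, in atoms (>= 3).
#' @param tol Per-distance tolerance in Angstrom (default 0.1).
#' @param max_path_len Optional cap on enumerated path length (with a
#'   warning); protects against pathological fused-ring graphs.
#' @return An object of class `mcs_result`: fields `size`, `tolerance`, and
#'   `candidates`, a list of `mcs_match` objects (fields `atoms_a`, `atoms_b`
#'   -- sorted index vectors -- `mappings`, `fingerprint`, `tolerance`).
#' @export
find_mcs <- function(mol_a, mol_b, min_size = 3L, tol = 0.1,
                     max_path_len = NULL) {
  stopifnot(inherits(mol_a, "molecule"), inherits(mol_b, "molecule"))
  min_size <- as.integer(min_size)
  if (min_size < 3L) stop("min_size must be >= 3")

  comp_mask <- function(mol) {
    comp <- graph_components(n_atoms(mol), mol$bonds)
    if (max(comp) == 1L) return(rep(TRUE, n_atoms(mol)))
    sizes <- tabulate(comp)
    warning(sprintf(
      "molecule '%s' is disconnected; MCS search restricted to its largest component (%d atoms)",
      mol$name, max(sizes)))
    comp == which.max(sizes)
  }
  in_a <- comp_mask(mol_a)
  in_b <- comp_mask(mol_b)

  smax <- min(sum(in_a), sum(in_b))
  if (!is.null(max_path_len) && max_path_len < smax) {
    warning("path length capped at ", max_path_len,
            " atoms; substructures larger than the cap cannot be found")
    smax <- as.integer(max_path_len)
  }
  if (smax < min_size) {
    stop(errorCondition(
      sprintf("no MCS found: no common substructure of >= %d atoms", min_size),
      class = c("ligmerge_no_mcs", "error", "condition")))
  }

  index_paths <- function(mol, mask) {
    ps <- enumerate_paths(mol, 3L, smax)
    ps <- Filter(function(p) all(mask[p$atoms]), ps)
    by_len <- split(ps, vapply(ps, function(p) length(p$atoms), integer(1)))
    lapply(by_len, function(grp) {
      split(grp, vapply(grp, `[[`, character(1), "key"))
    })
  }
  pa <- index_paths(mol_a, in_a)
  pb <- index_paths(mol_b, in_b)

  sort_paths <- function(grp) {
    m <- do.call(rbind, lapply(grp, `[[`, "atoms"))
    grp[do.call(order, as.data.frame(m))]
  }

  for (s in seq(smax, min_size)) {
    ga <- pa[[as.character(s)]]
    gb <- pb[[as.character(s)]]
    if (is.null(ga) || is.null(gb)) next
    keys <- sort(intersect(names(ga), names(gb)))
    if (length(keys) == 0L) next

    cands <- new.env(parent = emptyenv())
    order_keys <- character(0)
    for (key in keys) {
      la <- sort_paths(ga[[key]])
      lb <- sort_paths(gb[[key]])
      fpa <- lapply(la, function(p) fingerprint(mol_a, p$atoms))
      fpb <- lapply(lb, function(p) fingerprint(mol_b, p$atoms))
      for (i in seq_along(la)) {
        for (j in seq_along(lb)) {
          if (!fingerprints_match(fpa[[i]], fpb[[j]], tol)) next
          maps <- verify_mappings(mol_a, la[[i]]$atoms, mol_b, lb[[j]]$atoms,
                                  tol)
          if (length(maps) == 0L) next
          aa <- sort(la[[i]]$atoms)
          for (m in maps) {
            mm <- align_mapping(aa, la[[i]]$atoms, m)
            ck <- paste(paste(aa, collapse = ","),
                        paste(sort(mm), collapse = ","), sep = "|")
            if (!is.null(cands[[ck]])) {
              sigs <- vapply(cands[[ck]]$mappings,
                             function(x) paste(x, collapse = ","),
                             character(1))
              if (!(paste(mm, collapse = ",") %in% sigs)) {
                cands[[ck]]$mappings <- c(cands[[ck]]$mappings, list(mm))
              }
            } else {
              order_keys <- c(order_keys, ck)
              cands[[ck]] <- list(atoms_a = aa, atoms_b = sort(mm),
                                  mappings = list(mm))
            }
          }
        }
      }
    }

    if (length(order_keys) > 0L) {
      order_keys <- sort(order_keys)
      candidates <- lapply(order_keys, function(ck) {
        c0 <- cands[[ck]]
        structure(
          list(atoms_a = c0$atoms_a, atoms_b = c0$atoms_b,
               mappings = c0$mappings, tolerance = tol,
               fingerprint = fingerprint(mol_a, c0$atoms_a)),
          class = "mcs_match")
      })
      return(structure(list(size = s, tolerance = tol,
                            candidates = candidates),
                       class = "mcs_result"))
    }
  }

  stop(errorCondition(
    sprintf("no MCS found: no common substructure of >= %d atoms", min_size),
    class = c("ligmerge_no_mcs", "error", "condition")))
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<MCS: %d atoms, %d candidate(s), tolerance %.3g A>\n",
              x$size, length(x$candidates), x$tolerance))
  invisible(x)
}

# Is `mapping` a valid element- and distance-preserving bijection for this
# match? Used to validate user-supplied mappings.
mapping_is_verified <- function(match, mol_a, mol_b, mapping) {
  mapping <- as.integer(mapping)
  if (length(mapping) != length(match$atoms_a)) return(FALSE)
  if (!setequal(mapping, match$atoms_b)) return(FALSE)
  if (!all(mol_a$elements[match$atoms_a] == mol_b$elements[mapping])) {
    return(FALSE)
  }
  da <- as.matrix(stats::dist(mol_a$coords[match$atoms_a, , drop = FALSE]))
  db <- as.matrix(stats::dist(mol_b$coords[mapping, , drop = FALSE]))
  all(abs(da - db) <= match$tolerance)
}

#' Enumerate all symmetry-consistent atom mappings of an MCS
#'
#' Backtracking enumeration of every element-preserving bijection from the
#' match's A-side atoms onto its B-side atoms under which all pairwise
#' distances agree within `tol`. For symmetric substructures (rings, a
#' toluene scaffold) several such mappings exist, each giving a distinct
#' superimposition of the parents.
#'
#' @param match An `mcs_match` candidate (from [find_mcs()]).
#' @param mol_a,mol_b The parent molecules.
#' @param tol Distance tolerance in Angstrom (defaults to the match's).
#' @return A list of mappings (integer vectors aligned to `match$atoms_a`),
#'   in deterministic order; a superset of `match$mappings`.
#' @export
enumerate_symmetry_mappings <- function(match, mol_a, mol_b,
                                        tol = match$tolerance) {
  stopifnot(inherits(match, "mcs_match"))
  aa <- match$atoms_a
  bb <- match$atoms_b
  n <- length(aa)
  ea <- mol_a$elements[aa]
  eb <- mol_b$elements[bb]
  da <- as.matrix(stats::dist(mol_a$coords[aa, , drop = FALSE]))
  db_full <- as.matrix(stats::dist(mol_b$coords[bb, , drop = FALSE]))

  out <- list()
  assign_b <- integer(n)  # positions into bb
  used <- logical(n)
  bt <- function(k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- bb[assign_b]
      return(invisible())
    }
    for (p in seq_len(n)) {
      if (used[p] || eb[p] != ea[k]) next
      ok <- TRUE
      if (k > 1L) {
        prev <- seq_len(k - 1L)
        if (any(abs(da[k, prev] - db_full[p, assign_b[prev]]) > tol)) {
          ok <- FALSE
        }
      }
      if (ok) {
        used[p] <<- TRUE
        assign_b[k] <<- p
        bt(k + 1L)
        used[p] <<- FALSE
      }
    }
  }
  bt(1L)
  out
}
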