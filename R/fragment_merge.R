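# Fragment extraction and recombination: substituent moieties hanging off
# the common substructure are identified in each parent, per-handle parent
# choices are enumerated (respecting multiple-handle fragments), clashing
# combinations are rejected, and the survivors are assembled into merged
# molecules in parent A's frame.

#' Extract substituent fragments relative to a common substructure
#'
#' Fragments are the connected components of the bond graph induced by the
#' non-MCS atoms. Each fragment records its anchors: every bond crossing
#' from the fragment into the MCS, as (handle atom, fragment atom) pairs.
#' A fragment anchored to two or more distinct handle atoms is a
#' multiple-handle fragment.
#'
#' @param mol A `molecule`.
#' @param mcs_atoms Integer vector of the molecule's MCS atom indices.
#' @return A list of fragments, each a list with `atoms` (integer vector)
#'   and `anchors` (two-column matrix: `handle`, `fragment_atom`).
#' @export
extract_fragments <- function(mol, mcs_atoms) {
  mcs_atoms <- as.integer(mcs_atoms)
  n <- n_atoms(mol)
  if (any(mcs_atoms < 1L) || any(mcs_atoms > n)) {
    stop("mcs_atoms out of range")
  }
  non <- setdiff(seq_len(n), mcs_atoms)
  if (length(non) == 0L) return(list())

  in_non <- seq_len(n) %in% non
  sub_bonds <- mol$bonds[in_non[mol$bonds[, 1L]] & in_non[mol$bonds[, 2L]], ,
                         drop = FALSE]
  # reindex into the induced subgraph
  sub_index <- integer(n); sub_index[non] <- seq_along(non)
  comp <- graph_components(length(non),
                           normalize_bonds(cbind(sub_index[sub_bonds[, 1L]],
                                                 sub_index[sub_bonds[, 2L]]),
                                           length(non)))
  cross <- mol$bonds[xor(in_non[mol$bonds[, 1L]], in_non[mol$bonds[, 2L]]), ,
                     drop = FALSE]
  frags <- lapply(seq_len(max(comp)), function(k) {
    atoms <- non[comp == k]
    in_frag_1 <- cross[, 1L] %in% atoms
    in_frag_2 <- cross[, 2L] %in% atoms
    anchors <- rbind(
      cbind(handle = cross[in_frag_2, 1L],
            fragment_atom = cross[in_frag_2, 2L]),
      cbind(handle = cross[in_frag_1, 2L],
            fragment_atom = cross[in_frag_1, 1L]))
    if (nrow(anchors) == 0L) {
      stop("structural error: a non-MCS component of '", mol$name,
           "' has no bond into the common substructure")
    }
    anchors <- anchors[order(anchors[, 1L], anchors[, 2L]), , drop = FALSE]
    list(atoms = atoms, anchors = anchors)
  })
  frags
}

#' Identify handle atoms for one superimposed overlay
#'
#' A handle atom is an MCS atom carrying at least one substituent fragment in
#' either parent. Handles are expressed as MCS positions (indices into
#' `match$atoms_a`); the corresponding parent-B atom is taken through the
#' symmetry mapping in force.
#'
#' @param match An `mcs_match`.
#' @param mapping The verified mapping used for this overlay.
#' @param fragments_a,fragments_b Fragment lists from [extract_fragments()].
#' @return A list of handles: `pos` (MCS position), `atom_a`, `atom_b`,
#'   `frags_a`, `frags_b` (indices into the fragment lists).
#' @export
handle_atoms <- function(match, mapping, fragments_a, fragments_b) {
  stopifnot(inherits(match, "mcs_match"))
  mapping <- as.integer(mapping)
  handles <- list()
  for (k in seq_along(match$atoms_a)) {
    a_atom <- match$atoms_a[k]
    b_atom <- mapping[k]
    fa <- which(vapply(fragments_a,
                       function(f) a_atom %in% f$anchors[, "handle"],
                       logical(1)))
    fb <- which(vapply(fragments_b,
                       function(f) b_atom %in% f$anchors[, "handle"],
                       logical(1)))
    if (length(fa) > 0L || length(fb) > 0L) {
      handles[[length(handles) + 1L]] <-
        list(pos = k, atom_a = a_atom, atom_b = b_atom,
             frags_a = fa, frags_b = fb)
    }
  }
  handles
}

# Positions (among `handles`) at which fragment `fi` of parent `parent`
# is anchored.
fragment_handle_positions <- function(handles, parent, fi) {
  field <- if (parent == "A") "frags_a" else "frags_b"
  which(vapply(handles, function(h) fi %in% h[[field]], logical(1)))
}

plan_selection <- function(handles, choice) {
  sel <- list()
  for (i in seq_along(handles)) {
    parent <- choice[i]
    fis <- if (parent == "A") handles[[i]]$frags_a else handles[[i]]$frags_b
    for (fi in fis) sel[[length(sel) + 1L]] <- c(parent = parent, idx = fi)
  }
  if (length(sel) == 0L) return(character(0))
  unique(vapply(sel, function(s) paste0(s[["parent"]], s[["idx"]]),
                character(1)))
}

#' Enumerate consistent per-handle merge plans
#'
#' Each handle selects a parent (A or B) and inherits that parent's full
#' substituent set at that handle; a handle where the chosen parent has no
#' substituent is left bare (an implicit open valence). Plans in which a
#' multiple-handle fragment would be selected at some but not all of its
#' handle atoms are never emitted. Plans selecting identical fragment
#' content are collapsed to one.
#'
#' @param handles Handle list from [handle_atoms()].
#' @param fragments_a,fragments_b Fragment lists (for consistency checks).
#' @param all_combinations If TRUE, return every consistent deduplicated
#'   plan (the full cross-product of per-handle choices); if FALSE, return a
#'   single uniformly random consistent plan drawn with `rng_seed`.
#' @param rng_seed Seed for the single-plan draw (default 0).
#' @return A list of plans, each with `choice` (character vector over
#'   handles), `fragments` (selected fragment ids, e.g. `"A1"`), and
#'   `signature`.
#' @export
enumerate_plans <- function(handles, fragments_a, fragments_b,
                            all_combinations = TRUE, rng_seed = 0L) {
  h <- length(handles)
  if (h == 0L) {
    plans <- list(list(choice = character(0), fragments = character(0),
                       signature = ""))
    return(plans)
  }

  # handle sets of multiple-handle fragments (by parent)
  multi <- list()
  for (parent in c("A", "B")) {
    frs <- if (parent == "A") fragments_a else fragments_b
    for (fi in seq_along(frs)) {
      pos <- fragment_handle_positions(handles, parent, fi)
      if (length(pos) >= 2L) multi[[length(multi) + 1L]] <- pos
    }
  }

  grid <- expand.grid(rep(list(c("A", "B")), h), stringsAsFactors = FALSE)
  consistent <- vapply(seq_len(nrow(grid)), function(r) {
    ch <- as.character(grid[r, ])
    all(vapply(multi, function(pos) length(unique(ch[pos])) == 1L,
               logical(1)))
  }, logical(1))
  grid <- grid[consistent, , drop = FALSE]

  plans <- list()
  seen <- character(0)
  for (r in seq_len(nrow(grid))) {
    ch <- as.character(grid[r, ])
    frag_ids <- sort(plan_selection(handles, ch))
    sig <- paste(frag_ids, collapse = ";")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    plans[[length(plans) + 1L]] <-
      list(choice = ch, fragments = frag_ids, signature = sig)
  }

  if (!all_combinations) {
    pick <- with_seed(rng_seed, sample.int(length(plans), 1L))
    plans <- plans[pick]
  }
  plans
}

#' Assemble a merged molecule from a plan
#'
#' The MCS atoms are copied from parent A (A's frame is the output frame);
#' chosen A-fragments are copied verbatim and chosen B-fragments carry their
#' superposed coordinates. Intra-MCS bonds come from A, intra-fragment bonds
#' from the owning parent, and each anchor bond is re-created between the
#' fragment atom and its handle atom.
#'
#' @param mol_a Parent A.
#' @param superposed_b Parent B already transformed into A's frame.
#' @param match The `mcs_match` used.
#' @param mapping The symmetry mapping in force.
#' @param plan A plan from [enumerate_plans()].
#' @param fragments_a,fragments_b Fragment lists of the two parents.
#' @return An object of class `merged_molecule`: fields `molecule`,
#'   `fragment_of` (per-atom fragment label, NA for MCS atoms), `plan`,
#'   and `provenance`.
#' @export
assemble_merged <- function(mol_a, superposed_b, match, mapping, plan,
                            fragments_a, fragments_b) {
  stopifnot(inherits(match, "mcs_match"))
  mapping <- as.integer(mapping)
  aa <- match$atoms_a
  n_mcs <- length(aa)

  elements <- mol_a$elements[aa]
  coords <- mol_a$coords[aa, , drop = FALSE]
  frag_label <- rep(NA_character_, n_mcs)

  # new index of each parent atom that enters the merged molecule
  new_of_a <- integer(n_atoms(mol_a))
  new_of_a[aa] <- seq_len(n_mcs)
  new_of_b <- integer(n_atoms(superposed_b))
  new_of_b[mapping] <- seq_len(n_mcs)

  bonds <- mol_a$bonds[mol_a$bonds[, 1L] %in% aa &
                       mol_a$bonds[, 2L] %in% aa, , drop = FALSE]
  bonds <- cbind(new_of_a[bonds[, 1L]], new_of_a[bonds[, 2L]])

  handle_sig <- character(0)
  for (fid in plan$fragments) {
    parent <- substr(fid, 1L, 1L)
    fi <- as.integer(substr(fid, 2L, nchar(fid)))
    frag <- if (parent == "A") fragments_a[[fi]] else fragments_b[[fi]]
    src <- if (parent == "A") mol_a else superposed_b
    new_of <- if (parent == "A") new_of_a else new_of_b

    offset <- length(elements)
    idx_in_frag <- stats::setNames(offset + seq_along(frag$atoms),
                                   as.character(frag$atoms))
    elements <- c(elements, src$elements[frag$atoms])
    coords <- rbind(coords, src$coords[frag$atoms, , drop = FALSE])
    frag_label <- c(frag_label, rep(fid, length(frag$atoms)))

    fb <- src$bonds[src$bonds[, 1L] %in% frag$atoms &
                    src$bonds[, 2L] %in% frag$atoms, , drop = FALSE]
    if (nrow(fb) > 0L) {
      bonds <- rbind(bonds, cbind(idx_in_frag[as.character(fb[, 1L])],
                                  idx_in_frag[as.character(fb[, 2L])]))
    }
    for (r in seq_len(nrow(frag$anchors))) {
      handle_new <- new_of[frag$anchors[r, "handle"]]
      bonds <- rbind(bonds, cbind(handle_new,
                                  idx_in_frag[as.character(
                                    frag$anchors[r, "fragment_atom"])]))
      handle_sig <- c(handle_sig, sprintf("%s@%d", fid, aa[handle_new]))
    }
  }

  # content signature in the A frame: which fragment atom sets sit at which
  # A-side handle atoms (collapses identical selections across overlays)
  content_sig <- paste(sort(handle_sig), collapse = ";")
  frag_atoms_sig <- paste(sort(vapply(plan$fragments, function(fid) {
    parent <- substr(fid, 1L, 1L)
    fi <- as.integer(substr(fid, 2L, nchar(fid)))
    frag <- if (parent == "A") fragments_a[[fi]] else fragments_b[[fi]]
    sprintf("%s{%s}", fid, paste(frag$atoms, collapse = ","))
  }, character(1))), collapse = ";")

  mol <- molecule(elements, coords, bonds,
                  name = sprintf("%s__%s", mol_a$name, superposed_b$name),
                  provenance = sprintf(
                    "merged: MCS %d atoms from '%s'; fragments [%s]",
                    n_mcs, mol_a$name, plan$signature))
  structure(
    list(molecule = mol, fragment_of = frag_label, plan = plan,
         provenance = list(parent_a = mol_a$name, parent_b = superposed_b$name,
                           content_signature = paste(frag_atoms_sig,
                                                     content_sig, sep = "||"))),
    class = "merged_molecule")
}

#' @export
print.merged_molecule <- function(x, ...) {
  cat(sprintf("<merged molecule: %d atoms (%d MCS), fragments [%s]>\n",
              n_atoms(x$molecule), sum(is.na(x$fragment_of)),
              x$plan$signature))
  invisible(x)
}

#' Test a merged molecule for steric clashes between fragments
#'
#' TRUE iff any heavy-atom pair drawn from two different chosen fragments
#' lies closer than `clash_cutoff`. Pairs involving MCS atoms and pairs
#' within one fragment are exempt (anchor bonds are legitimately short).
#'
#' @param merged A `merged_molecule`.
#' @param clash_cutoff Distance threshold in Angstrom (> 0; default 2.0).
#' @return Logical.
#' @export
has_clash <- function(merged, clash_cutoff = 2.0) {
  stopifnot(inherits(merged, "merged_molecule"))
  if (clash_cutoff <= 0) stop("clash_cutoff must be > 0")
  lab <- merged$fragment_of
  idx <- which(!is.na(lab))
  if (length(idx) < 2L) return(FALSE)
  d <- as.matrix(stats::dist(merged$molecule$coords[idx, , drop = FALSE]))
  li <- lab[idx]
  differ <- outer(li, li, "!=")
  any(d[differ & upper.tri(d)] < clash_cutoff)
}

#' Merge two ligands: the full hybridization pipeline
#'
#' Strips hydrogens, perceives bonds (keeping any CONECT bonds), finds the
#' maximum geometric common substructure, superimposes parent B onto parent
#' A under each symmetry-consistent mapping (or one seed-chosen mapping),
#' enumerates consistent substituent combinations per overlay, drops
#' clashing combinations, and deduplicates the resulting hybrid molecules
#' across overlays and MCS candidates.
#'
#' @param mol_a,mol_b Input `molecule`s (hydrogens allowed; they are
#'   stripped).
#' @param min_mcs_size Minimum common substructure size in atoms (>= 3).
#' @param tolerance Per-distance MCS tolerance in Angstrom (default 0.1).
#' @param clash_cutoff Inter-fragment clash threshold in Angstrom
#'   (default 2.0).
#' @param all_symmetry_relations Consider every symmetry mapping (TRUE) or a
#'   single seed-chosen one (FALSE).
#' @param all_substituent_combinations Generate every consistent fragment
#'   combination (TRUE) or one random combination per overlay (FALSE).
#' @param output_mcs Also return the MCS itself as a molecule.
#' @param rng_seed Seed for the random choices (default 0).
#' @param bond_slack Slack for distance-based bond perception (Angstrom).
#' @param max_path_len Optional cap on stretch length during MCS search.
#' @return An object of class `ligmerge_result`: `merged` (list of
#'   `merged_molecule`), `mcs` (the `mcs_result`), optionally
#'   `mcs_molecule`, and `summary` (named counts including
#'   `plans_skipped_clash`).
#' @export
merge_pair <- function(mol_a, mol_b, min_mcs_size = 3L, tolerance = 0.1,
                       clash_cutoff = 2.0, all_symmetry_relations = TRUE,
                       all_substituent_combinations = TRUE,
                       output_mcs = FALSE, rng_seed = 0L, bond_slack = 0.45,
                       max_path_len = NULL) {
  a <- strip_hydrogens(mol_a)
  b <- strip_hydrogens(mol_b)
  a <- perceive_bonds(a, bond_slack)
  b <- perceive_bonds(b, bond_slack)

  mcs <- find_mcs(a, b, min_size = min_mcs_size, tol = tolerance,
                  max_path_len = max_path_len)

  merged_out <- list()
  seen <- character(0)
  plans_total <- 0L
  skipped <- 0L
  mapping_count <- 0L

  for (ci in seq_along(mcs$candidates)) {
    cand <- mcs$candidates[[ci]]
    syms <- enumerate_symmetry_mappings(cand, a, b)
    if (!all_symmetry_relations && length(syms) > 1L) {
      pick <- with_seed(rng_seed + ci, sample.int(length(syms), 1L))
      syms <- syms[pick]
    }
    mapping_count <- mapping_count + length(syms)
    frags_a <- extract_fragments(a, cand$atoms_a)
    frags_b <- extract_fragments(b, cand$atoms_b)

    for (mi in seq_along(syms)) {
      mapping <- syms[[mi]]
      sup <- superpose_on_mcs(a, b, cand, mapping)
      handles <- handle_atoms(cand, mapping, frags_a, frags_b)
      plans <- enumerate_plans(handles, frags_a, frags_b,
                               all_combinations = all_substituent_combinations,
                               rng_seed = rng_seed + 1000L * ci + mi)
      plans_total <- plans_total + length(plans)
      for (pi in seq_along(plans)) {
        mm <- assemble_merged(a, sup$molecule, cand, mapping, plans[[pi]],
                              frags_a, frags_b)
        if (has_clash(mm, clash_cutoff)) {
          skipped <- skipped + 1L
          next
        }
        key <- paste(paste(cand$atoms_a, collapse = ","),
                     mm$provenance$content_signature, sep = "##")
        if (key %in% seen) next
        seen <- c(seen, key)
        mm$provenance$mcs_candidate <- ci
        mm$provenance$mapping_id <- mi
        mm$provenance$plan_id <- pi
        mm$provenance$superposition_rmsd <- sup$rmsd
        merged_out[[length(merged_out) + 1L]] <- mm
      }
    }
  }

  if (length(merged_out) == 0L) {
    warning("all fragment combinations were skipped for steric clashes; ",
            "no merged molecules generated")
  }

  res <- list(
    merged = merged_out,
    mcs = mcs,
    summary = c(mcs_size = mcs$size,
                mcs_candidates = length(mcs$candidates),
                mappings = mapping_count,
                plans = plans_total,
                plans_skipped_clash = skipped,
                molecules = length(merged_out)))
  if (output_mcs) {
    res$mcs_molecule <- subset_molecule(a, mcs$candidates[[1L]]$atoms_a,
                                        note = "maximum common substructure")
    res$mcs_molecule$name <- paste0(a$name, "__", b$name, "__mcs")
  }
  structure(res, class = "ligmerge_result")
}

#' @export
print.ligmerge_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ligand merge: MCS %d atoms (%d candidate(s), %d mapping(s)); %d plan(s), %d clash-skipped; %d merged molecule(s)>\n",
    s[["mcs_size"]], s[["mcs_candidates"]], s[["mappings"]], s[["plans"]],
    s[["plans_skipped_clash"]], s[["molecules"]]))
  invisible(x)
}

#' Write merged molecules to PDB files
#'
#' Filenames follow `<A-stem>__<B-stem>__mcs<k>_map<m>_plan<p>.pdb`, where
#' k, m, p identify the MCS candidate, symmetry mapping, and substituent
#' plan that produced each molecule.
#'
#' @param result A `ligmerge_result`.
#' @param dir Output directory (created if needed).
#' @param stem_a,stem_b Filename stems for the two parents (default: their
#'   molecule names).
#' @return Character vector of the files written.
#' @export
write_merged <- function(result, dir, stem_a = NULL, stem_b = NULL) {
  stopifnot(inherits(result, "ligmerge_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (mm in result$merged) {
    sa <- stem_a %||% mm$provenance$parent_a
    sb <- stem_b %||% mm$provenance$parent_b
    fn <- file.path(dir, sprintf("%s__%s__mcs%d_map%d_plan%d.pdb",
                                 sa, sb, mm$provenance$mcs_candidate,
                                 mm$provenance$mapping_id,
                                 mm$provenance$plan_id))
    write_pdb(mm$molecule, fn)
    files <- c(files, fn)
  }
  if (!is.null(result$mcs_molecule)) {
    fn <- file.path(dir, paste0(result$mcs_molecule$name, ".pdb"))
    write_pdb(result$mcs_molecule, fn)
    files <- c(files, fn)
  }
  files
}
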