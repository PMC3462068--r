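# Molecular data model: heavy-atom 3D structures with a bond graph,
# PDB v3.3 reading/writing, distance-based bond perception, and
# hydrogen stripping.

# Single-bond covalent radii in Angstrom (Cordero et al. consensus values),
# keyed by uppercase element symbol. D is treated as H.
.covalent_radii <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, AS = 1.19, SE = 1.20,
  BR = 1.20, I = 1.39
)

canonical_element <- function(x) toupper(trimws(x))

#' Covalent radius of an element
#'
#' Looks up the single-bond covalent radius used for distance-based bond
#' perception. Symbols are matched case-insensitively.
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  element <- canonical_element(element)
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    missing <- unique(element[is.na(r)])
    stop("no covalent radius known for element(s): ",
         paste(missing, collapse = ", "))
  }
  unname(r)
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2L) stop("bonds must be a two-column matrix")
  storage.mode(bonds) <- "integer"
  if (anyNA(bonds)) stop("bond endpoints must be integers")
  if (any(bonds < 1L) || any(bonds > n_atoms)) {
    stop("bond endpoint out of range (atoms are indexed 1..", n_atoms, ")")
  }
  if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bonds are not allowed")
  ab <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  ab <- unique(ab)
  ab <- ab[order(ab[, 1L], ab[, 2L]), , drop = FALSE]
  colnames(ab) <- c("a", "b")
  ab
}

#' Construct a molecule
#'
#' A molecule is a heavy-atom-capable 3D structure: element symbols, Cartesian
#' coordinates in Angstrom, and an undirected bond graph. Bonds are stored
#' deduplicated with the smaller atom index first.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix with one row per atom and columns x, y, z (A).
#' @param bonds Two-column integer matrix of bonded atom-index pairs, or NULL.
#' @param name Label for the molecule (defaults to "mol").
#' @param provenance Character vector recording operations applied so far.
#' @return An object of class `molecule`.
#' @export
molecule <- function(elements, coords, bonds = NULL, name = "mol",
                     provenance = character()) {
  elements <- canonical_element(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (length(elements) == 0L) stop("empty model: a molecule needs >= 1 atom")
  if (ncol(coords) != 3L) stop("coords must have three columns (x, y, z)")
  if (nrow(coords) != length(elements)) {
    stop("coords must have one row per element")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(
    list(name = name, elements = elements, coords = coords,
         bonds = normalize_bonds(bonds, length(elements)),
         provenance = provenance),
    class = "molecule"
  )
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' @export
print.molecule <- function(x, ...) {
  tab <- table(x$elements)
  cat(sprintf("<molecule '%s': %d atoms (%s), %d bonds>\n",
              x$name, n_atoms(x),
              paste(sprintf("%s%d", names(tab), tab), collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

distance_matrix <- function(mol) as.matrix(stats::dist(mol$coords))

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, 1L]; b <- mol$bonds[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

# Connected-component membership by breadth-first search.
graph_components <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1L]; b <- bonds[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Keep a subset of atoms (ascending indices), reindexing atoms and bonds.
subset_molecule <- function(mol, keep, note = NULL) {
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L) stop("empty model: no atoms left after subsetting")
  new_index <- integer(n_atoms(mol))
  new_index[keep] <- seq_along(keep)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    ok <- b[, 1L] %in% keep & b[, 2L] %in% keep
    b <- cbind(new_index[b[ok, 1L]], new_index[b[ok, 2L]])
  }
  prov <- c(mol$provenance,
            note %||% paste0("subset to atoms [",
                             paste(keep, collapse = ","), "]"))
  molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE], b,
           name = mol$name, provenance = prov)
}

largest_component <- function(mol) {
  comp <- graph_components(n_atoms(mol), mol$bonds)
  if (max(comp) == 1L) return(mol)
  sizes <- tabulate(comp)
  keep_comp <- which.max(sizes)
  warning(sprintf(
    "molecule '%s' has %d disconnected components; using the largest (%d of %d atoms)",
    mol$name, max(comp), sizes[keep_comp], n_atoms(mol)))
  subset_molecule(mol, which(comp == keep_comp),
                  note = "restricted to largest connected component")
}

infer_element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  if (nchar(nm) == 0L) stop("cannot infer element from atom name '",
                            atom_name, "'")
  nm <- toupper(nm)
  two <- substr(nm, 1L, 2L)
  if (nchar(nm) >= 2L && two %in% names(.covalent_radii) &&
      nchar(two) == 2L && !(two %in% c("CA", "CD", "CE", "CG", "CB", "NA",
                                       "ND", "NE", "OD", "OE", "OG", "SD",
                                       "SG", "HB", "HD", "HE", "HG"))) {
    return(two)
  }
  substr(nm, 1L, 1L)
}

#' Read a small molecule from a PDB file
#'
#' Parses ATOM/HETATM records from a PDB v3.3 fixed-column file. Coordinates
#' come from columns 31-54; the element symbol from columns 77-78 when
#' present, otherwise it is inferred from the atom-name field. CONECT records,
#' if present, populate the bond graph (deduplicated and symmetric). Only the
#' first MODEL of a multi-model file is read (with a warning), and atoms with
#' an alternate-location indicator other than blank or 'A' are skipped.
#'
#' @param path Path to a PDB file.
#' @return A `molecule`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1L, 6L)
  model_idx <- which(trimws(rec) == "MODEL")
  if (length(model_idx) > 1L) {
    warning("multi-model file: reading only the first MODEL in ", path)
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl) > 0L) endmdl[1L] else model_idx[2L]
    keep <- seq_len(stop_at - 1L)
    lines <- lines[keep]
    rec <- rec[keep]
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  atom_lines <- lines[is_atom]
  if (length(atom_lines) == 0L) stop("empty model: no ATOM/HETATM records in ",
                                     path)

  alt <- substr(atom_lines, 17L, 17L)
  keep <- alt %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  if (length(atom_lines) == 0L) {
    stop("empty model: all atoms carry skipped alternate locations in ", path)
  }

  n <- length(atom_lines)
  serials <- suppressWarnings(as.integer(substr(atom_lines, 7L, 11L)))
  names_f <- substr(atom_lines, 13L, 16L)
  xs <- suppressWarnings(as.numeric(substr(atom_lines, 31L, 38L)))
  ys <- suppressWarnings(as.numeric(substr(atom_lines, 39L, 46L)))
  zs <- suppressWarnings(as.numeric(substr(atom_lines, 47L, 54L)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0L) {
    stop("unparseable coordinate field in line: ", atom_lines[bad[1L]])
  }

  elem_field <- trimws(substr(atom_lines, 77L, 78L))
  elements <- character(n)
  for (i in seq_len(n)) {
    elements[i] <- if (nchar(elem_field[i]) > 0L) {
      canonical_element(elem_field[i])
    } else {
      infer_element_from_name(names_f[i])
    }
  }

  # serial -> 1-based atom index (duplicated serials keep the first)
  serial_map <- integer(0)
  if (!anyNA(serials)) {
    serial_map <- stats::setNames(seq_len(n), as.character(serials))
    serial_map <- serial_map[!duplicated(names(serial_map))]
  }

  bonds <- matrix(integer(), ncol = 2L)
  conect <- lines[rec == "CONECT"]
  if (length(conect) > 0L && length(serial_map) > 0L) {
    pairs <- list()
    for (ln in conect) {
      fields <- c(substr(ln, 7L, 11L), substr(ln, 12L, 16L),
                  substr(ln, 17L, 21L), substr(ln, 22L, 26L),
                  substr(ln, 27L, 31L))
      vals <- suppressWarnings(as.integer(fields))
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2L) next
      base <- serial_map[as.character(vals[1L])]
      if (is.na(base)) next
      for (p in vals[-1L]) {
        j <- serial_map[as.character(p)]
        if (!is.na(j) && j != base) pairs[[length(pairs) + 1L]] <- c(base, j)
      }
    }
    if (length(pairs) > 0L) bonds <- do.call(rbind, pairs)
  }

  molecule(elements, cbind(xs, ys, zs), bonds,
           name = sub("\\.[Pp][Dd][Bb]$", "", basename(path)),
           provenance = paste0("read from ", path))
}

#' Perceive bonds from interatomic distances
#'
#' Adds a bond between every atom pair whose distance does not exceed the sum
#' of the two single-bond covalent radii plus `slack`. Bonds already present
#' (e.g. from CONECT records) are kept; the result is the union.
#'
#' @param mol A `molecule`.
#' @param slack Extra distance allowance in Angstrom (default 0.45).
#' @return The molecule with perceived bonds added.
#' @export
perceive_bonds <- function(mol, slack = 0.45) {
  stopifnot(inherits(mol, "molecule"))
  if (slack < 0) stop("slack must be >= 0")
  n <- n_atoms(mol)
  radii <- covalent_radius(mol$elements)  # errors on unknown elements
  if (n >= 2L) {
    d <- distance_matrix(mol)
    cutoff <- outer(radii, radii, "+") + slack
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    bonds <- rbind(mol$bonds, unname(hit))
  } else {
    bonds <- mol$bonds
  }
  mol$bonds <- normalize_bonds(bonds, n)
  mol$provenance <- c(mol$provenance,
                      sprintf("perceived bonds (slack %.2f A)", slack))
  mol
}

#' Remove hydrogen atoms
#'
#' Drops all H and D atoms together with their incident bonds, reindexing the
#' remaining atoms consecutively. Idempotent.
#'
#' @param mol A `molecule`.
#' @return The heavy-atom molecule.
#' @export
strip_hydrogens <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  keep <- which(!(mol$elements %in% c("H", "D")))
  if (length(keep) == 0L) stop("empty model: molecule contains only hydrogens")
  if (length(keep) == n_atoms(mol)) return(mol)
  subset_molecule(mol, keep,
                  note = sprintf("stripped %d hydrogen atom(s); kept [%s]",
                                 n_atoms(mol) - length(keep),
                                 paste(keep, collapse = ",")))
}

format_atom_name <- function(element, counter) {
  nm <- paste0(element, counter)
  if (nchar(element) == 1L) nm <- paste0(" ", nm)  # 1-char elements start col 14
  substr(sprintf("%-4s", nm), 1L, 4L)
}

#' Write a molecule to a PDB file
#'
#' Emits HETATM records with element-derived atom names, fixed-format
#' coordinates (%8.3f), the element symbol right-justified in columns 77-78,
#' one CONECT group per bonded atom, and a terminating END record. A file
#' written by this function re-reads to the same elements, bonds, and
#' coordinates to 0.001 Angstrom.
#'
#' @param mol A `molecule`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  counts <- integer(0)
  lines <- character(0)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) + 1L
    lines <- c(lines, sprintf(
      "HETATM%5d %s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, format_atom_name(el, counts[el]),
      mol$coords[i, 1L], mol$coords[i, 2L], mol$coords[i, 3L], el))
  }
  if (nrow(mol$bonds) > 0L) {
    adj <- adjacency_list(mol)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      while (length(nb) > 0L) {
        chunk <- nb[seq_len(min(4L, length(nb)))]
        nb <- nb[-seq_len(min(4L, length(nb)))]
        lines <- c(lines, paste0("CONECT", sprintf("%5d", i),
                                 paste(sprintf("%5d", chunk), collapse = "")))
      }
    }
  }
  lines <- c(lines, "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write PDB file ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
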