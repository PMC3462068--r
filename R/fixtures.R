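# Synthetic fixture molecules with analytically known ground truth.
#
# Scaffolds (chains, rings, a ring-plus-methyl "toluene" shape) are built at
# ideal geometry and decorated with substituent payloads placed at ideal
# bond length along analytically chosen directions, so the expected MCS
# size, symmetry-mapping count, handle count, and merge-plan count can all
# be computed combinatorially from the specs, without running the pipeline.

#' Scaffold specification for fixture molecules
#'
#' @param kind `"linear_chain"`, `"ring"`, or `"ring_plus_methyl"` (a ring of
#'   `size - 1` atoms plus one exocyclic atom bonded to ring position 1).
#' @param size Heavy-atom count (>= 3; rings need >= 3 ring atoms).
#' @param elements Element symbols, one per atom (default all `"C"`). For
#'   `ring_plus_methyl` the last entry is the exocyclic atom.
#' @param bond_length Ideal bond length in Angstrom (default 1.5); ring atoms
#'   sit on a regular polygon with this edge.
#' @param noise_sigma Isotropic Gaussian coordinate jitter in Angstrom
#'   (default 0); applied identically to both parents of a pair.
#' @return A `scaffold_spec` list.
#' @export
scaffold_spec <- function(kind = c("linear_chain", "ring", "ring_plus_methyl"),
                          size, elements = NULL, bond_length = 1.5,
                          noise_sigma = 0) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 3L) stop("scaffold size must be >= 3")
  if (kind == "ring_plus_methyl" && size < 4L) {
    stop("ring_plus_methyl needs >= 4 atoms (ring of >= 3 plus one)")
  }
  elements <- canonical_element(elements %||% rep("C", size))
  if (length(elements) != size) stop("elements must have one entry per atom")
  structure(list(kind = kind, size = size, elements = elements,
                 bond_length = bond_length, noise_sigma = noise_sigma),
            class = "scaffold_spec")
}

ring_coords <- function(n, edge) {
  radius <- edge / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

#' Build the bare scaffold molecule for a spec
#'
#' @param spec A `scaffold_spec`.
#' @param seed Seed for the coordinate jitter (used when `noise_sigma > 0`).
#' @param name Molecule name.
#' @return A `molecule` at ideal (optionally jittered) geometry with explicit
#'   bonds.
#' @export
scaffold_molecule <- function(spec, seed = 0L, name = "scaffold") {
  stopifnot(inherits(spec, "scaffold_spec"))
  n <- spec$size
  L <- spec$bond_length
  if (spec$kind == "linear_chain") {
    coords <- cbind((seq_len(n) - 1L) * L, 0, 0)
    bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  } else if (spec$kind == "ring") {
    coords <- ring_coords(n, L)
    bonds <- rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(n, 1L))
  } else {
    nr <- n - 1L
    rc <- ring_coords(nr, L)
    exo <- rc[1L, ] + unit_vector(rc[1L, ]) * L  # radially outward from atom 1
    coords <- rbind(rc, exo)
    bonds <- rbind(cbind(seq_len(nr - 1L), seq_len(nr - 1L) + 1L),
                   c(nr, 1L), c(1L, n))
  }
  if (spec$noise_sigma > 0) {
    coords <- coords + with_seed(seed,
      matrix(stats::rnorm(3L * n, 0, spec$noise_sigma), n, 3L))
  }
  molecule(spec$elements, coords, bonds, name = name,
           provenance = sprintf("fixture scaffold (%s, %d atoms)",
                                spec$kind, n))
}

#' Substituent specification for fixture molecules
#'
#' @param position Scaffold atom index carrying the payload (for `"bridge"`,
#'   the first of the two bridged positions).
#' @param payload `"atom"` (one atom), `"chain"` (two atoms in a line),
#'   `"branch"` (three atoms, one fork), or `"bridge"` (one atom bonded to
#'   two distinct scaffold positions -- a multiple-handle fragment).
#' @param elements Element symbols for the payload atoms (1, 2, 3, or 1
#'   entries respectively).
#' @param position2 Second scaffold position, for `"bridge"` only.
#' @return A `substituent_spec` list.
#' @export
substituent_spec <- function(position, payload = c("atom", "chain", "branch",
                                                   "bridge"),
                             elements = "F", position2 = NULL) {
  payload <- match.arg(payload)
  need <- c(atom = 1L, chain = 2L, branch = 3L, bridge = 1L)[[payload]]
  elements <- canonical_element(elements)
  if (length(elements) != need) {
    stop("payload '", payload, "' needs ", need, " element(s)")
  }
  if (payload == "bridge") {
    if (is.null(position2) || position2 == position) {
      stop("bridge payloads need two distinct positions")
    }
  } else if (!is.null(position2)) {
    stop("position2 is only meaningful for bridge payloads")
  }
  structure(list(position = as.integer(position), payload = payload,
                 elements = elements,
                 position2 = if (is.null(position2)) NULL
                             else as.integer(position2)),
            class = "substituent_spec")
}

substituent_uid <- function(sub) {
  paste(sub$payload, paste(sub$elements, collapse = ","),
        sub$position, sub$position2 %||% "", sep = ":")
}

# Outward direction for a payload at scaffold position p.
payload_direction <- function(spec, coords, p) {
  n <- spec$size
  if (spec$kind == "linear_chain") {
    if (p == 1L) c(-1, 0, 0)
    else if (p == n) c(1, 0, 0)
    else c(0, 1, 0)
  } else if (spec$kind == "ring") {
    unit_vector(coords[p, ] - colMeans(coords))
  } else {
    ring_cen <- colMeans(coords[seq_len(n - 1L), , drop = FALSE])
    if (p == n) unit_vector(coords[n, ] - coords[1L, ])
    else unit_vector(coords[p, ] - ring_cen)
  }
}

decorate <- function(scaf_mol, spec, subs, name) {
  elements <- scaf_mol$elements
  coords <- scaf_mol$coords
  bonds <- scaf_mol$bonds
  L <- spec$bond_length
  used_positions <- integer(0)
  for (sub in subs) {
    p <- sub$position
    if (p < 1L || p > spec$size) stop("substituent position out of range")
    if (p %in% used_positions) {
      stop("substituent collision: two payloads on scaffold position ", p)
    }
    used_positions <- c(used_positions, p)
    d <- payload_direction(spec, scaf_mol$coords, p)
    base <- scaf_mol$coords[p, ]
    if (sub$payload == "atom") {
      elements <- c(elements, sub$elements)
      coords <- rbind(coords, base + d * L)
      bonds <- rbind(bonds, c(p, length(elements)))
    } else if (sub$payload == "chain") {
      i1 <- length(elements) + 1L
      elements <- c(elements, sub$elements)
      coords <- rbind(coords, base + d * L, base + d * 2 * L)
      bonds <- rbind(bonds, c(p, i1), c(i1, i1 + 1L))
    } else if (sub$payload == "branch") {
      # fork out of the scaffold plane so branch arms stay clear of the ring
      perp <- c(0, 0, 1)
      a1 <- base + d * L
      a2 <- a1 + L * (cos(pi / 3) * d + sin(pi / 3) * perp)
      a3 <- a1 + L * (cos(pi / 3) * d - sin(pi / 3) * perp)
      i1 <- length(elements) + 1L
      elements <- c(elements, sub$elements)
      coords <- rbind(coords, a1, a2, a3)
      bonds <- rbind(bonds, c(p, i1), c(i1, i1 + 1L), c(i1, i1 + 2L))
    } else {  # bridge
      q <- sub$position2
      if (q %in% used_positions) {
        stop("substituent collision: two payloads on scaffold position ", q)
      }
      used_positions <- c(used_positions, q)
      mid <- (scaf_mol$coords[p, ] + scaf_mol$coords[q, ]) / 2
      cen <- colMeans(scaf_mol$coords[seq_len(min(spec$size,
        if (spec$kind == "ring_plus_methyl") spec$size - 1L else spec$size)), ,
        drop = FALSE])
      dir_out <- unit_vector(mid - cen)
      half <- sqrt(sum((scaf_mol$coords[p, ] - mid)^2))
      h <- sqrt(max(L^2 - half^2, 0.3))
      i1 <- length(elements) + 1L
      elements <- c(elements, sub$elements)
      coords <- rbind(coords, mid + dir_out * h)
      bonds <- rbind(bonds, c(p, i1), c(q, i1))
    }
  }
  molecule(elements, coords, bonds, name = name,
           provenance = c(scaf_mol$provenance,
                          sprintf("decorated with %d substituent(s)",
                                  length(subs))))
}

# Dihedral symmetry operations on positions 1..n of a regular polygon:
# rotations and reflections, returned as permutations.
dihedral_ops <- function(n) {
  ops <- list()
  for (k in 0:(n - 1L)) {
    ops[[length(ops) + 1L]] <- ((seq_len(n) - 1L + k) %% n) + 1L
  }
  for (a in 0:(n - 1L)) {
    ops[[length(ops) + 1L]] <- ((a - (seq_len(n) - 1L)) %% n) + 1L
  }
  ops
}

expected_symmetry_count <- function(spec) {
  e <- spec$elements
  if (spec$kind == "linear_chain") {
    1L + as.integer(identical(e, rev(e)))
  } else if (spec$kind == "ring") {
    sum(vapply(dihedral_ops(spec$size),
               function(s) all(e[s] == e), logical(1)))
  } else {
    nr <- spec$size - 1L
    er <- e[seq_len(nr)]
    # the exocyclic atom must map to itself, so only ring operations fixing
    # position 1 survive
    sum(vapply(dihedral_ops(nr),
               function(s) s[1L] == 1L && all(er[s] == er), logical(1)))
  }
}

expected_plan_count <- function(handle_positions, subs_a, subs_b) {
  h <- length(handle_positions)
  if (h == 0L) return(1L)
  payload_at <- function(subs, pos) {
    hits <- Filter(function(s) pos %in% c(s$position, s$position2), subs)
    sort(vapply(hits, substituent_uid, character(1)))
  }
  multi_sets <- list()
  for (tag in c("A", "B")) {
    subs <- if (tag == "A") subs_a else subs_b
    for (s in subs) {
      if (s$payload == "bridge") {
        multi_sets[[length(multi_sets) + 1L]] <-
          match(c(s$position, s$position2), handle_positions)
      }
    }
  }
  grid <- expand.grid(rep(list(c("A", "B")), h), stringsAsFactors = FALSE)
  sigs <- character(0)
  for (r in seq_len(nrow(grid))) {
    ch <- as.character(grid[r, ])
    ok <- all(vapply(multi_sets,
                     function(pos) length(unique(ch[pos])) == 1L, logical(1)))
    if (!ok) next
    sel <- character(0)
    for (i in seq_len(h)) {
      subs <- if (ch[i] == "A") subs_a else subs_b
      pay <- payload_at(subs, handle_positions[i])
      if (length(pay) > 0L) sel <- c(sel, paste0(ch[i], ":", pay))
    }
    sigs <- c(sigs, paste(sort(unique(sel)), collapse = ";"))
  }
  length(unique(sigs))
}

#' Build a fixture pair with known ground truth
#'
#' Both parents share the scaffold's exact coordinates (jitter, when
#' requested, is drawn once and applied before decoration, so the shared
#' substructure stays exactly common) and are then decorated with their own
#' substituent payloads. The expected MCS size, symmetry-mapping count,
#' handle count, and consistent merge-plan count are computed
#' combinatorially from the specs, never by running the pipeline.
#'
#' Payloads must not be identical between the parents at the same position
#' (a shared payload would extend the common substructure beyond the
#' scaffold and invalidate the expected values).
#'
#' @param scaffold A `scaffold_spec`.
#' @param subs_a,subs_b Lists of `substituent_spec` for parents A and B.
#' @param seed Seed for the (shared) coordinate jitter.
#' @return A list: `mol_a`, `mol_b`, and `expected` with fields `mcs_size`,
#'   `symmetry_count`, `handle_count`, `plan_count`.
#' @export
build_pair <- function(scaffold, subs_a = list(), subs_b = list(),
                       seed = 0L) {
  stopifnot(inherits(scaffold, "scaffold_spec"))
  for (s in c(subs_a, subs_b)) stopifnot(inherits(s, "substituent_spec"))

  uids_a <- vapply(subs_a, substituent_uid, character(1))
  uids_b <- vapply(subs_b, substituent_uid, character(1))
  if (length(intersect(uids_a, uids_b)) > 0L) {
    stop("shared payload: an identical substituent at the same position ",
         "would extend the common substructure beyond the scaffold")
  }

  scaf <- scaffold_molecule(scaffold, seed = seed)
  mol_a <- decorate(scaf, scaffold, subs_a, name = "parentA")
  mol_b <- decorate(scaf, scaffold, subs_b, name = "parentB")

  handle_positions <- sort(unique(unlist(lapply(c(subs_a, subs_b), function(s)
    c(s$position, s$position2)))))

  expected <- list(
    mcs_size = scaffold$size,
    symmetry_count = expected_symmetry_count(scaffold),
    handle_count = length(handle_positions),
    plan_count = expected_plan_count(handle_positions, subs_a, subs_b))
  list(mol_a = mol_a, mol_b = mol_b, expected = expected)
}

#' Draw a randomized fixture pair
#'
#' Samples a scaffold (chain, ring, or ring-plus-methyl; <= 14 heavy atoms
#' total) and decorates the two parents with substituents drawn from
#' disjoint element pools (A: F/Cl/Br, B: I/P/Si), so the maximum common
#' substructure is exactly the scaffold by construction. Deterministic
#' given `seed`.
#'
#' @param seed Integer seed.
#' @return As [build_pair()].
#' @export
random_fixture_pair <- function(seed) {
  with_seed(seed, {
    kind <- sample(c("linear_chain", "ring", "ring_plus_methyl"), 1L)
    size <- switch(kind,
                   linear_chain = sample(3:6, 1L),
                   ring = sample(5:8, 1L),
                   ring_plus_methyl = sample(6:8, 1L))
    scaffold_elems <- sample(c("C", "N", "O", "S"), size, replace = TRUE,
                             prob = c(0.7, 0.1, 0.1, 0.1))
    spec <- scaffold_spec(kind, size, scaffold_elems,
                          noise_sigma = sample(c(0, 0.02), 1L))

    pools <- list(A = c("F", "CL", "BR"), B = c("I", "P", "SI"))
    # ring position 1 already carries the exocyclic atom in ring_plus_methyl
    open_positions <- if (kind == "ring_plus_methyl") {
      setdiff(seq_len(size), 1L)
    } else {
      seq_len(size)
    }
    draw_subs <- function(parent) {
      k <- sample(0:2, 1L)
      if (k == 0L) return(list())
      positions <- sample(open_positions, k)
      lapply(positions, function(p) {
        payload <- sample(c("atom", "chain"), 1L)
        el <- sample(pools[[parent]],
                     if (payload == "atom") 1L else 2L, replace = TRUE)
        substituent_spec(p, payload, el)
      })
    }
    subs_a <- draw_subs("A")
    subs_b <- draw_subs("B")
    build_pair(spec, subs_a, subs_b, seed = seed)
  })
}
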