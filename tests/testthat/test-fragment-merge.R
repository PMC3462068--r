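# Fragment extraction, plan enumeration, assembly, clash filtering.

# asymmetric 6-ring pair with single-atom payloads at two positions
two_handle_fixture <- function() {
  build_pair(asym_ring_spec(),
             list(substituent_spec(1, "atom", "F"),
                  substituent_spec(4, "atom", "CL")),
             list(substituent_spec(1, "atom", "BR"),
                  substituent_spec(4, "atom", "I")))
}

# parent A bridges ring positions 1-2 (multiple-handle fragment);
# parent B has one single-atom fragment per handle
bridge_fixture <- function() {
  build_pair(asym_ring_spec(),
             list(substituent_spec(1, "bridge", "F", position2 = 2)),
             list(substituent_spec(1, "atom", "BR"),
                  substituent_spec(2, "atom", "I")))
}

test_that("extract_fragments finds components and anchors", {
  tol <- toluene()
  frags <- extract_fragments(tol, 1:6)
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$atoms, 7L)
  expect_equal(unname(frags[[1]]$anchors[, "handle"]), 1L)

  fx <- two_handle_fixture()
  frags_a <- extract_fragments(fx$mol_a, 1:6)
  expect_length(frags_a, 2L)
  expect_equal(sort(vapply(frags_a, function(f) f$anchors[1, "handle"],
                           integer(1))), c(1L, 4L))

  # bridge: one fragment, two anchors to distinct handles
  bf <- bridge_fixture()
  frags <- extract_fragments(bf$mol_a, 1:6)
  expect_length(frags, 1L)
  expect_equal(sort(unname(frags[[1]]$anchors[, "handle"])), c(1L, 2L))

  # a non-MCS component with no bond into the MCS is a structural error
  loose <- molecule(c("C", "C", "C", "O"),
                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(9, 9, 9)),
                    bonds = rbind(c(1L, 2L), c(2L, 3L)))
  expect_error(extract_fragments(loose, 1:3), "structural error")
})

test_that("enumerate_plans covers the cross-product and stays consistent", {
  fx <- two_handle_fixture()
  res <- find_mcs(fx$mol_a, fx$mol_b)
  cand <- res$candidates[[1]]
  frags_a <- extract_fragments(fx$mol_a, cand$atoms_a)
  frags_b <- extract_fragments(fx$mol_b, cand$atoms_b)
  handles <- handle_atoms(cand, cand$mappings[[1]], frags_a, frags_b)
  expect_length(handles, 2L)
  plans <- enumerate_plans(handles, frags_a, frags_b)
  expect_length(plans, 4L)  # 2 handles x 2 parents

  # multiple-handle fragment: mixed plans are inconsistent
  bf <- bridge_fixture()
  bres <- find_mcs(bf$mol_a, bf$mol_b)
  bcand <- bres$candidates[[1]]
  bfa <- extract_fragments(bf$mol_a, bcand$atoms_a)
  bfb <- extract_fragments(bf$mol_b, bcand$atoms_b)
  bh <- handle_atoms(bcand, bcand$mappings[[1]], bfa, bfb)
  expect_length(bh, 2L)
  bplans <- enumerate_plans(bh, bfa, bfb)
  expect_length(bplans, 2L)  # all-A and all-B only
  expect_equal(bf$expected$plan_count, 2L)

  # single-random mode: deterministic under a seed, member of the full set
  one <- enumerate_plans(handles, frags_a, frags_b,
                         all_combinations = FALSE, rng_seed = 5)
  expect_length(one, 1L)
  expect_identical(one,
                   enumerate_plans(handles, frags_a, frags_b,
                                   all_combinations = FALSE, rng_seed = 5))
  expect_true(one[[1]]$signature %in%
                vapply(plans, `[[`, character(1), "signature"))
})

test_that("assemble_merged recovers parents and mixes fragments", {
  fx <- two_handle_fixture()
  a <- fx$mol_a; b <- fx$mol_b
  res <- find_mcs(a, b)
  cand <- res$candidates[[1]]
  mapping <- cand$mappings[[1]]
  sup <- superpose_on_mcs(a, b, cand, mapping)
  frags_a <- extract_fragments(a, cand$atoms_a)
  frags_b <- extract_fragments(b, cand$atoms_b)
  handles <- handle_atoms(cand, mapping, frags_a, frags_b)
  plans <- enumerate_plans(handles, frags_a, frags_b)

  sigs <- vapply(plans, `[[`, character(1), "signature")
  all_a <- plans[[which(sigs == "A1;A2")]]
  merged_a <- assemble_merged(a, sup$molecule, cand, mapping, all_a,
                              frags_a, frags_b)
  # all-A plan reproduces parent A exactly (atoms, bonds, coordinates)
  expect_equal(sort(merged_a$molecule$elements), sort(a$elements))
  expect_equal(n_atoms(merged_a$molecule), n_atoms(a))
  perm <- order(c(cand$atoms_a, unlist(lapply(frags_a, `[[`, "atoms"))))
  expect_equal(merged_a$molecule$coords[perm, ], unname(a$coords),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nrow(merged_a$molecule$bonds), nrow(a$bonds))

  # all-B plan: B fragments at superposed coordinates, MCS at A's
  all_b <- plans[[which(sigs == "B1;B2")]]
  merged_b <- assemble_merged(a, sup$molecule, cand, mapping, all_b,
                              frags_a, frags_b)
  expect_equal(sort(merged_b$molecule$elements), sort(b$elements))
  b_frag_elems <- c("BR", "I")
  expect_true(all(b_frag_elems %in% merged_b$molecule$elements))

  # mixed plan: atom count = MCS + one A fragment + one B fragment
  mixed <- plans[[which(!(sigs %in% c("A1;A2", "B1;B2")))[1]]]
  merged_m <- assemble_merged(a, sup$molecule, cand, mapping, mixed,
                              frags_a, frags_b)
  expect_equal(n_atoms(merged_m$molecule), 6L + 1L + 1L)
  # anchor bonds restored: every fragment atom is connected
  deg <- tabulate(merged_m$molecule$bonds, n_atoms(merged_m$molecule))
  expect_true(all(deg >= 1L))
})

test_that("has_clash flags only short inter-fragment contacts", {
  # para substituents on a benzene ring: far apart, no clash
  fx <- build_pair(scaffold_spec("ring", 6),
                   list(substituent_spec(1, "atom", "F"),
                        substituent_spec(4, "atom", "CL")),
                   list())
  res <- merge_pair(fx$mol_a, fx$mol_b)
  # para payload atoms sit 2*(R + 1.5) = 6 A apart: nothing is skipped
  expect_equal(unname(res$summary["plans_skipped_clash"]), 0L)

  # hand-built merged molecule with two 1-atom fragments 1.0 A apart
  mm <- structure(list(
    molecule = molecule(c("C", "F", "CL"),
                        rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0)),
                        bonds = rbind(c(1L, 2L), c(1L, 3L))),
    fragment_of = c(NA, "A1", "B1"),
    plan = list(signature = "A1;B1")), class = "merged_molecule")
  expect_true(has_clash(mm, 2.0))
  expect_false(has_clash(mm, 0.5))
  mm$fragment_of <- c(NA, "A1", "A1")  # same fragment: exempt
  expect_false(has_clash(mm, 2.0))
})

test_that("merge_pair yields the exact combinatorial product set", {
  fx <- two_handle_fixture()
  res <- merge_pair(fx$mol_a, fx$mol_b)
  expect_equal(unname(res$summary["molecules"]), 4L)
  expect_equal(unname(res$summary["mcs_size"]), fx$expected$mcs_size)

  # both parent substituent patterns among the outputs
  elem_sets <- vapply(res$merged, function(m)
    paste(sort(m$molecule$elements), collapse = ","), character(1))
  expect_true(paste(sort(fx$mol_a$elements), collapse = ",") %in% elem_sets)
  expect_true(paste(sort(fx$mol_b$elements), collapse = ",") %in% elem_sets)
  # and two novel hybrids
  expect_equal(sum(!(elem_sets %in% c(
    paste(sort(fx$mol_a$elements), collapse = ","),
    paste(sort(fx$mol_b$elements), collapse = ",")))), 2L)
})

test_that("self-merge reproduces the parent without novel atoms", {
  tol <- toluene()
  res <- merge_pair(tol, tol)
  elems <- sort(tol$elements)
  found_parent <- any(vapply(res$merged, function(m) {
    identical(sort(m$molecule$elements), elems) &&
      max(abs(sort(as.numeric(dist(m$molecule$coords))) -
              sort(as.numeric(dist(tol$coords))))) < 1e-6
  }, logical(1)))
  expect_true(found_parent)
  for (m in res$merged) {
    expect_true(all(m$molecule$elements %in% tol$elements))
  }
})

test_that("single-random mode emits a member of the all-combinations set", {
  fx <- two_handle_fixture()
  full <- merge_pair(fx$mol_a, fx$mol_b)
  full_sigs <- vapply(full$merged, function(m) m$plan$signature, character(1))
  for (seed in 1:10) {
    one <- merge_pair(fx$mol_a, fx$mol_b,
                      all_substituent_combinations = FALSE, rng_seed = seed)
    expect_equal(unname(one$summary["molecules"]), 1L)
    expect_true(one$merged[[1]]$plan$signature %in% full_sigs)
  }
})

test_that("count law holds for 1-3 handles of single-handle fragments", {
  positions <- list(c(1L), c(1L, 4L), c(1L, 3L, 5L))
  pools_a <- c("F", "CL", "BR")
  pools_b <- c("I", "P", "SI")
  for (h in 1:3) {
    pos <- positions[[h]]
    subs_a <- lapply(seq_along(pos), function(i)
      substituent_spec(pos[i], "atom", pools_a[i]))
    subs_b <- lapply(seq_along(pos), function(i)
      substituent_spec(pos[i], "atom", pools_b[i]))
    fx <- build_pair(asym_ring_spec(), subs_a, subs_b)
    res <- merge_pair(fx$mol_a, fx$mol_b)
    expect_equal(unname(res$summary["molecules"]), 2L^h,
                 info = paste(h, "handles"))
    expect_equal(fx$expected$plan_count, 2L^h)
  }
})

test_that("raising clash_cutoff never increases the product count", {
  # bulky chains on adjacent (ortho) ring positions
  fx <- build_pair(scaffold_spec("ring", 6),
                   list(substituent_spec(1, "chain", c("F", "F")),
                        substituent_spec(2, "chain", c("CL", "CL"))),
                   list(substituent_spec(1, "chain", c("I", "I")),
                        substituent_spec(2, "chain", c("P", "P"))))
  counts <- integer(0)
  for (cutoff in c(0.5, 1.5, 2.5, 3.5, 5)) {
    res <- suppressWarnings(
      merge_pair(fx$mol_a, fx$mol_b, clash_cutoff = cutoff,
                 all_symmetry_relations = FALSE))
    counts <- c(counts, unname(res$summary["molecules"]))
  }
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[length(counts)])  # the sweep actually filters
})

test_that("merged molecules satisfy their structural invariants", {
  for (seed in c(3, 8)) {
    fx <- random_fixture_pair(seed)
    res <- tryCatch(suppressWarnings(merge_pair(fx$mol_a, fx$mol_b)),
                    ligmerge_no_mcs = function(e) NULL)
    if (is.null(res)) next
    n_mcs <- res$summary[["mcs_size"]]
    for (m in res$merged) {
      expect_equal(sum(is.na(m$fragment_of)), n_mcs)
      expect_false(has_clash(m, 2.0))
      expect_false(anyDuplicated(
        paste(m$molecule$coords[, 1], m$molecule$coords[, 2],
              m$molecule$coords[, 3])) > 0)
    }
  }
})
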