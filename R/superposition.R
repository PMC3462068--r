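# Rigid-body superposition: Kabsch least-squares fit of matched MCS atoms,
# applied to whole molecules.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' two corresponded point sets (centroid subtraction, covariance SVD,
#' determinant sign correction). Reflections are refused: the returned
#' rotation always has determinant +1, so chirality is never silently
#' inverted.
#'
#' @param coords_ref,coords_mov n x 3 coordinate matrices (Angstrom); row k
#'   of each is the same matched atom pair. n >= 3.
#' @return An object of class `rigid_transform` with fields `rotation`
#'   (3 x 3, det +1) and `translation` (length-3 vector). Applying it to
#'   `coords_mov` attains the global minimum RMSD against `coords_ref`.
#' @export
kabsch <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  if (nrow(coords_ref) != nrow(coords_mov) || ncol(coords_ref) != 3L ||
      ncol(coords_mov) != 3L) {
    stop("coordinate matrices must be n x 3 with corresponding rows")
  }
  n <- nrow(coords_ref)
  if (n < 3L) stop("kabsch needs >= 3 point pairs")

  cen_ref <- colMeans(coords_ref)
  cen_mov <- colMeans(coords_mov)
  pr <- sweep(coords_ref, 2L, cen_ref)
  pm <- sweep(coords_mov, 2L, cen_mov)

  sv_m <- svd(pm)$d
  if (sv_m[2L] < 1e-8 * max(sv_m[1L], 1)) {
    warning("collinear point set: rotation about the line is arbitrary ",
            "(solution is still RMSD-optimal)")
  }

  h <- t(pm) %*% pr
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = rot,
                 translation = as.numeric(cen_ref - rot %*% cen_mov)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

transform_points <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2L, -transform$translation)
}

#' Apply a rigid transform to a molecule
#'
#' Maps every atom position x to `rotation %*% x + translation`; elements and
#' bonds are unchanged.
#'
#' @param mol A `molecule`.
#' @param transform A `rigid_transform`.
#' @return The transformed molecule.
#' @export
apply_transform <- function(mol, transform) {
  stopifnot(inherits(mol, "molecule"), inherits(transform, "rigid_transform"))
  mol$coords <- transform_points(mol$coords, transform)
  mol$provenance <- c(mol$provenance, "applied rigid transform")
  mol
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superimpose parent B onto parent A via their common substructure
#'
#' The Kabsch transform is computed on the MCS atoms only (A as the
#' reference, under the given verified mapping), then applied to all of
#' `mol_b`, positioning the whole of B in A's frame.
#'
#' @param mol_a,mol_b The parent molecules.
#' @param match An `mcs_match` candidate.
#' @param mapping One of the verified mappings for `match` (integer vector
#'   aligned to `match$atoms_a`).
#' @return A list: `molecule` (transformed copy of `mol_b`), `rmsd` (achieved
#'   RMSD over the MCS atoms, Angstrom), and `transform`.
#' @export
superpose_on_mcs <- function(mol_a, mol_b, match, mapping) {
  stopifnot(inherits(match, "mcs_match"))
  if (!mapping_is_verified(match, mol_a, mol_b, mapping)) {
    stop("mapping is not a verified mapping for this match")
  }
  ref <- mol_a$coords[match$atoms_a, , drop = FALSE]
  mov <- mol_b$coords[mapping, , drop = FALSE]
  tr <- kabsch(ref, mov)
  b2 <- apply_transform(mol_b, tr)
  b2$provenance <- c(b2$provenance, sprintf(
    "superposed onto '%s' via %d MCS atoms", mol_a$name, length(mapping)))
  list(molecule = b2,
       rmsd = rmsd_points(ref, b2$coords[mapping, , drop = FALSE]),
       transform = tr)
}
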