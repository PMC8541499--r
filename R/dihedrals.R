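# Row-wise cross product for F x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Dihedral over all frames given four F x 3 coordinate matrices; degrees.
dihedral_frames <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2u)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

# Per-residue backbone atom bookkeeping shared by the dihedral and DSSP
# code: residue ordinals, chain of each residue, and the atom index of each
# backbone atom name (NA when absent).
residue_backbone_index <- function(ensemble) {
  at <- ensemble$topology$atoms
  res <- sort(unique(at$residue_index))
  pick <- function(nm) vapply(res, function(r) {
    i <- which(at$residue_index == r & at$name == nm)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  list(
    residues = res,
    chain = vapply(res, function(r) at$chain_id[at$residue_index == r][1], ""),
    resname = vapply(res, function(r) at$residue_name[at$residue_index == r][1], ""),
    N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
    H = pick("H")
  )
}

# F x 3 coordinate matrix of one atom across frames.
atom_frames <- function(ensemble, idx) {
  m <- ensemble$coords[, idx, , drop = FALSE]
  dim(m) <- c(dim(ensemble$coords)[1], 3)
  m
}

#' Backbone phi/psi dihedrals per frame and residue
#'
#' Standard definitions `phi = C(i-1)-N(i)-CA(i)-C(i)` and
#' `psi = N(i)-CA(i)-C(i)-N(i+1)`. Dihedrals undefined at chain termini
#' (no preceding/following residue in the same chain) are `NA`.
#'
#' @param ensemble A [conf_ensemble()] with backbone N, CA, C atoms.
#' @return List with `phi` and `psi`: `frames x residues` matrices in
#'   degrees, plus `residues` (0-based indices) and `chain`.
#' @export
backbone_dihedrals <- function(ensemble) {
  bb <- residue_backbone_index(ensemble)
  nr <- length(bb$residues)
  nf <- n_frames(ensemble)
  if (any(is.na(bb$N)) || any(is.na(bb$CA)) || any(is.na(bb$C)))
    stop("backbone N/CA/C atoms missing for some residue")
  phi <- psi <- matrix(NA_real_, nf, nr)
  for (r in seq_len(nr)) {
    if (r > 1 && bb$chain[r - 1] == bb$chain[r]) {
      phi[, r] <- dihedral_frames(
        atom_frames(ensemble, bb$C[r - 1]), atom_frames(ensemble, bb$N[r]),
        atom_frames(ensemble, bb$CA[r]), atom_frames(ensemble, bb$C[r]))
    }
    if (r < nr && bb$chain[r + 1] == bb$chain[r]) {
      psi[, r] <- dihedral_frames(
        atom_frames(ensemble, bb$N[r]), atom_frames(ensemble, bb$CA[r]),
        atom_frames(ensemble, bb$C[r]), atom_frames(ensemble, bb$N[r + 1]))
    }
  }
  list(phi = phi, psi = psi, residues = bb$residues, chain = bb$chain)
}
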