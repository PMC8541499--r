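# DSSP-style secondary-structure assignment.
#
# Hydrogen bonds are scored with the Kabsch-Sander electrostatic model:
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
# (distances in angstrom between the carbonyl C/O of the acceptor residue
# and the amide N/H of the donor residue), a bond being assigned when
# E < -0.5 kcal/mol. Pattern codes follow the original priority order:
# alpha-helix (H) > bridge/strand (B/E) > 3_10 (G) > pi (I) > turn (T) >
# bend (S); everything else is coil (C).

.hb_q <- 0.084 * 332        # kcal/mol * angstrom
.hb_cut <- -0.5             # kcal/mol
.hb_ca_gate <- 0.9          # nm; CA-CA distance beyond which pairs are skipped

#' Assign secondary structure by the DSSP hydrogen-bond algorithm
#'
#' Implements the Kabsch-Sander assignment on every frame of the ensemble:
#' n to n+4 hydrogen-bond patterns give H, n to n+3 give G, n to n+5 give
#' I, inter-strand bridges give E (ladders) or B (isolated bridges), turns
#' T, and bends S (CA-chain curvature above 70 degrees). Proline and
#' chain-start residues are never hydrogen-bond donors. The amide hydrogen
#' is taken from the topology when present (atom name `H`) or placed 0.1 nm
#' from N opposite the preceding carbonyl, the standard DSSP construction;
#' `hydrogens = "place"` forces geometric placement everywhere, which is
#' what reference DSSP implementations do regardless of the input file.
#'
#' @param ensemble A [conf_ensemble()] with backbone N, CA, C, O atoms.
#' @param hydrogens `"detect"` (use explicit amide H when present) or
#'   `"place"` (always place geometrically).
#' @return Object of class `ss_assignment`: list with `codes` (a
#'   `frames x residues` character matrix over H, G, I, E, B, T, S, C),
#'   `residues`, `resname`, `chain`, and `hydrogens` (the mode used).
#' @export
dssp_assign <- function(ensemble, hydrogens = c("detect", "place")) {
  hydrogens <- match.arg(hydrogens)
  bb <- residue_backbone_index(ensemble)
  nr <- length(bb$residues)
  nf <- n_frames(ensemble)
  if (any(is.na(bb$N)) || any(is.na(bb$CA)) || any(is.na(bb$C)) ||
      any(is.na(bb$O)))
    stop("backbone N/CA/C/O atoms required for every residue")
  codes <- matrix("C", nf, nr)
  if (nr < 3) {
    return(structure(list(codes = codes, residues = bb$residues,
                          resname = bb$resname, chain = bb$chain,
                          hydrogens = hydrogens),
                     class = "ss_assignment"))
  }

  Nc <- lapply(seq_len(nr), function(r) atom_frames(ensemble, bb$N[r]))
  CAc <- lapply(seq_len(nr), function(r) atom_frames(ensemble, bb$CA[r]))
  Cc <- lapply(seq_len(nr), function(r) atom_frames(ensemble, bb$C[r]))
  Oc <- lapply(seq_len(nr), function(r) atom_frames(ensemble, bb$O[r]))

  # Amide hydrogen per residue (F x 3), or NULL when the residue cannot
  # donate (proline, chain start, or no H available).
  Hc <- vector("list", nr)
  for (r in seq_len(nr)) {
    if (bb$resname[r] == "PRO") next
    chain_start <- r == 1 || bb$chain[r - 1] != bb$chain[r]
    if (chain_start) next
    if (hydrogens == "detect" && !is.na(bb$H[r])) {
      Hc[[r]] <- atom_frames(ensemble, bb$H[r])
    } else {
      d <- Cc[[r - 1]] - Oc[[r - 1]]
      Hc[[r]] <- Nc[[r]] + 0.1 * d / sqrt(rowSums(d^2))
    }
  }

  # hb[f, a, d]: CO of residue a accepts an H bond from NH of residue d.
  hb <- array(FALSE, c(nf, nr, nr))
  for (a in seq_len(nr)) {
    for (d in seq_len(nr)) {
      if (a == d || is.null(Hc[[d]])) next
      rca <- sqrt(rowSums((CAc[[a]] - CAc[[d]])^2))
      near <- rca <= .hb_ca_gate
      if (!any(near)) next
      rON <- sqrt(rowSums((Oc[[a]] - Nc[[d]])^2)) * 10
      rCH <- sqrt(rowSums((Cc[[a]] - Hc[[d]])^2)) * 10
      rOH <- sqrt(rowSums((Oc[[a]] - Hc[[d]])^2)) * 10
      rCN <- sqrt(rowSums((Cc[[a]] - Nc[[d]])^2)) * 10
      e <- .hb_q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[, a, d] <- near & e < .hb_cut
    }
  }

  # CA-chain curvature for bends (kappa > 70 degrees), per frame/residue.
  kappa <- matrix(NA_real_, nf, nr)
  for (r in seq_len(nr)) {
    if (r < 3 || r > nr - 2) next
    if (bb$chain[r - 2] != bb$chain[r] || bb$chain[r + 2] != bb$chain[r]) next
    u <- CAc[[r]] - CAc[[r - 2]]
    v <- CAc[[r + 2]] - CAc[[r]]
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    kappa[, r] <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  }

  same_chain <- function(i, j) bb$chain[i] == bb$chain[j]

  for (f in seq_len(nf)) {
    h <- hb[f, , ]
    turn <- function(n, p) {
      p >= 1 && p + n <= nr && same_chain(p, p + n) && h[p, p + n]
    }
    ss <- rep("C", nr)

    # Alpha helices: two consecutive 4-turns.
    for (p in 2:nr) {
      if (turn(4, p - 1) && turn(4, p)) ss[p:(p + 3)] <- "H"
    }

    # Bridges and ladders.
    bridge <- matrix(0L, nr, nr)  # 1 parallel, -1 antiparallel
    for (i in 2:(nr - 1)) {
      for (j in 2:(nr - 1)) {
        if (j <= i) next
        if (same_chain(i, j) && j - i < 3) next
        if (!same_chain(i - 1, i + 1) || !same_chain(j - 1, j + 1)) next
        par <- (h[i - 1, j] && h[j, i + 1]) || (h[j - 1, i] && h[i, j + 1])
        anti <- (h[i, j] && h[j, i]) || (h[i - 1, j + 1] && h[j - 1, i + 1])
        if (par) bridge[i, j] <- bridge[j, i] <- 1L
        else if (anti) bridge[i, j] <- bridge[j, i] <- -1L
      }
    }
    if (any(bridge != 0)) {
      for (i in seq_len(nr)) {
        js <- which(bridge[i, ] != 0)
        for (j in js) {
          typ <- bridge[i, j]
          in_ladder <-
            (i > 1 && any(bridge[i - 1, ] == typ &
                            abs(which(bridge[i - 1, ] == typ) - j) == 1)) ||
            (i < nr && any(bridge[i + 1, ] == typ &
                             abs(which(bridge[i + 1, ] == typ) - j) == 1))
          lab <- if (in_ladder) "E" else "B"
          if (ss[i] != "H" && !(ss[i] == "E" && lab == "B")) ss[i] <- lab
        }
      }
    }

    # 3_10 helices: two consecutive 3-turns.
    for (p in 2:nr) {
      if (turn(3, p - 1) && turn(3, p)) {
        sel <- p:(p + 2)
        sel <- sel[ss[sel] %in% c("C", "T", "S")]
        ss[sel] <- "G"
      }
    }
    # Pi helices: two consecutive 5-turns.
    for (p in 2:nr) {
      if (turn(5, p - 1) && turn(5, p)) {
        sel <- p:(p + 4)
        sel <- sel[ss[sel] %in% c("C", "T", "S")]
        ss[sel] <- "I"
      }
    }
    # Turns: interior residues of any single n-turn.
    for (n in c(3, 4, 5)) {
      for (p in seq_len(nr)) {
        if (turn(n, p)) {
          sel <- (p + 1):(p + n - 1)
          sel <- sel[ss[sel] == "C"]
          ss[sel] <- "T"
        }
      }
    }
    # Bends.
    bendy <- which(ss == "C" & !is.na(kappa[f, ]) & kappa[f, ] > 70)
    ss[bendy] <- "S"
    codes[f, ] <- ss
  }

  structure(list(codes = codes, residues = bb$residues,
                 resname = bb$resname, chain = bb$chain,
                 hydrogens = hydrogens),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("ss_assignment: %d frames x %d residues\n", nrow(x$codes),
              ncol(x$codes)))
  if (nrow(x$codes) <= 5) {
    for (f in seq_len(nrow(x$codes)))
      cat(" ", paste(x$codes[f, ], collapse = ""), "\n")
  }
  invisible(x)
}

#' Relabel polyproline-II stretches of coil
#'
#' Extends a DSSP assignment with the PPII class: residues currently coil
#' (C) whose (phi, psi) lie within the PPII window in runs of at least
#' `min_run` consecutive residues are relabelled P. The default window is
#' (-75 +/- 29, +145 +/- 29) degrees. Non-coil DSSP codes are never
#' overwritten.
#'
#' @param assignment An `ss_assignment` from [dssp_assign()].
#' @param dihedrals Output of [backbone_dihedrals()] on the same ensemble.
#' @param phi_window,psi_window Length-2 numeric windows in degrees.
#' @param min_run Minimum run length of qualifying residues.
#' @return The assignment with codes relabelled.
#' @export
ppii_extend <- function(assignment, dihedrals,
                        phi_window = c(-104, -46), psi_window = c(116, 174),
                        min_run = 2) {
  codes <- assignment$codes
  phi <- dihedrals$phi; psi <- dihedrals$psi
  stopifnot(identical(dim(codes), dim(phi)))
  inwin <- !is.na(phi) & !is.na(psi) &
    phi >= phi_window[1] & phi <= phi_window[2] &
    psi >= psi_window[1] & psi <= psi_window[2]
  eligible <- inwin & codes == "C"
  chain <- assignment$chain
  nr <- ncol(codes)
  for (f in seq_len(nrow(codes))) {
    e <- eligible[f, ]
    r <- 1
    while (r <= nr) {
      if (!e[r]) { r <- r + 1; next }
      run_end <- r
      while (run_end < nr && e[run_end + 1] && chain[run_end + 1] == chain[r])
        run_end <- run_end + 1
      if (run_end - r + 1 >= min_run) codes[f, r:run_end] <- "P"
      r <- run_end + 1
    }
  }
  assignment$codes <- codes
  assignment
}

#' Per-residue secondary-structure propensity profile
#'
#' Aggregates a per-frame assignment into per-residue fractions of the
#' grouped classes: helix = H + G (alpha and 3_10), strand = E + B, turn =
#' T, bend = S, PPII = P, irregular = C + I. The peptide-level content is
#' the mean over residues.
#'
#' @param assignment An `ss_assignment` (optionally PPII-extended).
#' @return Object of class `ss_profile`: list with `per_residue`
#'   (data.frame of fractions, one row per residue) and `content` (named
#'   per-class means).
#' @export
ss_profile <- function(assignment) {
  codes <- assignment$codes
  nf <- nrow(codes)
  groups <- list(helix = c("H", "G"), strand = c("E", "B"), turn = "T",
                 bend = "S", ppii = "P", irregular = c("C", "I"))
  per <- data.frame(residue_index = assignment$residues,
                    residue_name = assignment$resname)
  for (g in names(groups))
    per[[g]] <- colMeans(matrix(codes %in% groups[[g]], nf))
  structure(list(per_residue = per,
                 content = colMeans(as.matrix(per[names(groups)]))),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat("ss_profile: peptide-level content (fraction)\n")
  print(round(x$content, 4))
  invisible(x)
}
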