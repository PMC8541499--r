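#' Residue-residue contact probability map
#'
#' Two residues are in contact in a frame when any pair of in-scope atoms
#' (heavy atoms by default) is closer than `cutoff`; the map entry is the
#' fraction of frames with a contact. The diagonal is 1 by convention.
#' Sequence-adjacent pairs are trivially in contact through the peptide
#' bond; they are reported like every other pair and flagged in the
#' `adjacent` attribute.
#'
#' @param ensemble A [conf_ensemble()].
#' @param cutoff Contact distance in nm.
#' @param atom_scope `"heavy"` (default) or `"all"` (include hydrogens).
#' @return Object of class `contact_map`: list with `probability`
#'   (symmetric residues x residues matrix), `cutoff`, `atom_scope`,
#'   `residues`, `adjacent` (logical matrix flagging `|i-j| <= 1`).
#' @export
contact_map <- function(ensemble, cutoff = 0.4,
                        atom_scope = c("heavy", "all")) {
  atom_scope <- match.arg(atom_scope)
  at <- ensemble$topology$atoms
  keep <- if (atom_scope == "heavy") which(!is_hydrogen(at)) else seq_len(nrow(at))
  res <- sort(unique(at$residue_index))
  nr <- length(res)
  if (nr < 2) stop("contact map needs at least 2 residues")
  nf <- n_frames(ensemble)
  idx <- lapply(res, function(r) keep[at$residue_index[keep] == r])
  prob <- diag(1, nr)
  for (i in seq_len(nr - 1)) {
    ai <- idx[[i]]
    if (!length(ai)) next
    for (j in (i + 1):nr) {
      aj <- idx[[j]]
      if (!length(aj)) next
      hit <- rep(FALSE, nf)
      for (a in ai) {
        pa <- atom_frames(ensemble, a)
        for (b in aj) {
          d2 <- rowSums((pa - atom_frames(ensemble, b))^2)
          hit <- hit | d2 < cutoff^2
        }
        if (all(hit)) break
      }
      prob[i, j] <- prob[j, i] <- mean(hit)
    }
  }
  adj <- abs(outer(seq_len(nr), seq_len(nr), `-`)) <= 1
  structure(list(probability = prob, cutoff = cutoff, atom_scope = atom_scope,
                 residues = res, adjacent = adj),
            class = "contact_map")
}

#' Contact-map difference (e.g. phosphorylated minus non-phosphorylated)
#'
#' @param map_a,map_b [contact_map()] objects with the same residue count
#'   and cutoff; the result is `map_a - map_b` element-wise.
#' @return A signed residues x residues matrix in `[-1, 1]`.
#' @export
contact_delta <- function(map_a, map_b) {
  if (!identical(dim(map_a$probability), dim(map_b$probability)))
    stop("contact maps have different residue counts")
  if (map_a$cutoff != map_b$cutoff)
    stop("contact maps computed at different cutoffs")
  map_a$probability - map_b$probability
}

#' Hydrogen bonds under an angle-dependent distance criterion
#'
#' A donor-H...acceptor triple is counted as bonded when the
#' donor-acceptor distance r_DA (nm) satisfies
#' `r_DA < r0 - k * theta^2`, with `theta` the H-donor-acceptor angle in
#' degrees (defaults r0 = 0.33 nm, k = 0.00044 nm/deg^2, the
#' Wernet-Nilsson-type rule). Hydrogens must be present: each donor heavy
#' atom is paired with the hydrogens within 0.12 nm of it.
#'
#' @param ensemble A [conf_ensemble()].
#' @param donors Integer atom indices of donor heavy atoms.
#' @param acceptors Integer atom indices of acceptor atoms.
#' @param r0,k Criterion constants (nm; nm/deg^2).
#' @return A list of length `n_frames`; each element a data.frame with
#'   columns `donor`, `hydrogen`, `acceptor` (atom indices) of the bonds
#'   present in that frame.
#' @export
hydrogen_bonds <- function(ensemble, donors, acceptors,
                           r0 = 0.33, k = 0.00044) {
  at <- ensemble$topology$atoms
  hyd <- which(is_hydrogen(at))
  if (!length(hyd))
    stop("no hydrogens in the ensemble; supply or place hydrogens before ",
         "applying the hydrogen-bond criterion")
  co <- ensemble$coords
  nf <- n_frames(ensemble)
  # Attach hydrogens to donors by first-frame covalent distance.
  f1 <- frame_coords(ensemble, 1)
  pairs <- list()
  for (d in donors) {
    dh <- sqrt(rowSums((f1[hyd, , drop = FALSE] -
                        matrix(f1[d, ], length(hyd), 3, byrow = TRUE))^2))
    for (h in hyd[dh < 0.12]) pairs[[length(pairs) + 1]] <- c(d, h)
  }
  if (!length(pairs))
    stop("no hydrogens attached to the requested donors; supply or place ",
         "hydrogens before applying the hydrogen-bond criterion")
  out <- replicate(nf, data.frame(donor = integer(), hydrogen = integer(),
                                  acceptor = integer()), simplify = FALSE)
  for (p in pairs) {
    d <- p[1]; h <- p[2]
    pd <- atom_frames(ensemble, d); ph <- atom_frames(ensemble, h)
    for (a in acceptors) {
      if (a == d || a == h) next
      pa <- atom_frames(ensemble, a)
      rda <- sqrt(rowSums((pa - pd)^2))
      u <- ph - pd; v <- pa - pd
      costh <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
      theta <- acos(pmax(-1, pmin(1, costh))) * 180 / pi
      bonded <- rda < (r0 - k * theta^2)
      for (f in which(bonded)) {
        out[[f]] <- rbind(out[[f]],
                          data.frame(donor = d, hydrogen = h, acceptor = a))
      }
    }
  }
  out
}

# Across-replicate probability and its error for a per-frame logical.
replicate_probability <- function(hit, replicate_id) {
  reps <- sort(unique(replicate_id))
  per <- vapply(reps, function(r) mean(hit[replicate_id == r]), 0)
  err <- if (length(per) > 1) stats::sd(per) / sqrt(length(per)) else 0
  c(probability = 100 * mean(per), error = 100 * err)
}

#' Salt-bridge probability table
#'
#' For each pair of a basic donor group (arginine NE/NH1/NH2, lysine NZ,
#' and the N-terminal amine, reported as its own `NT` row) and a phosphate
#' acceptor (O1P/O2P/O3P and the ester oxygen OG/OG1 of a phosphoresidue;
#' side-chain carboxylate oxygens if `include_carboxylates`), the
#' probability is the percentage of frames with at least one hydrogen bond
#' (criterion of [hydrogen_bonds()]) between the groups. The error is the
#' standard error of the per-replicate probabilities.
#'
#' @param ensemble A [conf_ensemble()] whose topology registers
#'   phosphorylated residues.
#' @param include_carboxylates Also treat Asp/Glu carboxylate oxygens as
#'   acceptors.
#' @param r0,k Hydrogen-bond criterion constants.
#' @return Object of class `interaction_table`: data.frame with columns
#'   `donor_residue`, `acceptor_residue`, `probability`, `error`
#'   (percent), plus attributes `kind` and `parameters`.
#' @export
salt_bridge_table <- function(ensemble, include_carboxylates = FALSE,
                              r0 = 0.33, k = 0.00044) {
  at <- ensemble$topology$atoms
  phos <- ensemble$topology$phospho_residues
  if (!length(phos)) {
    warning("no phosphorylated residues in topology; empty salt-bridge table")
    return(empty_interaction_table("salt_bridge"))
  }
  donor_rows <- list()
  base_names <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
  for (r in sort(unique(at$residue_index))) {
    rn <- at$residue_name[at$residue_index == r][1]
    if (rn %in% names(base_names)) {
      idx <- which(at$residue_index == r & at$name %in% base_names[[rn]])
      if (length(idx))
        donor_rows[[length(donor_rows) + 1]] <-
          list(label = sprintf("%s%d", rn, r), atoms = idx)
    }
  }
  # N-terminal amine: backbone N of the first residue of each chain.
  first_res <- tapply(at$residue_index, at$chain_id, min)
  nt_idx <- which(at$name == "N" &
                  at$residue_index %in% first_res[at$chain_id] &
                  !(at$residue_name == "PRO"))
  nt_idx <- nt_idx[at$residue_index[nt_idx] ==
                     first_res[at$chain_id[nt_idx]]]
  if (length(nt_idx))
    donor_rows[[length(donor_rows) + 1]] <- list(label = "NT", atoms = nt_idx)

  acc_rows <- list()
  for (r in phos) {
    idx <- which(at$residue_index == r &
                 at$name %in% c("O1P", "O2P", "O3P", "OG", "OG1", "OH"))
    if (length(idx))
      acc_rows[[length(acc_rows) + 1]] <-
        list(label = sprintf("%s%d", at$residue_name[idx[1]], r), atoms = idx)
  }
  if (include_carboxylates) {
    for (r in sort(unique(at$residue_index))) {
      rn <- at$residue_name[at$residue_index == r][1]
      if (rn %in% c("ASP", "GLU")) {
        idx <- which(at$residue_index == r &
                     at$name %in% c("OD1", "OD2", "OE1", "OE2"))
        if (length(idx))
          acc_rows[[length(acc_rows) + 1]] <-
            list(label = sprintf("%s%d", rn, r), atoms = idx)
      }
    }
  }
  if (!length(donor_rows) || !length(acc_rows))
    return(empty_interaction_table("salt_bridge"))

  nf <- n_frames(ensemble)
  rows <- list()
  for (dn in donor_rows) {
    bonds <- tryCatch(
      hydrogen_bonds(ensemble, dn$atoms,
                     unique(unlist(lapply(acc_rows, `[[`, "atoms"))),
                     r0 = r0, k = k),
      error = function(e) NULL)
    for (ac in acc_rows) {
      hit <- if (is.null(bonds)) rep(FALSE, nf) else
        vapply(bonds, function(b) any(b$acceptor %in% ac$atoms), TRUE)
      pe <- replicate_probability(hit, ensemble$replicate_id)
      rows[[length(rows) + 1]] <- data.frame(
        donor_residue = dn$label, acceptor_residue = ac$label,
        probability = pe[["probability"]], error = pe[["error"]])
    }
  }
  interaction_table(do.call(rbind, rows), "salt_bridge",
                    list(r0 = r0, k = k))
}

#' Arginine-tyrosine cation-pi probability table
#'
#' For every (Arg, Tyr) pair the probability (percent of frames) that both
#' distances from the arginine cation reference atom (guanidinium CZ by
#' default; the criterion requires both) to tyrosine CG and to tyrosine CZ
#' are at most `cutoff` (inclusive). The error is the standard error of
#' the per-replicate probabilities.
#'
#' @param ensemble A [conf_ensemble()].
#' @param cutoff Distance cutoff in nm (inclusive).
#' @param cation_atom Arginine atom used as the cation reference
#'   (`"CZ"`, `"NE"`, `"NH1"` or `"NH2"`).
#' @return An `interaction_table` (empty with a message when no Arg or no
#'   Tyr is present).
#' @export
cation_pi_table <- function(ensemble, cutoff = 0.6, cation_atom = "CZ") {
  at <- ensemble$topology$atoms
  args <- sort(unique(at$residue_index[at$residue_name == "ARG"]))
  tyrs <- sort(unique(at$residue_index[at$residue_name %in% c("TYR", "PTR")]))
  if (!length(args) || !length(tyrs))
    return(empty_interaction_table("cation_pi"))
  co <- ensemble$coords
  rows <- list()
  for (ra in args) {
    ic <- which(at$residue_index == ra & at$name == cation_atom)
    if (!length(ic)) stop("arginine ", ra, " lacks atom ", cation_atom)
    for (rt in tyrs) {
      icg <- which(at$residue_index == rt & at$name == "CG")
      icz <- which(at$residue_index == rt & at$name == "CZ")
      if (!length(icg) || !length(icz))
        stop("tyrosine ", rt, " lacks ring atoms CG/CZ")
      pc <- atom_frames(ensemble, ic[1])
      d1 <- sqrt(rowSums((pc - atom_frames(ensemble, icg[1]))^2))
      d2 <- sqrt(rowSums((pc - atom_frames(ensemble, icz[1]))^2))
      hit <- d1 <= cutoff & d2 <= cutoff
      pe <- replicate_probability(hit, ensemble$replicate_id)
      rows[[length(rows) + 1]] <- data.frame(
        donor_residue = sprintf("ARG%d", ra),
        acceptor_residue = sprintf("%s%d",
                                   at$residue_name[at$residue_index == rt][1], rt),
        probability = pe[["probability"]], error = pe[["error"]])
    }
  }
  interaction_table(do.call(rbind, rows), "cation_pi",
                    list(cutoff = cutoff, cation_atom = cation_atom))
}

interaction_table <- function(df, kind, parameters = list()) {
  rownames(df) <- NULL
  structure(df, kind = kind, parameters = parameters,
            class = c("interaction_table", "data.frame"))
}

empty_interaction_table <- function(kind) {
  interaction_table(data.frame(donor_residue = character(),
                               acceptor_residue = character(),
                               probability = numeric(), error = numeric()),
                    kind)
}
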