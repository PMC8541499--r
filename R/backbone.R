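# Ideal backbone internal coordinates (nm / degrees) used by the chain
# builder. The construction exists to make hydrogen-bond-testable geometry,
# not to model any force field.
.bb_geom <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
  b_c_o = 0.1231, b_n_h = 0.100,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_n_h = 119.5, omega = 180.0
)

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

# Accept "AAPG", c("ALA","PRO"), etc.
normalize_sequence <- function(sequence) {
  if (length(sequence) == 1 && !sequence %in% names(.aa3) &&
      nchar(sequence) > 1 && !grepl("[^A-Za-z]", sequence) &&
      nchar(sequence) != 3)
    sequence <- strsplit(toupper(sequence), "")[[1]]
  if (all(nchar(sequence) == 1)) {
    bad <- setdiff(toupper(sequence), names(.aa3))
    if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
    unname(.aa3[toupper(sequence)])
  } else {
    toupper(sequence)
  }
}

#' Build a full-backbone peptide at prescribed dihedrals
#'
#' Constructs a single-frame peptide with atoms N, H, CA, C, O per residue
#' (no amide H on proline) by sequential internal-coordinate placement with
#' fixed ideal bond lengths and angles (N-CA 0.1458 nm, CA-C 0.1525 nm,
#' C-N 0.1329 nm) and omega fixed at 180 deg. The requested phi/psi
#' dihedrals are recovered exactly (well within 0.5 deg) from the built
#' coordinates.
#'
#' Useful reference conformations: alpha-helix (-57, -47), 3_10-helix
#' (-49, -26), polyproline II (-75, +145), extended strand (-139, +135).
#'
#' @param sequence Residue codes: a vector of 3-letter codes or a string of
#'   1-letter codes.
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled.
#'   `phi[1]` and `psi[n]` are not defined by the chain and are used only
#'   to place the terminal carbonyl.
#' @param chain_id Chain identifier.
#' @return A single-frame [conf_ensemble()].
#' @export
build_backbone <- function(sequence, phi = -75, psi = 145, chain_id = "A") {
  res <- normalize_sequence(sequence)
  nres <- length(res)
  stopifnot(nres >= 2)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  g <- .bb_geom

  N <- CA <- C <- O <- matrix(NA_real_, nres, 3)
  H <- matrix(NA_real_, nres, 3)

  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    if (i < nres) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                               g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                g$a_c_n_ca, g$omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                               g$a_n_ca_c, phi[i + 1])
    }
    # Carbonyl O anti to the next amide N across the psi torsion.
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi[i] + 180)
    if (res[i] != "PRO") {
      if (i == 1) {
        H[1, ] <- place_atom(C[1, ], CA[1, ], N[1, ], g$b_n_h, 118, 180)
      } else {
        H[i, ] <- place_atom(O[i - 1, ], C[i - 1, ], N[i, ], g$b_n_h,
                             g$a_c_n_h, 180)
      }
    }
  }

  names_per <- lapply(seq_len(nres), function(i)
    if (res[i] == "PRO") c("N", "CA", "C", "O") else c("N", "H", "CA", "C", "O"))
  xyz_per <- lapply(seq_len(nres), function(i) {
    m <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
    if (res[i] == "PRO") m[-2, , drop = FALSE] else m
  })
  nm <- unlist(names_per)
  top <- topology(
    name = nm,
    residue_index = rep(seq_len(nres) - 1L, vapply(names_per, length, 1L)),
    residue_name = rep(res, vapply(names_per, length, 1L)),
    chain_id = chain_id,
    element = substr(nm, 1, 1)
  )
  conf_ensemble(do.call(rbind, xyz_per), top)
}

#' Merge two single-frame ensembles into one multi-chain frame
#'
#' Atoms of `b` follow those of `a`; residue indices of `b` are shifted to
#' continue after `a`. Used to build multi-chain fixtures such as
#' two-strand beta sheets.
#'
#' @param a,b Single-frame [conf_ensemble()] objects with distinct chain ids.
#' @return A single-frame [conf_ensemble()].
#' @export
merge_single_frames <- function(a, b) {
  stopifnot(n_frames(a) == 1, n_frames(b) == 1)
  ta <- a$topology$atoms; tb <- b$topology$atoms
  tb$residue_index <- tb$residue_index + max(ta$residue_index) + 1L
  at <- rbind(ta, tb)
  top <- topology(at$name, at$residue_index, at$residue_name, at$chain_id,
                  at$element, at$mass)
  conf_ensemble(rbind(frame_coords(a, 1), frame_coords(b, 1)), top)
}

#' Apply a rigid transform to a whole ensemble
#'
#' @param ensemble A [conf_ensemble()].
#' @param rot 3x3 rotation matrix.
#' @param shift Length-3 translation (nm).
#' @return The transformed ensemble.
#' @export
rigid_transform <- function(ensemble, rot = diag(3), shift = c(0, 0, 0)) {
  ensemble$coords <- transform_frames(ensemble$coords, rot, shift)
  ensemble
}

#' Build a two-residue interaction fixture with controlled geometry
#'
#' Minimal two-residue systems whose governing interaction distance equals
#' `separation`, for validating the interaction criteria:
#'
#' * `"contact"`: two alanine-like residues whose minimum inter-residue
#'   heavy-atom distance is exactly `separation`.
#' * `"cation_pi"`: an arginine guanidinium group and a tyrosine ring
#'   fragment placed so that both criterion distances (cation reference
#'   atom to TYR CG and to TYR CZ) equal `separation`.
#' * `"salt_bridge"`: an arginine NH1 donor (with hydrogen HH11) and a
#'   phosphoserine O1P acceptor at donor-acceptor distance `separation`,
#'   with the hydrogen placed for a near-linear donor-H-acceptor
#'   arrangement (angle at H = `dha_angle`).
#'
#' @param kind One of `"salt_bridge"`, `"cation_pi"`, `"contact"`.
#' @param separation Governing distance in nm; must be positive.
#' @param n_frames Number of identical frames to emit.
#' @param dha_angle Donor-H-acceptor angle at the hydrogen (degrees), for
#'   `"salt_bridge"`.
#' @return A [conf_ensemble()].
#' @export
build_interaction_fixture <- function(kind = c("salt_bridge", "cation_pi",
                                               "contact"),
                                      separation, n_frames = 1,
                                      dha_angle = 170) {
  kind <- match.arg(kind)
  if (separation <= 0) stop("separation must be positive")
  fx <- switch(kind,
    contact = {
      nm <- c("CA", "CB", "CA", "CB")
      xyz <- rbind(c(0, 0, 0), c(-0.153, 0, 0),
                   c(separation, 0, 0), c(separation + 0.153, 0, 0))
      list(name = nm, residue_index = c(0L, 0L, 1L, 1L),
           residue_name = rep("ALA", 4), xyz = xyz)
    },
    cation_pi = {
      # TYR CG and CZ are para ring carbons ~0.28 nm apart; the cation sits
      # on their perpendicular bisector at `separation` from both.
      ring <- 0.28
      if (separation <= ring / 2)
        stop("separation too small for the ring geometry")
      y <- sqrt(separation^2 - (ring / 2)^2)
      nm <- c("NE", "CZ", "NH1", "NH2",        # ARG guanidinium
              "CB", "CG", "CZ")                # TYR fragment
      cz <- c(ring / 2, y, 0)                  # cation reference atom
      xyz <- rbind(
        cz + c(-0.133, 0.02, 0), cz, cz + c(0.115, 0.067, 0),
        cz + c(0.115, -0.067, 0.02),
        c(-0.15, -0.05, 0), c(0, 0, 0), c(ring, 0, 0)
      )
      list(name = nm, residue_index = c(rep(0L, 4), rep(1L, 3)),
           residue_name = c(rep("ARG", 4), rep("TYR", 3)), xyz = xyz)
    },
    salt_bridge = {
      b_nh <- 0.100
      # Triangle D-H-A with |DH| = b_nh, |DA| = separation, angle at H set:
      # the angle at the donor follows from the sine rule.
      th_a <- asin(pmin(1, b_nh * sin(dha_angle * pi / 180) / separation))
      th_d <- (180 - dha_angle) * pi / 180 - th_a
      hpos <- b_nh * c(cos(th_d), sin(th_d), 0)
      acc <- c(separation, 0, 0)
      nm <- c("NE", "CZ", "NH1", "HH11", "NH2",     # ARG fragment
              "P", "O1P", "O2P", "O3P", "OG")       # SEP phosphate
      xyz <- rbind(
        c(-0.23, 0.3, 0), c(-0.133, 0.2, 0), c(0, 0, 0), hpos,
        c(-0.25, 0.1, 0.1),
        acc + c(0.16, 0, 0), acc, acc + c(0.23, 0.1, 0),
        acc + c(0.23, -0.1, 0), acc + c(0.31, 0, 0.1)
      )
      list(name = nm, residue_index = c(rep(0L, 5), rep(1L, 5)),
           residue_name = c(rep("ARG", 5), rep("SEP", 5)), xyz = xyz)
    })
  top <- topology(fx$name, fx$residue_index, fx$residue_name,
                  element = substr(gsub("^[0-9]+", "", fx$name), 1, 1))
  coords <- array(0, c(n_frames, nrow(fx$xyz), 3))
  for (i in seq_len(n_frames)) coords[i, , ] <- fx$xyz
  conf_ensemble(coords, top)
}

# Rigid placement of the second strand of the antiparallel sheet fixture,
# frozen from a one-off least-squares registration of the inter-strand
# hydrogen-bond distances (O(i)...N(9-i) and N(i)...O(9-i) at 0.29 nm,
# paired CA-CA near 0.49 nm) for two ideal extended strands.
.sheet_rot <- matrix(c(
  -0.9137709681, -0.1905383747, -0.3587725543,
  -0.1441073662, -0.6736962500,  0.7248216537,
  -0.3798100643,  0.7140227521,  0.5881460912), 3, 3)
.sheet_shift <- c(2.3316302617, 1.2725551373, -0.5794847330)

#' Build a two-chain antiparallel beta-sheet fixture
#'
#' Two ideal extended strands (phi = -139, psi = +135) of `n_residues`
#' alanines each, the second rigidly placed in antiparallel register with
#' the first so that the inter-strand backbone hydrogen bonds form. The
#' placement is a frozen constant, so the fixture is fully deterministic.
#' Interior residues of both strands are assigned E by the hydrogen-bond
#' pattern.
#'
#' @param n_residues Residues per strand (the frozen register is for 8).
#' @return A single-frame, two-chain [conf_ensemble()].
#' @export
build_beta_sheet <- function(n_residues = 8) {
  a <- build_backbone(rep("ALA", n_residues), -139, 135, chain_id = "A")
  b <- rigid_transform(build_backbone(rep("ALA", n_residues), -139, 135,
                                      chain_id = "B"),
                       .sheet_rot, .sheet_shift)
  merge_single_frames(a, b)
}

#' Deformation-mode two-state conformer pair
#'
#' A pair of single-frame bead-chain conformers for multi-state ensemble
#' studies: the first is a fixed random coil, the second the same coil
#' displaced along a fixed random deformation mode. Because the two states
#' share their overall shape, least-squares fitting is well conditioned
#' for both and a two-state mixture projects onto a cleanly bimodal PC1.
#'
#' @param n_residues Beads per conformer.
#' @param deformation_sd Per-coordinate displacement scale (nm) between
#'   the two states.
#' @param seed_coil,seed_deform Seeds fixing the coil and the deformation.
#' @return List of two single-frame [conf_ensemble()] objects.
#' @export
two_state_conformers <- function(n_residues = 12, deformation_sd = 0.1,
                                 seed_coil = 101, seed_deform = 202) {
  base <- generate_gaussian_chain(n_residues, 0.38, 1, seed = seed_coil)
  m1 <- frame_coords(base, 1)
  m2 <- m1 + with_seed(seed_deform,
                       matrix(stats::rnorm(length(m1), 0, deformation_sd),
                              nrow(m1), 3))
  list(conf_ensemble(m1, base$topology),
       conf_ensemble(m2, base$topology))
}
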