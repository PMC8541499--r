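# Seed handling for generators: reproducible given `seed`, without
# clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Topology for single-bead-per-residue pseudo-atom chains: bead named CA
# (so the default end-to-end endpoints and backbone selection apply), unit
# equal masses.
bead_topology <- function(n_residues) {
  topology(
    name = rep("CA", n_residues),
    residue_index = seq_len(n_residues) - 1L,
    residue_name = rep("GLY", n_residues),
    element = rep("C", n_residues),
    mass = rep(1.0, n_residues)
  )
}

#' Generate a freely-jointed (ideal Gaussian) chain ensemble
#'
#' One pseudo-atom bead per residue with unit equal masses; each bond is an
#' independent uniformly random direction of fixed length. This is the
#' Gaussian-coil reference model of polymer physics: for N bonds,
#' mean squared end-to-end distance is N b^2 and mean squared radius of
#' gyration b^2 N (N + 2) / (6 (N + 1)), so the shape factor tends to 6
#' for long chains.
#'
#' @param n_residues Number of beads (N + 1 for N bonds); at least 2.
#' @param bond_length Bond length b in nm.
#' @param n_frames Number of independent conformations.
#' @param seed Integer random seed; same seed, same ensemble.
#' @return A [conf_ensemble()].
#' @export
generate_gaussian_chain <- function(n_residues, bond_length = 0.38,
                                    n_frames = 1000, seed = 1) {
  stopifnot(n_residues >= 2, bond_length > 0, n_frames >= 1)
  nb <- n_residues - 1L
  coords <- with_seed(seed, {
    z <- matrix(stats::runif(n_frames * nb, -1, 1), n_frames, nb)
    phi <- matrix(stats::runif(n_frames * nb, 0, 2 * pi), n_frames, nb)
    s <- sqrt(1 - z^2)
    out <- array(0, c(n_frames, n_residues, 3))
    out[, -1, 1] <- bond_length * s * cos(phi)
    out[, -1, 2] <- bond_length * s * sin(phi)
    out[, -1, 3] <- bond_length * z
    for (k in 2:n_residues) out[, k, ] <- out[, k, ] + out[, k - 1, ]
    out
  })
  conf_ensemble(coords, bead_topology(n_residues))
}

#' Generate a rigid-rod ensemble
#'
#' Collinear equally spaced beads; frames differ only by a rigid rotation
#' and translation (the first frame is the untransformed rod along x).
#' For N bonds the rod has Ree = N b exactly, Rg^2 = b^2 N (N + 2) / 12,
#' hence shape factor 12 N / (N + 2).
#'
#' @inheritParams generate_gaussian_chain
#' @return A [conf_ensemble()].
#' @export
generate_rigid_rod <- function(n_residues, bond_length = 0.38,
                               n_frames = 1, seed = 1) {
  stopifnot(n_residues >= 2, bond_length > 0, n_frames >= 1)
  base <- cbind((seq_len(n_residues) - 1) * bond_length, 0, 0)
  coords <- array(0, c(n_frames, n_residues, 3))
  coords[1, , ] <- base
  if (n_frames > 1) {
    with_seed(seed, {
      for (i in 2:n_frames) {
        rot <- random_rotation()
        shift <- stats::rnorm(3)
        coords[i, , ] <- sweep(base %*% t(rot), 2, shift, `+`)
      }
    })
  }
  conf_ensemble(coords, bead_topology(n_residues))
}

#' Generate a multi-state ensemble with known state populations
#'
#' Each frame is a copy of one of the supplied single-frame conformers,
#' drawn with the given weights, uniformly randomly rotated about its
#' centroid, and perturbed by isotropic Gaussian coordinate noise. The
#' generating state of every frame is recorded, giving ground truth for
#' landscape/basin recovery.
#'
#' @param conformers List of single-frame [conf_ensemble()] objects sharing
#'   one topology.
#' @param weights State probabilities; must sum to 1.
#' @param noise_sd Isotropic coordinate noise (nm) applied after rotation.
#' @param n_frames Total frame count.
#' @param n_replicates Number of replicate labels, assigned evenly as
#'   contiguous blocks.
#' @param seed Integer random seed.
#' @param rotate If `FALSE`, frames are not rotated (useful for exactness
#'   tests).
#' @return A [conf_ensemble()] with an extra element `state`: the 1-based
#'   generating conformer index per frame.
#' @export
generate_multistate_ensemble <- function(conformers, weights, noise_sd = 0.02,
                                         n_frames = 1000, n_replicates = 1,
                                         seed = 1, rotate = TRUE) {
  stopifnot(length(conformers) >= 1, length(weights) == length(conformers))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  ref <- conformers[[1]]$topology
  for (e in conformers) {
    if (!identical(e$topology$atoms, ref$atoms))
      stop("conformers must share one topology")
    if (n_frames(e) != 1) stop("conformers must be single-frame ensembles")
  }
  na <- nrow(ref$atoms)
  source_frames <- lapply(conformers, frame_coords, i = 1)
  centroids <- lapply(source_frames, colMeans)
  drawn <- with_seed(seed, {
    state <- sample.int(length(conformers), n_frames, replace = TRUE,
                        prob = weights)
    coords <- array(0, c(n_frames, na, 3))
    for (i in seq_len(n_frames)) {
      k <- state[i]
      m <- source_frames[[k]]
      if (rotate) {
        cen <- centroids[[k]]
        m <- sweep(sweep(m, 2, cen) %*% t(random_rotation()), 2, cen, `+`)
      }
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(3 * na, 0, noise_sd), na, 3)
      coords[i, , ] <- m
    }
    list(state = state, coords = coords)
  })
  rid <- as.integer(floor((seq_len(n_frames) - 1) * n_replicates / n_frames))
  out <- conf_ensemble(drawn$coords, ref, replicate_id = rid)
  out$state <- drawn$state
  out
}
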