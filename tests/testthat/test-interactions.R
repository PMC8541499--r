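test_that("contact fixtures sit exactly on the intended side of the cutoff", {
  expect_equal(contact_map(build_interaction_fixture("contact", 0.35,
                                                     n_frames = 3))$probability[1, 2], 1)
  expect_equal(contact_map(build_interaction_fixture("contact", 0.45,
                                                     n_frames = 3))$probability[1, 2], 0)
})

test_that("contact map equals a brute-force all-pairs oracle", {
  g <- generate_gaussian_chain(5, 0.25, 20, seed = 17)
  cm <- contact_map(g, cutoff = 0.4)
  # independent O(frames * atoms^2) double loop
  oracle <- diag(1, 5)
  at <- g$topology$atoms
  for (i in 1:4) for (j in (i + 1):5) {
    hits <- 0
    for (f in 1:20) {
      m <- frame_coords(g, f)
      d <- sqrt(sum((m[i, ] - m[j, ])^2))
      if (d < 0.4) hits <- hits + 1
    }
    oracle[i, j] <- oracle[j, i] <- hits / 20
  }
  expect_equal(cm$probability, oracle)
  expect_true(isSymmetric(cm$probability))
  expect_true(all(diag(cm$probability) == 1))
})

test_that("contact delta is zero on self, bounded, and antisymmetric", {
  a <- contact_map(generate_gaussian_chain(6, 0.3, 15, seed = 1))
  b <- contact_map(generate_gaussian_chain(6, 0.3, 15, seed = 2))
  expect_true(all(contact_delta(a, a) == 0))
  d <- contact_delta(a, b)
  expect_true(all(d >= -1 & d <= 1))
  expect_equal(contact_delta(b, a), -d)
  csmall <- contact_map(generate_gaussian_chain(4, 0.3, 15, seed = 3))
  expect_error(contact_delta(a, csmall), "residue counts")
  b$cutoff <- 0.5
  expect_error(contact_delta(a, b), "cutoffs")
})

test_that("hydrogen-bond criterion matches the hand-computed inequality", {
  hb <- function(r, th) {
    e <- hb_triple(r, th)
    bonds <- hydrogen_bonds(e, donors = 1, acceptors = 3)
    nrow(bonds[[1]]) > 0
  }
  expect_true(hb(0.28, 10))    # bound 0.33 - 0.00044*100 = 0.286
  expect_false(hb(0.40, 5))    # exceeds the zero-angle bound 0.33
  expect_false(hb(0.30, 30))   # bound 0.33 - 0.396 < 0: impossible
  # no hydrogens at all -> guidance error
  bare <- select_atoms(hb_triple(0.28, 10), c(1, 3))
  expect_error(hydrogen_bonds(bare, donors = 1, acceptors = 2), "hydrogens")
})

test_that("salt-bridge probabilities and replicate errors are correct", {
  on <- build_interaction_fixture("salt_bridge", 0.28, n_frames = 4)
  tab <- salt_bridge_table(on)
  arg_row <- tab[tab$donor_residue == "ARG0", ]
  expect_equal(arg_row$probability, 100)
  off <- build_interaction_fixture("salt_bridge", 0.50, n_frames = 4)
  tab0 <- salt_bridge_table(off)
  expect_true(all(tab0$probability == 0))
  # no phospho residues: empty table with a warning
  expect_warning(empty <- salt_bridge_table(tiny_peptide()), "no phospho")
  expect_equal(nrow(empty), 0)
})

test_that("across-replicate errors are the standard error of replicate frequencies", {
  # 5 replicates x 10 frames with per-replicate bonded frequencies
  # 0.4, 0.5, 0.5, 0.6, 0.5
  freqs <- c(4, 5, 5, 6, 5)
  bonded <- build_interaction_fixture("salt_bridge", 0.28)
  unbonded <- build_interaction_fixture("salt_bridge", 0.50)
  frames <- list()
  for (r in seq_along(freqs)) {
    frames <- c(frames,
                replicate(freqs[r], frame_coords(bonded, 1), simplify = FALSE),
                replicate(10 - freqs[r], frame_coords(unbonded, 1),
                          simplify = FALSE))
  }
  co <- array(0, c(50, n_atoms(bonded), 3))
  for (f in 1:50) co[f, , ] <- frames[[f]]
  ens <- conf_ensemble(co, bonded$topology,
                       replicate_id = rep(0:4, each = 10))
  tab <- salt_bridge_table(ens)
  arg_row <- tab[tab$donor_residue == "ARG0", ]
  expect_equal(arg_row$probability, 50)
  expect_equal(arg_row$error, 100 * sd(freqs / 10) / sqrt(5))
})

test_that("every salt-bridge frame is also a contact frame for the pair", {
  for (sep in c(0.26, 0.28, 0.30)) {
    fx <- build_interaction_fixture("salt_bridge", sep, n_frames = 2)
    tab <- salt_bridge_table(fx)
    if (any(tab$probability > 0)) {
      cm <- contact_map(fx, cutoff = 0.4)
      expect_equal(cm$probability[1, 2], 1)
    }
  }
})

test_that("cation-pi criterion requires both distances, inclusively", {
  p55 <- cation_pi_table(build_interaction_fixture("cation_pi", 0.55))
  expect_equal(p55$probability, 100)
  p60 <- cation_pi_table(build_interaction_fixture("cation_pi", 0.60))
  expect_equal(p60$probability, 100)   # boundary is inclusive
  p65 <- cation_pi_table(build_interaction_fixture("cation_pi", 0.65))
  expect_equal(p65$probability, 0)
  # no arginine present: empty table
  expect_equal(nrow(cation_pi_table(tiny_peptide())), 0)
  # alternative cation reference atom is honoured
  alt <- cation_pi_table(build_interaction_fixture("cation_pi", 0.55),
                         cation_atom = "NE")
  expect_s3_class(alt, "interaction_table")
})

test_that("probabilities are invariant under frame reordering", {
  g <- generate_gaussian_chain(5, 0.25, 16, seed = 23)
  cm1 <- contact_map(g)
  perm <- rev(seq_len(16))
  g2 <- g
  g2$coords <- g$coords[perm, , , drop = FALSE]
  expect_equal(contact_map(g2)$probability, cm1$probability)
})
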