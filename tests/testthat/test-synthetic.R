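test_that("freely-jointed chain has fixed bond lengths and is seed-reproducible", {
  g <- generate_gaussian_chain(20, 0.38, 50, seed = 4)
  bonds <- apply(g$coords, 1, function(m) {
    m <- matrix(m, ncol = 3)
    sqrt(rowSums(diff(m)^2))
  })
  expect_true(max(abs(bonds - 0.38)) < 1e-9)
  expect_identical(g$coords, generate_gaussian_chain(20, 0.38, 50, seed = 4)$coords)
  expect_false(identical(g$coords, generate_gaussian_chain(20, 0.38, 50, seed = 5)$coords))
})

test_that("freely-jointed chain reproduces ideal-coil closed forms", {
  n_res <- 101; nb <- 100; b <- 0.38
  g <- generate_gaussian_chain(n_res, b, 1e4, seed = 42)
  ree2 <- mean(end_to_end_distance(g)$values^2)
  rg2 <- mean(radius_of_gyration(g)$values^2)
  expect_equal(ree2, nb * b^2, tolerance = 0.03)
  expect_equal(rg2, b^2 * nb * (nb + 2) / (6 * (nb + 1)), tolerance = 0.03)
})

test_that("rigid rod geometry is exact", {
  n_res <- 11; b <- 0.38
  r <- generate_rigid_rod(n_res, b, n_frames = 5, seed = 1)
  # collinearity: every triple spans zero triangle area
  for (f in 1:5) {
    m <- frame_coords(r, f)
    v1 <- m[2, ] - m[1, ]
    for (k in 3:n_res) {
      vk <- m[k, ] - m[1, ]
      cr <- c(v1[2] * vk[3] - v1[3] * vk[2], v1[3] * vk[1] - v1[1] * vk[3],
              v1[1] * vk[2] - v1[2] * vk[1])
      expect_lt(sqrt(sum(cr^2)), 1e-9)
    }
  }
  expect_equal(end_to_end_distance(r)$values,
               rep((n_res - 1) * b, 5), tolerance = 1e-9)
  nb <- n_res - 1
  expect_equal(radius_of_gyration(r)$values^2,
               rep(b^2 * nb * (nb + 2) / 12, 5), tolerance = 1e-9)
})

test_that("backbone builder recovers requested dihedrals", {
  for (target in list(c(-57, -47), c(-75, 145))) {
    bb <- build_backbone(rep("ALA", 15), target[1], target[2])
    dh <- backbone_dihedrals(bb)
    expect_lt(max(abs(dh$phi[1, -1] - target[1])), 0.5)
    expect_lt(max(abs(dh$psi[1, -15] - target[2])), 0.5)
  }
  # exactly one (phi, psi) pair defined on a 2-residue chain
  dh2 <- backbone_dihedrals(build_backbone(c("ALA", "ALA"), -57, -47))
  expect_equal(sum(!is.na(dh2$phi)), 1)
  expect_equal(sum(!is.na(dh2$psi)), 1)
  expect_error(build_backbone("AAZB"), "unknown residue")
})

test_that("proline gets no amide hydrogen", {
  bb <- build_backbone(c("ALA", "PRO", "ALA"), -75, 145)
  at <- bb$topology$atoms
  expect_false(any(at$name == "H" & at$residue_name == "PRO"))
  expect_true(any(at$name == "H" & at$residue_index == 2))
})

test_that("interaction fixtures place the governing distances exactly", {
  cp <- build_interaction_fixture("cation_pi", 0.55)
  at <- cp$topology$atoms
  m <- frame_coords(cp, 1)
  cz_arg <- which(at$residue_name == "ARG" & at$name == "CZ")
  cg <- which(at$residue_name == "TYR" & at$name == "CG")
  cz_tyr <- which(at$residue_name == "TYR" & at$name == "CZ")
  expect_equal(sqrt(sum((m[cz_arg, ] - m[cg, ])^2)), 0.55, tolerance = 1e-6)
  expect_equal(sqrt(sum((m[cz_arg, ] - m[cz_tyr, ])^2)), 0.55, tolerance = 1e-6)

  sb <- build_interaction_fixture("salt_bridge", 0.28, dha_angle = 170)
  at <- sb$topology$atoms
  m <- frame_coords(sb, 1)
  d <- which(at$name == "NH1"); h <- which(at$name == "HH11")
  a <- which(at$name == "O1P")
  expect_equal(sqrt(sum((m[d, ] - m[a, ])^2)), 0.28, tolerance = 1e-9)
  expect_equal(sqrt(sum((m[d, ] - m[h, ])^2)), 0.10, tolerance = 1e-9)
  # angle at the hydrogen
  u <- m[d, ] - m[h, ]; v <- m[a, ] - m[h, ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang, 170, tolerance = 1e-6)

  ct <- build_interaction_fixture("contact", 0.45)
  at <- ct$topology$atoms
  m <- frame_coords(ct, 1)
  dmin <- min(as.matrix(dist(m))[at$residue_index == 0, at$residue_index == 1])
  expect_equal(dmin, 0.45, tolerance = 1e-9)

  expect_error(build_interaction_fixture("contact", -1), "positive")
})

test_that("multi-state generator matches its ground truth", {
  pair <- two_state_conformers()
  # single-state: every frame identical to the conformer when unperturbed
  ms1 <- generate_multistate_ensemble(pair[1], 1.0, noise_sd = 0,
                                      n_frames = 5, seed = 1, rotate = FALSE)
  for (f in 1:5)
    expect_identical(frame_coords(ms1, f), frame_coords(pair[[1]], 1))
  # two-state counts within binomial 3 sigma
  n <- 1e4; w <- 0.7
  ms <- generate_multistate_ensemble(pair, c(w, 1 - w), noise_sd = 0.02,
                                     n_frames = n, n_replicates = 5, seed = 8)
  k <- sum(ms$state == 1)
  expect_lt(abs(k - n * w), 3 * sqrt(n * w * (1 - w)))
  # replicate labels even and contiguous
  expect_equal(as.vector(table(ms$replicate_id)), rep(n / 5, 5))
  # purity: same arguments, same ensemble
  ms2 <- generate_multistate_ensemble(pair, c(w, 1 - w), noise_sd = 0.02,
                                      n_frames = n, n_replicates = 5, seed = 8)
  expect_identical(ms$coords, ms2$coords)
  expect_error(generate_multistate_ensemble(pair, c(0.5, 0.4)), "sum to 1")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_gaussian_chain(5, 0.38, 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("generated ensembles survive the PDB round-trip", {
  g <- generate_gaussian_chain(6, 0.38, 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(g, path)
  back <- read_multimodel_pdb(path)
  expect_equal(back$coords, g$coords, tolerance = 1e-4)
})
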