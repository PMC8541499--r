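test_that("rigid-body copies collapse to zero RMSD after fitting", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair[1], 1.0, noise_sd = 0,
                                     n_frames = 40, seed = 5)
  fit <- medoid_fit(ms)
  r <- rmsd_to_frame(fit$ensemble, fit$medoid)
  expect_lt(max(r), 1e-6)
})

test_that("medoid matches exhaustive search on a small ensemble", {
  g <- generate_gaussian_chain(6, 0.38, 9, seed = 31)
  fit <- medoid_fit(g)
  sums <- sapply(1:9, function(f) sum(rmsd_to_frame(g, f)))
  expect_equal(fit$medoid, which.min(sums))
})

test_that("fitting is idempotent", {
  g <- generate_gaussian_chain(8, 0.38, 25, seed = 13)
  fit1 <- medoid_fit(g)
  fit2 <- medoid_fit(fit1$ensemble)
  expect_lt(max(abs(fit2$ensemble$coords - fit1$ensemble$coords)), 1e-9)
})

test_that("PCA basis is orthonormal and reconstructs centred coordinates", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair, c(0.6, 0.4), noise_sd = 0.02,
                                     n_frames = 300, seed = 3)
  fit <- medoid_fit(ms)
  pca <- shared_pca(fit$ensemble)
  v <- pca$components
  expect_lt(max(abs(t(v) %*% v - diag(ncol(v)))), 1e-8)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  # full reconstruction
  x <- matrix(fit$ensemble$coords, nrow = 300)
  rec <- pca$scores_full_a %*% t(v)
  ctr <- sweep(x, 2, pca$mean_structure)
  expect_lt(max(abs(rec - ctr)), 1e-8)
})

test_that("a repeated conformation has (near) zero explained variance", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair[1], 1.0, noise_sd = 0,
                                     n_frames = 120, seed = 2)
  fit <- medoid_fit(ms)
  pca <- shared_pca(fit$ensemble)
  expect_lt(sum(pca$explained_variance), 1e-12)
})

test_that("two-conformer PC1 is bimodal and recovers generation labels", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair, c(0.5, 0.5), noise_sd = 0.02,
                                     n_frames = 2000, seed = 19)
  fit <- medoid_fit(ms)
  pca <- shared_pca(fit$ensemble)
  pc1 <- pca$projections_a[, 1]
  side <- pc1 > mean(range(pc1))
  agreement <- max(mean(side == (ms$state == 1)),
                   mean(side == (ms$state == 2)))
  expect_gte(agreement, 0.99)
})

test_that("free-energy surface of a Gaussian cloud has the right shape", {
  set.seed(41)
  proj <- cbind(rnorm(10000), rnorm(10000))
  fes <- free_energy_surface(proj, grid_size = 150)
  expect_equal(min(fes$free_energy), 0)
  # minimum near the sample centroid: the mode of a KDE on 1e4 standard
  # normal points jitters by ~0.1-0.2 sigma, so test the basin core only
  idx <- which(fes$free_energy == 0, arr.ind = TRUE)[1, ]
  ctr <- colMeans(proj)
  expect_lt(abs(fes$x[idx[1]] - ctr[1]), 0.3)
  expect_lt(abs(fes$y[idx[2]] - ctr[2]), 0.3)
  # F at the 2-sigma ring is ~2 RT (KDE smoothing widens slightly)
  ring <- which(abs(sqrt(outer(fes$x^2, fes$y^2, `+`)) - 2) < 0.05,
                arr.ind = TRUE)
  fring <- mean(fes$free_energy[ring])
  expect_equal(fring, 2, tolerance = 0.15)
  expect_error(free_energy_surface(proj[1:50, ]), "100")
  expect_error(free_energy_surface(cbind(rep(1, 200), rnorm(200))),
               "degenerate")
})

test_that("basin detection recovers a two-state mixture", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair, c(0.7, 0.3), noise_sd = 0.02,
                                     n_frames = 5000, n_replicates = 5,
                                     seed = 27)
  fit <- medoid_fit(ms)
  pca <- shared_pca(fit$ensemble)
  fes <- free_energy_surface(pca$projections_a, 200, ms$replicate_id)
  bs <- find_basins(fes, max_level = 5)
  expect_equal(nrow(bs$table), 2)
  expect_equal(bs$table$population[1], 0.7, tolerance = 0.05)
  expect_equal(bs$table$population[2], 0.3, tolerance = 0.05)
  expect_equal(bs$table$min_F_RT[2] - bs$table$min_F_RT[1], log(7 / 3),
               tolerance = 0.2)
  expect_identical(bs$table$energy_class[1], "<=1RT")
  # representative frames carry the right generation label and lie in
  # their basin's cells
  rep1 <- representative_frame(bs, 1)
  expect_equal(ms$state[rep1], 1)
  expect_false(is.na(bs$frame_basin[rep1]))
  expect_equal(bs$frame_basin[rep1], 1)
  # populations sum to <= 1; to 1 when the level covers everything
  expect_lte(sum(bs$table$population), 1)
  bs_all <- find_basins(fes, max_level = 30)
  expect_equal(sum(bs_all$table$population), 1, tolerance = 0.01)
})

test_that("a unimodal cloud yields exactly one low basin", {
  set.seed(4)
  proj <- cbind(rnorm(2000, 0, 0.5), rnorm(2000, 0, 0.5))
  bs <- find_basins(free_energy_surface(proj, 120), max_level = 3)
  expect_equal(nrow(bs$table), 1)
  expect_identical(bs$table$energy_class, "<=1RT")
  expect_gt(bs$table$population, 0.9)
})

test_that("the landscape is invariant under a global rigid transform", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair, c(0.7, 0.3), noise_sd = 0.02,
                                     n_frames = 600, seed = 15)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  moved <- rigid_transform(ms, rot, c(2, -1, 3))
  run <- function(e) {
    fit <- medoid_fit(e)
    pca <- shared_pca(fit$ensemble)
    fes <- free_energy_surface(pca$projections_a, 100)
    list(ev = pca$explained_variance,
         pop = find_basins(fes, 5)$table$population)
  }
  a <- run(ms); b <- run(moved)
  expect_equal(a$ev, b$ev, tolerance = 1e-6)
  expect_equal(a$pop, b$pop, tolerance = 1e-6)
})

test_that("shared and single-ensemble PCA coincide on identical inputs", {
  pair <- two_state_conformers()
  ms <- generate_multistate_ensemble(pair, c(0.7, 0.3), noise_sd = 0.02,
                                     n_frames = 400, seed = 9)
  fit <- medoid_fit(ms)
  single <- shared_pca(fit$ensemble)
  both <- shared_pca(fit$ensemble, fit$ensemble)
  expect_equal(abs(single$projections_a), abs(both$projections_a),
               tolerance = 1e-8)
  # explained variances differ only through the (n-1) vs (2n-1) denominator
  expect_equal(single$explained_variance, both$explained_variance,
               tolerance = 2e-3)
  # atom-count mismatch is rejected
  other <- generate_gaussian_chain(5, 0.38, 400, seed = 1)
  fother <- medoid_fit(other)
  expect_error(shared_pca(fit$ensemble, fother$ensemble), "atom counts")
})
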