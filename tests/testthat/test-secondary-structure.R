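# Reference assignment strings for the built panel, produced once by an
# independent DSSP implementation (mdtraj 1.11.1, full codes, blanks
# mapped to C) on multi-model PDB files written from these exact builders.
reference_panel <- function() {
  list(
    list(build = function() build_backbone(rep("ALA", 16), -57, -47),
         ref = "CHHHHHHHHHHHHHHC"),
    list(build = function() build_backbone(rep("ALA", 12), -49, -26),
         ref = "CGGGGGGGGGGC"),
    list(build = function() build_backbone(rep("ALA", 15), -75, 145),
         ref = "CCCCCCCCCCCCCCC"),
    list(build = function() build_backbone(
           rep("ALA", 14),
           phi = c(rep(-139, 4), rep(-57, 6), rep(-139, 4)),
           psi = c(rep(135, 4), rep(-47, 6), rep(135, 4))),
         ref = "CCCCHHHHHHCCCC"),
    list(build = function() build_backbone(
           rep("ALA", 9),
           phi = c(rep(-139, 3), rep(-57, 3), rep(-139, 3)),
           psi = c(rep(135, 3), rep(-47, 3), rep(135, 3))),
         ref = "CCCTTTCCC"),
    list(build = function() build_backbone(
           rep("ALA", 10),
           phi = c(rep(-139, 3), rep(-57, 4), rep(-139, 3)),
           psi = c(rep(135, 3), rep(-47, 4), rep(135, 3))),
         ref = "CCCHHHHCCC"),
    list(build = function() build_beta_sheet(8),
         ref = "CEEEEEECCEEEEEEC")
  )
}

test_that("DSSP assignment agrees with the independent reference on the panel", {
  agree <- 0; total <- 0
  for (case in reference_panel()) {
    mine <- paste(dssp_assign(case$build())$codes[1, ], collapse = "")
    expect_equal(nchar(mine), nchar(case$ref))
    m <- strsplit(mine, "")[[1]]; r <- strsplit(case$ref, "")[[1]]
    agree <- agree + sum(m == r); total <- total + length(r)
  }
  expect_gte(agree / total, 0.95)
})

test_that("an unpaired extended strand carries no E or B", {
  ext <- build_backbone(rep("ALA", 12), -139, 135)
  codes <- dssp_assign(ext)$codes
  expect_false(any(codes %in% c("E", "B")))
})

test_that("antiparallel strands pair into E while placed hydrogens match", {
  sheet <- build_beta_sheet(8)
  detect <- dssp_assign(sheet, hydrogens = "detect")$codes[1, ]
  placed <- dssp_assign(sheet, hydrogens = "place")$codes[1, ]
  expect_true(sum(detect == "E") >= 8)
  expect_identical(detect, placed)
})

test_that("assignment is invariant under rigid-body motion", {
  hel <- build_backbone(rep("ALA", 12), -57, -47)
  set.seed(21)
  th <- runif(3, 0, 2 * pi)
  rot <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                  0, 0, 1), 3, byrow = TRUE)
  moved <- rigid_transform(hel, rot, c(5, -3, 1))
  expect_identical(dssp_assign(moved)$codes, dssp_assign(hel)$codes)
})

test_that("inverting a frame through the origin flips dihedral signs", {
  bb <- build_backbone(rep("ALA", 8), -75, 145)
  inv <- bb
  inv$coords <- -inv$coords
  dh <- backbone_dihedrals(bb)
  dhi <- backbone_dihedrals(inv)
  expect_equal(dhi$phi[1, -1], -dh$phi[1, -1], tolerance = 1e-9)
  expect_equal(dhi$psi[1, -8], -dh$psi[1, -8], tolerance = 1e-9)
  expect_true(is.na(dh$phi[1, 1]))
})

test_that("PPII extension relabels qualifying coil runs only", {
  pp <- build_backbone(rep("ALA", 15), -75, 145)
  ext <- ppii_extend(dssp_assign(pp), backbone_dihedrals(pp))
  codes <- ext$codes[1, ]
  expect_true(all(codes[2:14] == "P"))   # interior residues
  # ideal helix: no P anywhere
  hel <- build_backbone(rep("ALA", 15), -57, -47)
  exth <- ppii_extend(dssp_assign(hel), backbone_dihedrals(hel))
  expect_false(any(exth$codes == "P"))
  # an isolated single residue in the window stays non-P (run length rule)
  lone <- build_backbone(rep("ALA", 11),
                         phi = c(rep(-57, 5), -75, rep(-57, 5)),
                         psi = c(rep(-47, 5), 145, rep(-47, 5)))
  extl <- ppii_extend(dssp_assign(lone), backbone_dihedrals(lone))
  expect_false(any(extl$codes == "P"))
})

test_that("PPII extension never reduces non-coil class counts", {
  set.seed(33)
  for (rep_i in 1:5) {
    phi <- runif(12, -180, 180)
    psi <- runif(12, -180, 180)
    bb <- build_backbone(rep("ALA", 12), phi, psi)
    ss <- dssp_assign(bb)
    ext <- ppii_extend(ss, backbone_dihedrals(bb))
    for (cl in c("H", "G", "I", "E", "B", "T", "S"))
      expect_gte(sum(ext$codes == cl), sum(ss$codes == cl))
    # P only ever replaces C
    changed <- ss$codes != ext$codes
    expect_true(all(ss$codes[changed] == "C"))
    expect_true(all(ext$codes[changed] == "P"))
  }
})

test_that("profiles aggregate grouped classes that sum to one", {
  hel <- build_backbone(rep("ALA", 12), -57, -47)
  ext <- build_backbone(rep("ALA", 12), -139, 135)
  co <- array(0, c(10, n_atoms(hel), 3))
  for (f in 1:5) co[f, , ] <- frame_coords(hel, 1)
  for (f in 6:10) co[f, , ] <- frame_coords(ext, 1)
  ens <- conf_ensemble(co, hel$topology)
  prof <- ss_profile(dssp_assign(ens))
  per <- prof$per_residue
  sums <- rowSums(per[, c("helix", "strand", "turn", "bend", "ppii",
                          "irregular")])
  expect_equal(sums, rep(1, 12), tolerance = 1e-9)
  # interior residues: helix in exactly the 5 helical frames
  expect_equal(per$helix[6], 0.5, tolerance = 1e-9)
  # chains shorter than 3 residues are all-coil
  two <- build_backbone(c("ALA", "ALA"), -57, -47)
  expect_true(all(dssp_assign(two)$codes == "C"))
})
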