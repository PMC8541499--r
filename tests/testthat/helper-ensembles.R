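# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except temporary files written by the tests themselves.

# Minimal 2-residue peptide with a handful of frames.
tiny_peptide <- function(n_frames = 3) {
  top <- topology(
    name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    residue_index = c(0, 0, 0, 0, 1, 1, 1, 1),
    residue_name = c(rep("ALA", 4), rep("GLY", 4)),
    element = c("N", "C", "C", "O", "N", "C", "C", "O")
  )
  co <- array(0, c(n_frames, 8, 3))
  base <- matrix(c(0, 0, 0, 0.15, 0, 0, 0.25, 0.1, 0, 0.25, 0.22, 0,
                   0.38, 0.05, 0, 0.52, 0.1, 0, 0.62, 0.2, 0, 0.62, 0.32, 0),
                 ncol = 3, byrow = TRUE)
  for (f in seq_len(n_frames)) co[f, , ] <- base + (f - 1) * 0.01
  conf_ensemble(co, top)
}

# Phosphoserine residue fragment (phosphate group) for I/O tests.
sep_fragment <- function() {
  top <- topology(
    name = c("N", "CA", "P", "O1P", "O2P", "O3P"),
    residue_index = rep(0, 6), residue_name = rep("SEP", 6),
    element = c("N", "C", "P", "O", "O", "O")
  )
  xyz <- matrix(c(0, 0, 0, 0.15, 0, 0, 0.4, 0.1, 0,
                  0.55, 0.1, 0, 0.4, 0.25, 0, 0.4, 0.0, 0.15),
                ncol = 3, byrow = TRUE)
  conf_ensemble(xyz, top)
}

# Donor-H-acceptor triple at prescribed r_DA (nm) and H-donor-acceptor
# angle theta (degrees), for hydrogen-bond criterion tests.
hb_triple <- function(r_da, theta) {
  top <- topology(
    name = c("N", "H", "O"), residue_index = c(0, 0, 1),
    residue_name = c("ALA", "ALA", "SER"), element = c("N", "H", "O")
  )
  th <- theta * pi / 180
  xyz <- rbind(c(0, 0, 0), 0.1 * c(cos(th), sin(th), 0), c(r_da, 0, 0))
  conf_ensemble(xyz, top)
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
}
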