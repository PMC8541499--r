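# Shared construction of the two-variant synthetic peptide study system.
#
# A 12-residue peptide sampled as a mixture of three backbone conformers
# (PPII, alpha-helix, extended). The "phosphorylated" variant carries SEP
# at position 7 and a PPII-enriched mixture, emulating the PPII increase
# reported for phosphorylated disordered segments; both variants share
# residue count and backbone topology, as the comparison pipeline
# requires.

peptide_variant_pair <- function(n_frames = 2000, seed = 77,
                                 noise_sd = 0.01) {
  seq_non <- c("GLY", "ALA", "PRO", "ALA", "ALA", "LYS", "SER",
               "ALA", "PRO", "ALA", "ALA", "GLY")
  seq_phos <- replace(seq_non, 7, "SEP")
  conformers <- function(sq) list(
    ppii = build_backbone(sq, -75, 145),
    helix = build_backbone(sq, -57, -47),
    extended = build_backbone(sq, -139, 135)
  )
  mix <- function(sq, w, sd_offset) {
    generate_multistate_ensemble(conformers(sq), w, noise_sd = noise_sd,
                                 n_frames = n_frames, n_replicates = 5,
                                 seed = seed + sd_offset)
  }
  list(
    nonphos = mix(seq_non, c(0.45, 0.25, 0.30), 0),
    phos = mix(seq_phos, c(0.60, 0.10, 0.30), 1)
  )
}
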