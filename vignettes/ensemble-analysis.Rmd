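---
title: "Analysing conformational ensembles of disordered phosphopeptides"
author: "idpensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing conformational ensembles of disordered phosphopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpensemble)
```

## Scope and model

Intrinsically disordered peptides (IDPs) do not fold into a single
structure; they are described by conformational ensembles, and questions
such as "what does phosphorylation do to this peptide?" become questions
about how ensemble-level observables shift. `idpensemble` implements the
analysis layer of that comparison for multi-model PDB ensembles:

* **global dimensions** — per-frame radius of gyration
  $R_g = \sqrt{\sum_i m_i \lVert r_i - r_\mathrm{com} \rVert^2 / \sum_i m_i}$,
  end-to-end distance $R_{ee}$ (CA–CA of the terminal residues by
  default), their distributions, and the shape factor
  $r_s = \langle R_{ee}^2\rangle / \langle R_g^2\rangle$;
* **secondary structure** — per-frame DSSP assignment from backbone
  hydrogen bonds, extended with a polyproline-II (PPII) class;
* **interactions** — residue–residue contact maps (0.4 nm atom-pair
  cutoff), salt bridges via a hydrogen-bond criterion, and
  arginine–tyrosine cation–$\pi$ pairs via a two-distance rule;
* **free-energy landscapes** — 2-D kernel densities over the first two
  principal components of fitted backbone coordinates, in RT units, with
  basin detection, populations and representative frames;
* a **synthetic-ensemble generator** providing ground truth for all of
  the above without molecular dynamics.

All coordinates are handled in nm internally; PDB I/O converts from and
to ångström. Phosphoserine, phosphothreonine and phosphotyrosine are
recognised by their PDB component codes (SEP, TPO, PTR; user-extensible)
and registered in the topology, which is what the salt-bridge analysis
keys on.

## The shape factor and its conventions

For a Gaussian coil $r_s \to 6$ and for a rigid rod $r_s \to 12$, which
makes $r_s$ a convenient compactness/stiffness diagnostic between those
poles. The defining ratio can be read two ways; this package defaults to
the **ratio of mean squares**, because only that convention makes the
two reference values exact limits of the discrete models:

* freely-jointed chain with $N$ bonds of length $b$:
  $\langle R_{ee}^2\rangle = N b^2$,
  $\langle R_g^2\rangle = b^2 N(N+2) / (6(N+1))$, hence
  $r_s = 6(N+1)/(N+2) \to 6$;
* rigid rod: $r_s = 12N/(N+2) \to 12$ exactly.

The alternative, the ratio of squared means, is available via
`convention = "square-of-mean"` and always labelled in the result.

```{r shape}
coil <- generate_gaussian_chain(101, 0.38, 2000, seed = 1)
ensemble_shape_factor(coil)
```

## Error estimation for correlated series

MD-derived series are autocorrelated, so naive standard errors
underestimate. `block_average_error()` implements blocking: the series
is repeatedly pair-averaged and the naive standard error of each level
is tracked together with its own uncertainty. The error climbs with
block size until blocks exceed the correlation time, then plateaus. The
plateau is detected as the stretch of levels (each retaining at least 32
blocks) whose error is within its own uncertainty band of the next
level; the reported error is the inverse-variance-weighted mean over
that stretch. Weighting across the plateau rather than reading off a
single deep level was chosen deliberately: in repeated-realisation
studies it roughly halves the estimator's mean relative error (about 4%
versus 6% for an AR(1) series with $\phi = 0.9$) without biasing it,
because all plateau levels estimate the same quantity. Series shorter
than five usable levels fall back to the naive error, flagged
`converged = FALSE`.

Distributions use a Gaussian kernel with Scott's bandwidth
($\hat\sigma\, n^{-1/5}$). The evaluation grid extends four bandwidths
beyond the data range so that the trapezoidal integral of the density is
1 to within $10^{-3}$ even when much of the sample sits near the range
edges; at three bandwidths, edge-heavy samples can lose just over
$10^{-3}$ of kernel mass.

## DSSP with a PPII extension

Secondary structure is assigned per frame by the Kabsch–Sander
electrostatic hydrogen-bond model,
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol with a bond below $-0.5$ kcal/mol, and the standard pattern
rules (two consecutive n-turns make H/G/I helices; inter-strand bridges
make E/B; single turns T; CA-curvature above 70° bends S) with the usual
priority order. Prolines and chain-start residues never donate; the
amide hydrogen is taken from the file when present or placed 0.1 nm from
N opposite the preceding carbonyl — the same construction reference DSSP
implementations use, so both modes agree on ideal geometry. On a panel
of built conformations (α-helix, 3₁₀, antiparallel two-strand sheet,
turns, PPII) the assignment matches an independent reference DSSP
implementation residue-for-residue; the test suite asserts at least 95%
agreement to leave room for version-specific tie-breaking.

Classic DSSP has no PPII class, yet PPII dominates many disordered
peptides. `ppii_extend()` relabels coil residues whose $(\phi, \psi)$
fall in a PPII window in runs of ≥ 2 consecutive residues. The window
defaults to $\phi \in [-104°, -46°]$, $\psi \in [116°, 174°]$ (i.e.
$(-75°, +145°) \pm 29°$) — commonly used assignment bounds, exposed as
parameters because published extensions differ. P never overwrites a
non-coil DSSP code. Profiles group classes as helix = H+G,
strand = E+B, turn = T, bend = S, PPII = P, irregular = C+I; π-helix is
folded into "irregular" because the helix group is defined as α plus
3₁₀.

## Interaction criteria

Contacts: residues i and j are in contact in a frame when any pair of
heavy atoms (hydrogens optional) is within 0.4 nm. Sequence-adjacent
pairs are reported but flagged, as bonded neighbours are trivially in
contact. Salt bridges between basic donors (Arg NE/NH1/NH2, Lys NZ, the
N-terminal amine as its own `NT` row) and phosphate acceptors
(O1P/O2P/O3P and the ester oxygen) are scored by an angle-dependent
hydrogen-bond rule, $r_{DA} < 0.33 - 0.00044\,\theta^2$ nm with
$\theta$ the H–donor–acceptor angle in degrees; both constants are
configuration. Cation–π pairs require **both** distances from the
arginine cation reference atom to tyrosine CG and CZ to be ≤ 0.6 nm,
inclusive. Arginine has no NZ atom, so the guanidinium centre CZ is the
default reference, configurable to NE/NH1/NH2; the choice is recorded in
the output attributes. Probabilities are percentages of frames; errors
are the standard error of per-replicate probabilities, which is the
natural dispersion measure when an ensemble is pooled from independent
replicates.

## Landscapes, basins and numerical choices

Frames are least-squares fitted onto the ensemble's central structure —
the medoid under backbone RMSD, computed exactly up to 5000 frames and
on an evenly spaced 5000-frame subsample beyond that (the pairwise RMSD
kernel is compiled; the Kabsch trace uses an analytic 3×3 eigenvalue
solve). PCA is then fitted on the pooled frames of both variants with
equal weight per frame, so both project into one representation space
("shared basis"); fitting on one variant only and projecting the other
is available behind `fit_on = "a"`. The conditional free energy is
$F = -\ln(p/p_{max})$ in RT from a 2-D Gaussian KDE (Scott bandwidth per
axis, 200×200 grid over the occupied range ± 3 bandwidths).

Basins are found by steepest descent over the 8-neighbourhood of the
gridded F, restricted to cells at or below `max_level` (5 RT by
default, matching the outermost drawn contour); plateau ties break
towards the lower linear cell index, making the procedure
deterministic. Two numerical choices deserve note:

* **ripple merging** — a finite-sample KDE carries ripples of order
  0.01 RT, which would fragment one physical basin into several minima a
  few cells apart. Minima separated by a barrier below
  `min_barrier = 0.2` RT (far below the 1 RT contour spacing, far above
  the ripple scale) are merged, lower minimum winning.
* **unassigned frames** — frames whose cell lies above `max_level` are
  reported as unassigned rather than forced into a basin, so basin
  populations sum to ≤ 1.

Basin populations are fractions of frames in a basin's cells; the
representative conformation is the member frame nearest the minimum in
PC space.

```{r twostate}
pair <- two_state_conformers()
ms <- generate_multistate_ensemble(pair, c(0.7, 0.3), noise_sd = 0.02,
                                   n_frames = 3000, n_replicates = 5,
                                   seed = 11)
fit <- medoid_fit(ms)
fes <- free_energy_surface(shared_pca(fit$ensemble)$projections_a, 200)
find_basins(fes, max_level = 5)$table
```

## What the synthetic generator does and does not emulate

The generator produces: freely-jointed chains and rigid rods (exact
polymer statistics for the shape-factor limits), full-backbone peptides
at prescribed dihedrals with ideal bond geometry (N–CA 0.1458, CA–C
0.1525, C–N 0.1329 nm, ω = 180°; enough to make hydrogen-bond patterns
assignable), interaction fixtures with exactly placed criterion
distances, and multi-state mixtures with known weights, uniform random
rotations (quaternion method) and isotropic Gaussian noise applied after
rotation. Defaults were fixed once as study conditions: bond length
0.38 nm (a CA–CA virtual bond), 0.02 nm state noise (small thermal
jitter relative to the 0.1 nm inter-state deformation of
`two_state_conformers()`), five replicates, 10⁴ analysis frames for
quantitative recoveries (about the frame count a combined trajectory is
thinned to) and 2000 frames in the narrative scripts.

Two-state fixtures are built as a coil plus a *deformation* of the same
coil rather than two unrelated shapes: superposing a structure onto a
dissimilar reference is ill-conditioned, which widens and can split its
cluster in PC space — a property of Cartesian-PCA landscapes generally,
not of this implementation. Real IDP ensembles differ from all of this
in important ways: continuous conformational families rather than
discrete states, sequence-dependent dihedral statistics, side chains,
and solvent-mediated interactions. Passing the synthetic recoveries
therefore validates the *analysis operators* (estimators, criteria,
assignment and basin logic), not any claim about real peptides.

## Problem sizes and limitations

The shipped tests and scripts run at desk scale: 10⁴ frames for the
shape-factor, landscape and blocking calibrations, 2000 frames for the
two-variant narrative, 200×200 landscape grids. Block-error calibration
uses 2¹⁴-2¹⁶-point series where the AR(1) closed form
$\sigma\sqrt{(1+\phi)/(1-\phi)}/\sqrt{n}$ is an accurate reference.

Known limitations: DSSP β-bulge ladders are not merged (isolated-bridge
vs extended labelling can differ from reference implementations in
bulged sheets, covered by the 95% agreement margin); the PPII window is
a documented choice, not a universal constant; medoid selection beyond
5000 frames is subsampled; cation–π is limited to Arg/Tyr as defined by
the two-distance criterion; no binary trajectory formats — ensembles
enter as multi-model PDB or the plain-text frames format.
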