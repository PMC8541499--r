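#' @useDynLib idpensemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Residue codes recognised as phosphorylated (PDB chemical-component codes).
.default_phospho_codes <- c("SEP", "TPO", "PTR")

# Atomic masses (u) keyed on element symbol; fallback for bead models.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305, CA = 40.078, X = 1.0
)

#' Recognised phosphorylated residue codes
#'
#' Returns the residue names treated as phosphorylated when building a
#' topology: `SEP` (phosphoserine), `TPO` (phosphothreonine) and `PTR`
#' (phosphotyrosine), optionally extended by the user.
#'
#' @param extra Character vector of additional residue codes to recognise.
#' @return Character vector of residue codes.
#' @export
phospho_codes <- function(extra = NULL) {
  unique(c(.default_phospho_codes, toupper(extra)))
}

#' Look up an atomic mass
#'
#' Masses are keyed on the element symbol; when the element is missing the
#' first alphabetic character of the atom name is used as a fallback.
#'
#' @param element Element symbols (may contain `NA`).
#' @param name Atom names used as fallback.
#' @return Numeric vector of masses in u.
#' @export
element_mass <- function(element, name) {
  el <- toupper(ifelse(is.na(element) | element == "", NA, element))
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)), 1, 1))
  el[is.na(el)] <- fallback[is.na(el)]
  m <- unname(.element_masses[el])
  m[is.na(m)] <- 1.0
  m
}

#' Build a topology
#'
#' A topology is the per-atom annotation shared by every frame of an
#' ensemble: atom name, element, mass (u), 0-based residue index, 3-letter
#' residue name and chain id. Residues whose name is a recognised
#' phospho-code (see [phospho_codes()]) are registered in
#' `phospho_residues`.
#'
#' @param name,residue_name,chain_id Character vectors, one entry per atom.
#' @param residue_index Integer vector of 0-based residue ordinals,
#'   non-decreasing within a chain.
#' @param element Element symbols; missing entries are inferred from `name`.
#' @param mass Atomic masses in u; missing entries are filled from the
#'   element table.
#' @param phospho_aliases Extra residue codes to treat as phosphorylated.
#' @return An object of class `idp_topology`: a list with elements `atoms`
#'   (data.frame) and `phospho_residues` (integer vector of residue
#'   indices).
#' @export
topology <- function(name, residue_index, residue_name,
                     chain_id = "A", element = NA, mass = NA,
                     phospho_aliases = NULL) {
  n <- length(name)
  stopifnot(n >= 1, length(residue_index) == n, length(residue_name) == n)
  atoms <- data.frame(
    name = as.character(name),
    element = rep_len(as.character(element), n),
    mass = rep_len(as.numeric(mass), n),
    residue_index = as.integer(residue_index),
    residue_name = toupper(as.character(residue_name)),
    chain_id = rep_len(as.character(chain_id), n),
    stringsAsFactors = FALSE
  )
  miss <- is.na(atoms$mass)
  atoms$mass[miss] <- element_mass(atoms$element[miss], atoms$name[miss])
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (any(atoms$residue_index < 0)) stop("residue_index must be non-negative")
  for (ch in unique(atoms$chain_id)) {
    ri <- atoms$residue_index[atoms$chain_id == ch]
    if (is.unsorted(ri)) stop("residue_index must be non-decreasing within a chain")
  }
  codes <- phospho_codes(phospho_aliases)
  phos <- sort(unique(atoms$residue_index[atoms$residue_name %in% codes]))
  structure(list(atoms = atoms, phospho_residues = as.integer(phos)),
            class = "idp_topology")
}

#' @export
print.idp_topology <- function(x, ...) {
  cat(sprintf("idp_topology: %d atoms, %d residues", nrow(x$atoms),
              length(unique(x$atoms$residue_index))))
  if (length(x$phospho_residues))
    cat(sprintf(", phospho residues: %s",
                paste(x$phospho_residues, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Construct a conformational ensemble
#'
#' The universal container of the package: an array of frames over a fixed
#' topology. Coordinates are in nm throughout.
#'
#' @param coords Numeric array `frames x atoms x 3` (nm), or an
#'   `atoms x 3` matrix for a single frame.
#' @param topology An [topology()] object with one record per atom.
#' @param replicate_id Integer per-frame replicate label, contiguous from 0.
#'   Defaults to all-0.
#' @param frame_stride Optional time between saved frames (ps).
#' @return Object of class `conf_ensemble` with elements `topology`,
#'   `coords`, `replicate_id`, `frame_stride`.
#' @export
conf_ensemble <- function(coords, topology, replicate_id = NULL,
                          frame_stride = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!inherits(topology, "idp_topology")) stop("topology must be an idp_topology")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("frame atom count (", dim(coords)[2], ") != topology atom count (",
         nrow(topology$atoms), ")")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  nf <- dim(coords)[1]
  if (is.null(replicate_id)) replicate_id <- integer(nf)
  replicate_id <- as.integer(replicate_id)
  stopifnot(length(replicate_id) == nf)
  ids <- sort(unique(replicate_id))
  if (!identical(ids, seq(0L, max(ids))))
    stop("replicate_id values must be contiguous from 0")
  structure(list(topology = topology, coords = coords,
                 replicate_id = replicate_id, frame_stride = frame_stride),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble: %d frames x %d atoms, %d residues, %d replicate(s)\n",
              n_frames(x), n_atoms(x), n_residues(x),
              length(unique(x$replicate_id))))
  invisible(x)
}

#' Ensemble dimensions
#' @param ensemble A `conf_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' @rdname n_frames
#' @export
n_residues <- function(ensemble) length(unique(ensemble$topology$atoms$residue_index))

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param ensemble A `conf_ensemble`.
#' @param i Frame number (1-based).
#' @return `atoms x 3` numeric matrix (nm).
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$coords[i, , ], ncol = 3)
}

#' Select a sub-ensemble of atoms
#'
#' @param ensemble A `conf_ensemble`.
#' @param selector Either a function taking the topology `atoms` data.frame
#'   and returning a logical vector, a logical/integer index vector, or one
#'   of the shortcuts `"backbone"` (atoms named N, CA, C, O), `"calpha"`,
#'   `"heavy"` (non-hydrogen).
#' @return A `conf_ensemble` restricted to the selected atoms; frame count
#'   and order are preserved.
#' @export
select_atoms <- function(ensemble, selector) {
  atoms <- ensemble$topology$atoms
  keep <-
    if (is.function(selector)) selector(atoms)
    else if (is.character(selector) && length(selector) == 1 &&
             selector %in% c("backbone", "calpha", "heavy")) {
      switch(selector,
        backbone = atoms$name %in% c("N", "CA", "C", "O"),
        calpha   = atoms$name == "CA",
        heavy    = !is_hydrogen(atoms))
    } else selector
  if (is.logical(keep)) keep <- which(keep)
  keep <- as.integer(keep)
  if (length(keep) == 0) stop("selection matched no atoms")
  top <- ensemble$topology
  top$atoms <- atoms[keep, , drop = FALSE]
  rownames(top$atoms) <- NULL
  top$phospho_residues <- intersect(top$phospho_residues,
                                    unique(top$atoms$residue_index))
  conf_ensemble(ensemble$coords[, keep, , drop = FALSE], top,
                replicate_id = ensemble$replicate_id,
                frame_stride = ensemble$frame_stride)
}

# Hydrogen detection from element, falling back to atom-name pattern
# (e.g. "HA", "1HB", "HH11").
is_hydrogen <- function(atoms) {
  el <- toupper(atoms$element)
  known <- !is.na(el) & nzchar(el)
  out <- logical(nrow(atoms))
  out[known] <- el[known] == "H"
  nm <- toupper(gsub("^[0-9]+", "", atoms$name))
  out[!known] <- substr(nm[!known], 1, 1) == "H"
  out
}

#' Concatenate replicate ensembles
#'
#' Stacks several ensembles sharing a topology into one, relabelling
#' `replicate_id` by list position.
#'
#' @param ensembles List of `conf_ensemble` objects with identical
#'   topologies.
#' @return A single `conf_ensemble`.
#' @export
concatenate_replicates <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  ref <- ensembles[[1]]$topology
  for (e in ensembles)
    if (!identical(e$topology$atoms, ref$atoms))
      stop("topology mismatch between ensembles")
  nf <- vapply(ensembles, n_frames, integer(1))
  coords <- array(0, c(sum(nf), nrow(ref$atoms), 3))
  at <- 0L
  for (e in ensembles) {
    coords[at + seq_len(n_frames(e)), , ] <- e$coords
    at <- at + n_frames(e)
  }
  conf_ensemble(coords, ref,
                replicate_id = rep(seq_along(ensembles) - 1L, times = nf),
                frame_stride = ensembles[[1]]$frame_stride)
}

#' Equal-spacing frame subsampling
#'
#' Retains `n` frames at (as near as possible) constant stride, always
#' keeping the first frame, as when a combined trajectory is thinned to a
#' fixed analysis frame count.
#'
#' @param ensemble A `conf_ensemble`.
#' @param n Requested frame count (`<=` current frame count).
#' @return A `conf_ensemble` with `n` frames. Replicate ids are compacted
#'   to stay contiguous from 0.
#' @export
subsample_frames <- function(ensemble, n) {
  nf <- n_frames(ensemble)
  stopifnot(n >= 1, n <= nf)
  # constant stride nf/n (exact when n divides nf), first frame retained
  idx <- floor(seq(0, nf, length.out = n + 1))[seq_len(n)] + 1
  keep_frames(ensemble, idx)
}

# Frame subsetting helper used by subsampling and replicate extraction.
keep_frames <- function(ensemble, idx) {
  rid <- ensemble$replicate_id[idx]
  rid <- match(rid, sort(unique(rid))) - 1L
  conf_ensemble(ensemble$coords[idx, , , drop = FALSE], ensemble$topology,
                replicate_id = rid, frame_stride = ensemble$frame_stride)
}

#' Extract the frames of one replicate
#' @param ensemble A `conf_ensemble`.
#' @param id Replicate label (0-based).
#' @return A `conf_ensemble` containing only that replicate's frames.
#' @export
extract_replicate <- function(ensemble, id) {
  idx <- which(ensemble$replicate_id == id)
  if (!length(idx)) stop("no frames with replicate_id ", id)
  keep_frames(ensemble, idx)
}
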