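#' Read a multi-model PDB file as a conformational ensemble
#'
#' One ensemble frame per `MODEL`; a file without `MODEL` records yields a
#' single frame. Coordinates are converted from the PDB's angstrom to the
#' package-internal nm. Residues named with a recognised phospho-code
#' (SEP/TPO/PTR plus `phospho_aliases`) are registered in the topology's
#' `phospho_residues`. `replicate_id` defaults to 0 for all frames.
#'
#' @param path Path to a PDB file.
#' @param phospho_aliases Extra residue codes treated as phosphorylated.
#' @return A [conf_ensemble()].
#' @export
read_multimodel_pdb <- function(path, phospho_aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(readLines(path, warn = FALSE), path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  residx <- cumsum(c(0L, key[-1] != key[-length(key)]))
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  top <- topology(
    name = at$elety, residue_index = residx, residue_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "A", at$chain), element = elesy,
    phospho_aliases = phospho_aliases
  )
  nf <- nrow(pdb$xyz)
  coords <- array(0, c(nf, nrow(at), 3))
  for (i in seq_len(nf))
    coords[i, , ] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
  conf_ensemble(coords, top)
}

# Structural pre-checks bio3d does not report precisely: malformed
# coordinate fields (with line number) and per-MODEL atom-count mismatches.
.validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinates at line ", i, " of ", path)
  }
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    grp <- cumsum(model_starts)
    counts <- table(grp[is_atom & grp > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("inconsistent atom count across MODELs in ", path)
  }
  invisible(TRUE)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` pair per frame (also for single-frame
#' ensembles) with coordinates converted nm to angstrom. Residue names,
#' including phospho-codes, chain ids and element symbols are preserved.
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  at <- ensemble$topology$atoms
  nf <- n_frames(ensemble)
  xyz <- matrix(0, nrow = nf, ncol = 3 * nrow(at))
  for (i in seq_len(nf))
    xyz[i, ] <- as.vector(t(frame_coords(ensemble, i))) * 10
  elesy <- at$element
  elesy[is.na(elesy)] <- ""
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$residue_index + 1L, resid = at$residue_name,
    elety = at$name, chain = at$chain_id, elesy = elesy
  )
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MODEL", lines))) {
    is_atom <- grepl("^(ATOM  |HETATM)", lines)
    first <- which(is_atom)[1]; last <- max(which(is_atom))
    lines <- c(lines[seq_len(first - 1)], "MODEL        1",
               lines[first:last], "ENDMDL",
               if (last < length(lines)) lines[(last + 1):length(lines)])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write / read the auxiliary plain-text frames format
#'
#' A two-file representation for synthetic ensembles: a TSV of coordinates
#' (columns `frame`, `x`, `y`, `z`, one row per atom per frame, nm) and a
#' YAML topology sidecar (`<path>.topology.yaml`) listing atom name,
#' element, mass, residue index, residue name and chain, plus per-frame
#' replicate labels and the frame stride.
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Path of the frames TSV; the sidecar is written next to it.
#' @return Invisibly, `path`.
#' @export
write_frames_txt <- function(ensemble, path) {
  nf <- n_frames(ensemble); na <- n_atoms(ensemble)
  co <- ensemble$coords
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    x = as.vector(t(co[, , 1])), y = as.vector(t(co[, , 2])),
    z = as.vector(t(co[, , 3]))
  )
  utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    atoms = lapply(seq_len(na), function(i) {
      a <- ensemble$topology$atoms[i, ]
      list(name = a$name, element = if (is.na(a$element)) "" else a$element,
           mass = a$mass, residue_index = a$residue_index,
           residue_name = a$residue_name, chain = a$chain_id)
    }),
    replicate_id = as.integer(ensemble$replicate_id),
    frame_stride = ensemble$frame_stride
  )
  yaml::write_yaml(side, paste0(path, ".topology.yaml"))
  invisible(path)
}

#' @rdname write_frames_txt
#' @param phospho_aliases Extra residue codes treated as phosphorylated.
#' @export
read_frames_txt <- function(path, phospho_aliases = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- yaml::read_yaml(paste0(path, ".topology.yaml"))
  na <- length(side$atoms)
  nf <- nrow(df) / na
  if (nf != round(nf)) stop("frame table length is not a multiple of atom count")
  get <- function(field) vapply(side$atoms, function(a) as.character(a[[field]]), "")
  top <- topology(
    name = get("name"), residue_index = as.integer(get("residue_index")),
    residue_name = get("residue_name"), chain_id = get("chain"),
    element = ifelse(get("element") == "", NA, get("element")),
    mass = as.numeric(get("mass")), phospho_aliases = phospho_aliases
  )
  coords <- array(0, c(nf, na, 3))
  coords[, , 1] <- matrix(df$x, nrow = nf, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nrow = nf, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nrow = nf, byrow = TRUE)
  conf_ensemble(coords, top,
                replicate_id = side$replicate_id %||% NULL,
                frame_stride = side$frame_stride)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
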