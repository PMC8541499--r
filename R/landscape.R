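#' Fit an ensemble onto its central (medoid) structure
#'
#' The central structure is the frame minimising the sum of backbone RMSDs
#' to all frames (computed exactly up to `max_exact` frames, else on an
#' evenly spaced subsample of that size); every frame is then
#' least-squares superposed onto it, the transform being computed on the
#' fitting selection and applied to all atoms.
#'
#' @param ensemble A [conf_ensemble()].
#' @param selection Atom selection used for the fit (see [select_atoms()]).
#' @param max_exact Largest frame count for which the medoid search is
#'   exact.
#' @return List with `ensemble` (aligned) and `medoid` (frame index,
#'   1-based).
#' @export
medoid_fit <- function(ensemble, selection = "backbone", max_exact = 5000) {
  sub <- select_atoms(ensemble, selection)
  sel_idx <- which(selection_mask(ensemble, selection))
  nf <- n_frames(ensemble)
  idx <- if (nf <= max_exact) seq_len(nf)
         else unique(floor(seq(1, nf, length.out = max_exact)))
  sums <- cpp_medoid_sums(sub$coords, as.integer(idx))
  medoid <- idx[which.min(sums)]
  fitted <- ensemble
  fitted$coords <- cpp_fit_frames(ensemble$coords, as.integer(medoid),
                                  as.integer(sel_idx))
  list(ensemble = fitted, medoid = medoid)
}

# Logical mask of a selection over the full topology.
selection_mask <- function(ensemble, selector) {
  atoms <- ensemble$topology$atoms
  keep <-
    if (is.function(selector)) selector(atoms)
    else if (is.character(selector) && length(selector) == 1)
      switch(selector,
             backbone = atoms$name %in% c("N", "CA", "C", "O"),
             calpha = atoms$name == "CA",
             heavy = !is_hydrogen(atoms),
             stop("unknown selection: ", selector))
    else {
      m <- logical(nrow(atoms)); m[selector] <- TRUE; m
    }
  if (!any(keep)) stop("selection matched no atoms")
  keep
}

#' Backbone RMSD of every frame to a reference frame
#'
#' @param ensemble A [conf_ensemble()].
#' @param ref Reference frame index (1-based).
#' @param selection Atom selection for the RMSD.
#' @return Numeric vector of minimal (superposed) RMSDs in nm.
#' @export
rmsd_to_frame <- function(ensemble, ref, selection = "backbone") {
  sub <- select_atoms(ensemble, selection)
  as.vector(cpp_rmsd_to_ref(sub$coords, as.integer(ref)))
}

# Flatten frames x atoms x 3 to frames x 3*atoms (axis-major, consistent
# everywhere PCA coordinates are used).
flatten_coords <- function(coords) {
  matrix(coords, nrow = dim(coords)[1])
}

#' Principal component basis shared between two ensembles
#'
#' PCA of the (fitted) Cartesian coordinates of the selected atoms. In
#' two-ensemble mode the basis is fitted on the pooled frames of both
#' ensembles with equal weight per frame, so that both variants are
#' projected into the same representation space and are directly
#' comparable; single-ensemble mode fits on one ensemble alone.
#'
#' @param ensemble_a A fitted [conf_ensemble()] (see [medoid_fit()]).
#' @param ensemble_b Optional second fitted ensemble with the same atom
#'   count.
#' @param selection Atom selection entering the PCA (default backbone).
#' @param fit_on `"pooled"` (default) or `"a"`: fit the basis on the pooled
#'   frames or on ensemble A only (B is then projected onto A's basis).
#' @return Object of class `pc_basis`: list with `mean_structure`,
#'   `components` (columns, orthonormal), `explained_variance` (nm^2,
#'   non-increasing), `projections_a` and (if given) `projections_b`
#'   (`frames x 2` matrices over PC1/PC2), and `scores_full_a` for
#'   reconstruction checks.
#' @export
shared_pca <- function(ensemble_a, ensemble_b = NULL, selection = "backbone",
                       fit_on = c("pooled", "a")) {
  fit_on <- match.arg(fit_on)
  xa <- flatten_coords(select_atoms(ensemble_a, selection)$coords)
  xb <- NULL
  if (!is.null(ensemble_b)) {
    xb <- flatten_coords(select_atoms(ensemble_b, selection)$coords)
    if (ncol(xb) != ncol(xa))
      stop("ensembles have different selected atom counts")
  }
  xfit <- if (is.null(xb) || fit_on == "a") xa else rbind(xa, xb)
  ctr <- colMeans(xfit)
  sv <- svd(sweep(xfit, 2, ctr))
  comp <- sv$v
  expl <- sv$d^2 / (nrow(xfit) - 1)
  proj <- function(x) {
    p <- sweep(x, 2, ctr) %*% comp[, 1:2, drop = FALSE]
    colnames(p) <- c("PC1", "PC2")
    p
  }
  structure(list(
    mean_structure = ctr, components = comp, explained_variance = expl,
    projections_a = proj(xa),
    projections_b = if (!is.null(xb)) proj(xb) else NULL,
    scores_full_a = sweep(xa, 2, ctr) %*% comp,
    fit_on = fit_on
  ), class = "pc_basis")
}

#' Conditional free-energy landscape over the first two PCs
#'
#' 2-D Gaussian kernel density estimate of the projections, converted to a
#' free energy `F = -ln(p / p_max)` in RT units so the global minimum is
#' 0. Bandwidths per axis follow Scott's rule, `sd * n^(-1/6)`; the grid
#' spans the occupied range extended by three bandwidths.
#'
#' @param projections `frames x 2` matrix of (PC1, PC2) projections.
#' @param grid_size Grid points per axis.
#' @param replicate_id Optional per-frame replicate labels carried along.
#' @param bandwidth Optional length-2 kernel standard deviations.
#' @return Object of class `energy_landscape`: list with `x`, `y` (grid
#'   axes), `free_energy` (`grid_size x grid_size`, `[i, j]` at
#'   `(x[i], y[j])`), `density_bandwidth`, `projections`,
#'   `replicate_id`.
#' @export
free_energy_surface <- function(projections, grid_size = 200,
                                replicate_id = NULL, bandwidth = NULL) {
  projections <- as.matrix(projections)
  stopifnot(ncol(projections) == 2)
  n <- nrow(projections)
  if (n < 100) stop("free-energy surface needs at least 100 frames")
  sds <- apply(projections, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate projections: zero variance on a PC")
  if (is.null(bandwidth)) bandwidth <- sds * n^(-1 / 6)
  lims <- c(min(projections[, 1]) - 3 * bandwidth[1],
            max(projections[, 1]) + 3 * bandwidth[1],
            min(projections[, 2]) - 3 * bandwidth[2],
            max(projections[, 2]) + 3 * bandwidth[2])
  # MASS::kde2d uses kernel sd = h / 4.
  kd <- MASS::kde2d(projections[, 1], projections[, 2],
                    h = 4 * bandwidth, n = grid_size, lims = lims)
  fe <- -log(kd$z / max(kd$z))
  structure(list(x = kd$x, y = kd$y, free_energy = fe,
                 density_bandwidth = bandwidth, projections = projections,
                 replicate_id = replicate_id),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy_landscape: %dx%d grid, %d frames, bw = (%.3g, %.3g)\n",
              length(x$x), length(x$y), nrow(x$projections),
              x$density_bandwidth[1], x$density_bandwidth[2]))
  invisible(x)
}

#' Detect free-energy basins on a gridded landscape
#'
#' Grid cells at or below `max_level` (RT) are assigned to local minima by
#' steepest descent over the 8-neighbourhood of the gridded free energy
#' (plateau ties broken towards the lower linear index, so the procedure
#' is deterministic). Each basin's population is the fraction of frames
#' whose projection falls in its cells; frames in cells above `max_level`
#' remain unassigned. Basins are ordered by population; minima are
#' classified by energy (at most 1, 2 or 3 RT).
#'
#' Kernel density estimates carry sampling ripples far smaller than the
#' 1 RT contour scale; minima separated by a barrier below `min_barrier`
#' are therefore merged into one basin (lower minimum wins) before
#' populations are computed.
#'
#' @param landscape An [free_energy_surface()] result.
#' @param max_level Highest free energy (RT) considered part of a basin.
#' @param min_barrier Barrier height (RT) below which adjacent basins are
#'   merged.
#' @return Object of class `basin_set`: list with `table` (data.frame:
#'   `basin_id`, `min_pc1`, `min_pc2`, `min_F_RT`, `population`,
#'   `energy_class`, `representative_frame`), `cell_basin` (grid matrix of
#'   basin ids, NA outside), `frame_basin` (per-frame basin id, NA
#'   unassigned).
#' @export
find_basins <- function(landscape, max_level = 5, min_barrier = 0.2) {
  fe <- landscape$free_energy
  nx <- nrow(fe); ny <- ncol(fe)
  ncell <- nx * ny
  # Steepest-descent pointer for every cell (linear, column-major index).
  ptr <- integer(ncell)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      cell <- i + (j - 1) * nx
      best <- cell; bestf <- fe[i, j]
      for (dj in -1:1) {
        jj <- j + dj
        if (jj < 1 || jj > ny) next
        for (di in -1:1) {
          ii <- i + di
          if (ii < 1 || ii > nx || (di == 0 && dj == 0)) next
          nb <- ii + (jj - 1) * nx
          if (fe[ii, jj] < bestf - 1e-12 ||
              (abs(fe[ii, jj] - bestf) <= 1e-12 && nb < best)) {
            bestf <- fe[ii, jj]; best <- nb
          }
        }
      }
      ptr[cell] <- best
    }
  }
  # Resolve pointer chains to their terminal minima.
  repeat {
    nxt <- ptr[ptr]
    if (identical(nxt, ptr)) break
    ptr <- nxt
  }
  minima <- which(ptr == seq_len(ncell) & as.vector(fe) <= max_level)
  if (!length(minima)) {
    warning("no free-energy minima at or below ", max_level, " RT")
    return(structure(list(table = data.frame(), cell_basin = NULL,
                          frame_basin = NULL),
                     class = "basin_set"))
  }
  cell_ok <- as.vector(fe) <= max_level
  cell_basin <- rep(NA_integer_, ncell)
  keep <- cell_ok & ptr %in% minima
  cell_basin[keep] <- match(ptr[keep], minima)

  # Merge basins separated by a negligible barrier (KDE ripple scale).
  fev <- as.vector(fe)
  min_f <- fev[minima]
  repeat {
    nb_ids <- sort(unique(cell_basin[!is.na(cell_basin)]))
    if (length(nb_ids) < 2) break
    # lowest saddle between every adjacent basin pair
    saddle <- matrix(Inf, length(minima), length(minima))
    cells <- which(!is.na(cell_basin))
    ii <- (cells - 1) %% nx + 1
    jj <- (cells - 1) %/% nx + 1
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii2 <- ii + di; jj2 <- jj + dj
      valid <- ii2 >= 1 & ii2 <= nx & jj2 >= 1 & jj2 <= ny
      c2 <- ii2[valid] + (jj2[valid] - 1) * nx
      c1 <- cells[valid]
      b1 <- cell_basin[c1]; b2 <- cell_basin[c2]
      sel <- !is.na(b2) & b2 != b1
      if (!any(sel)) next
      h <- pmax(fev[c1[sel]], fev[c2[sel]])
      pa <- pmin(b1[sel], b2[sel]); pb <- pmax(b1[sel], b2[sel])
      hmin <- tapply(h, paste(pa, pb), min)
      for (key in names(hmin)) {
        ab <- as.integer(strsplit(key, " ")[[1]])
        if (hmin[[key]] < saddle[ab[1], ab[2]])
          saddle[ab[1], ab[2]] <- saddle[ab[2], ab[1]] <- hmin[[key]]
      }
    }
    barrier <- saddle - outer(min_f, min_f, pmax)
    diag(barrier) <- Inf
    barrier[!is.finite(saddle)] <- Inf
    if (min(barrier) >= min_barrier) break
    idx2 <- which(barrier == min(barrier), arr.ind = TRUE)[1, ]
    a <- idx2[1]; b <- idx2[2]
    lo <- if (min_f[a] < min_f[b] ||
              (min_f[a] == min_f[b] && a < b)) a else b
    hi <- if (lo == a) b else a
    cell_basin[cell_basin == hi] <- lo
    min_f[hi] <- Inf
  }
  live <- sort(unique(cell_basin[!is.na(cell_basin)]))
  minima <- minima[live]
  cell_basin <- match(cell_basin, live)

  # Bin frames onto grid cells (nearest grid point).
  pr <- landscape$projections
  gx <- landscape$x; gy <- landscape$y
  ix <- pmin(pmax(round((pr[, 1] - gx[1]) / (gx[2] - gx[1])) + 1, 1), nx)
  iy <- pmin(pmax(round((pr[, 2] - gy[1]) / (gy[2] - gy[1])) + 1, 1), ny)
  frame_cell <- ix + (iy - 1) * nx
  frame_basin <- cell_basin[frame_cell]

  nfrm <- nrow(pr)
  rows <- lapply(seq_along(minima), function(b) {
    cell <- minima[b]
    i <- (cell - 1) %% nx + 1; j <- (cell - 1) %/% nx + 1
    minf <- fe[i, j]
    members <- which(!is.na(frame_basin) & frame_basin == b)
    rep_frame <- if (length(members)) {
      d2 <- (pr[members, 1] - gx[i])^2 + (pr[members, 2] - gy[j])^2
      members[which.min(d2)]
    } else NA_integer_
    data.frame(
      basin_id = b, min_pc1 = gx[i], min_pc2 = gy[j], min_F_RT = minf,
      population = length(members) / nfrm,
      energy_class = if (minf <= 1) "<=1RT" else if (minf <= 2) "<=2RT"
                     else if (minf <= 3) "<=3RT" else ">3RT",
      representative_frame = rep_frame
    )
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$population)
  tab <- tab[ord, ]
  # Renumber basins by population rank.
  remap <- match(seq_along(minima), tab$basin_id)
  cell_basin <- remap[cell_basin]
  frame_basin <- remap[frame_basin]
  tab$basin_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 cell_basin = matrix(cell_basin, nx, ny),
                 frame_basin = frame_basin),
            class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat(sprintf("basin_set: %d basin(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Representative frame of a basin
#'
#' The basin member whose projection is nearest (Euclidean in PC space) to
#' the basin minimum.
#'
#' @param basins A `basin_set` from [find_basins()].
#' @param basin_id Basin identifier (population rank).
#' @return Frame index (1-based).
#' @export
representative_frame <- function(basins, basin_id) {
  row <- basins$table[basins$table$basin_id == basin_id, ]
  if (!nrow(row)) stop("no basin with id ", basin_id)
  row$representative_frame
}
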