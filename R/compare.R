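#' Parameter set for a two-variant comparison
#'
#' Collects every tunable of the analysis stages so that both variants are
#' analysed with identical parameters and the resolved set can be embedded
#' in the report for provenance.
#'
#' @param endpoint_atom Atom used for the end-to-end distance.
#' @param rs_convention Shape-factor convention (see [shape_factor()]).
#' @param contact_cutoff Contact distance (nm).
#' @param contact_scope `"heavy"` or `"all"` atoms for contacts.
#' @param hb_r0,hb_k Hydrogen-bond criterion constants (nm; nm/deg^2).
#' @param cation_atom Arginine cation reference atom.
#' @param cation_cutoff Cation-pi distance cutoff (nm).
#' @param ppii_phi,ppii_psi PPII dihedral windows (degrees).
#' @param ppii_min_run Minimum PPII run length (residues).
#' @param hydrogens Amide-hydrogen mode for DSSP (`"detect"`/`"place"`).
#' @param grid_size Landscape grid points per axis.
#' @param max_level Basin detection level (RT).
#' @return Named list of class `comparison_config`.
#' @export
comparison_config <- function(endpoint_atom = "CA",
                              rs_convention = "mean-square",
                              contact_cutoff = 0.4, contact_scope = "heavy",
                              hb_r0 = 0.33, hb_k = 0.00044,
                              cation_atom = "CZ", cation_cutoff = 0.6,
                              ppii_phi = c(-104, -46), ppii_psi = c(116, 174),
                              ppii_min_run = 2, hydrogens = "detect",
                              grid_size = 200, max_level = 5) {
  structure(list(
    endpoint_atom = endpoint_atom, rs_convention = rs_convention,
    contact_cutoff = contact_cutoff, contact_scope = contact_scope,
    hb_r0 = hb_r0, hb_k = hb_k, cation_atom = cation_atom,
    cation_cutoff = cation_cutoff, ppii_phi = ppii_phi, ppii_psi = ppii_psi,
    ppii_min_run = ppii_min_run, hydrogens = hydrogens,
    grid_size = grid_size, max_level = max_level
  ), class = "comparison_config")
}

# Single-variant analysis pass shared by run_comparison.
analyse_variant <- function(ensemble, config, with_backbone) {
  rg <- radius_of_gyration(ensemble)
  ree <- end_to_end_distance(ensemble, config$endpoint_atom)
  if (config$rs_convention == "mean-square") {
    rg_b <- block_average_error(transform_series(rg, function(x) x^2, "Rg2"))
    ree_b <- block_average_error(transform_series(ree, function(x) x^2, "Ree2"))
  } else {
    rg_b <- block_average_error(rg)
    ree_b <- block_average_error(ree)
  }
  out <- list(
    rg = block_average_error(rg),
    ree = block_average_error(ree),
    rs = shape_factor(rg_b, ree_b, convention = config$rs_convention),
    kde_rg = kde_distribution(rg),
    kde_ree = kde_distribution(ree),
    contacts = contact_map(ensemble, cutoff = config$contact_cutoff,
                           atom_scope = config$contact_scope),
    salt_bridges = suppressWarnings(
      salt_bridge_table(ensemble, r0 = config$hb_r0, k = config$hb_k)),
    cation_pi = cation_pi_table(ensemble, cutoff = config$cation_cutoff,
                                cation_atom = config$cation_atom)
  )
  if (with_backbone) {
    ss <- dssp_assign(ensemble, hydrogens = config$hydrogens)
    ss <- ppii_extend(ss, backbone_dihedrals(ensemble),
                      phi_window = config$ppii_phi,
                      psi_window = config$ppii_psi,
                      min_run = config$ppii_min_run)
    out$ss_profile <- ss_profile(ss)
  }
  out
}

#' Run the full two-variant comparison
#'
#' Executes the complete pipeline on a non-phosphorylated and a
#' phosphorylated ensemble with identical parameters: global dimensions
#' (block-averaged Rg, Ree, shape factor, KDE curves), secondary-structure
#' profiles (when full backbones are present), contact maps and their
#' difference, salt-bridge and cation-pi tables, and the free-energy
#' landscape pair on a shared PC basis with basin tables. The result is
#' deterministic given the inputs and config, and the inputs are not
#' modified.
#'
#' @param ensemble_nonphos,ensemble_phos [conf_ensemble()] objects with the
#'   same residue count and at least 100 frames each.
#' @param config A [comparison_config()].
#' @return Object of class `variant_comparison`: list with `config`,
#'   `variants` (per-variant analyses), `contact_delta`, `ss_delta` (when
#'   available), `pca`, `landscapes`, `basins`.
#' @export
run_comparison <- function(ensemble_nonphos, ensemble_phos,
                           config = comparison_config()) {
  if (n_residues(ensemble_nonphos) != n_residues(ensemble_phos))
    stop("variants have different residue counts")
  bb <- function(e) {
    at <- e$topology$atoms
    all(c("N", "CA", "C", "O") %in% at$name)
  }
  with_backbone <- bb(ensemble_nonphos) && bb(ensemble_phos) &&
    all(!is.na(residue_backbone_index(ensemble_nonphos)$N))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  va <- stage("analyse nonphos",
              analyse_variant(ensemble_nonphos, config, with_backbone))
  vb <- stage("analyse phos",
              analyse_variant(ensemble_phos, config, with_backbone))
  cdelta <- stage("contact delta", contact_delta(vb$contacts, va$contacts))
  fa <- stage("fit nonphos", medoid_fit(ensemble_nonphos))
  fb <- stage("fit phos", medoid_fit(ensemble_phos))
  pca <- stage("shared PCA", shared_pca(fa$ensemble, fb$ensemble))
  la <- stage("landscape nonphos",
              free_energy_surface(pca$projections_a, config$grid_size,
                                  ensemble_nonphos$replicate_id))
  lb <- stage("landscape phos",
              free_energy_surface(pca$projections_b, config$grid_size,
                                  ensemble_phos$replicate_id))
  ba <- stage("basins nonphos",
              suppressWarnings(find_basins(la, config$max_level)))
  bbas <- stage("basins phos",
                suppressWarnings(find_basins(lb, config$max_level)))
  out <- list(
    config = config,
    variants = list(nonphos = va, phos = vb),
    contact_delta = cdelta,
    pca = pca,
    landscapes = list(nonphos = la, phos = lb),
    basins = list(nonphos = ba, phos = bbas)
  )
  if (with_backbone) {
    pa <- va$ss_profile$per_residue
    pb <- vb$ss_profile$per_residue
    cls <- c("helix", "strand", "turn", "bend", "ppii", "irregular")
    out$ss_delta <- cbind(pa[, c("residue_index", "residue_name")],
                          pb[cls] - pa[cls])
  }
  structure(out, class = "variant_comparison")
}

#' Write the comparison as machine-readable tables
#'
#' Emits CSV files (dimensions summary, KDE curves, per-residue
#' secondary-structure profiles and differences, dense contact-map
#' matrices and their delta, salt-bridge and cation-pi tables with an NT
#' row where the N-terminal amine was detected, basin tables,
#' projections) plus `report.json` carrying the resolved configuration and
#' the summary numbers. Outputs are byte-stable across reruns on the same
#' input.
#'
#' @param comparison A [run_comparison()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(comparison, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("cannot write to ", out_dir)
  paths <- character()
  put <- function(df, name, row_names = FALSE) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = row_names)
    paths <<- c(paths, p)
  }
  vs <- comparison$variants
  dims <- do.call(rbind, lapply(names(vs), function(v) data.frame(
    variant = v,
    rg_mean = vs[[v]]$rg$mean, rg_error = vs[[v]]$rg$error,
    ree_mean = vs[[v]]$ree$mean, ree_error = vs[[v]]$ree$error,
    rs = vs[[v]]$rs$rs, rs_error = vs[[v]]$rs$error
  )))
  put(dims, "dimensions.csv")
  for (v in names(vs)) {
    put(data.frame(grid = vs[[v]]$kde_rg$grid,
                   density = vs[[v]]$kde_rg$density),
        sprintf("kde_rg_%s.csv", v))
    put(data.frame(grid = vs[[v]]$kde_ree$grid,
                   density = vs[[v]]$kde_ree$density),
        sprintf("kde_ree_%s.csv", v))
    if (!is.null(vs[[v]]$ss_profile))
      put(vs[[v]]$ss_profile$per_residue, sprintf("ss_profile_%s.csv", v))
    put(as.data.frame(vs[[v]]$contacts$probability),
        sprintf("contact_%s.csv", v))
    put(as.data.frame(vs[[v]]$salt_bridges),
        sprintf("salt_bridges_%s.csv", v))
    put(as.data.frame(vs[[v]]$cation_pi), sprintf("cation_pi_%s.csv", v))
    if (nrow(comparison$basins[[v]]$table))
      put(comparison$basins[[v]]$table, sprintf("basins_%s.csv", v))
    put(as.data.frame(comparison$landscapes[[v]]$projections),
        sprintf("projections_%s.csv", v))
  }
  put(as.data.frame(comparison$contact_delta), "contact_delta.csv")
  if (!is.null(comparison$ss_delta)) put(comparison$ss_delta, "ss_delta.csv")

  report <- list(
    config = unclass(comparison$config),
    variants = names(vs),
    dimensions = dims,
    interactions = list(
      salt_bridge_rows = vapply(vs, function(v) nrow(v$salt_bridges), 0L),
      cation_pi_rows = vapply(vs, function(v) nrow(v$cation_pi), 0L)
    ),
    landscape = list(
      explained_variance_pc12 =
        comparison$pca$explained_variance[1:2],
      basins = lapply(comparison$basins, function(b) b$table)
    )
  )
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, jp)
  invisible(paths)
}

#' Check a report against the shipped schema
#'
#' Lightweight structural validation: every key required by the schema
#' shipped at `inst/extdata/report-schema.json` must be present in the
#' report JSON.
#'
#' @param path Path to a `report.json` written by [render_tables()].
#' @return `TRUE` (invisibly) if valid; otherwise an error naming the
#'   missing keys.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "idpensemble"))
  rep <- jsonlite::read_json(path)
  missing <- setdiff(unlist(schema$required), names(rep))
  if (length(missing))
    stop("report is missing required keys: ", paste(missing, collapse = ", "))
  for (key in names(schema$properties)) {
    sub <- schema$properties[[key]]$required
    if (!is.null(sub)) {
      miss <- setdiff(unlist(sub), names(rep[[key]]))
      if (length(miss))
        stop("report['", key, "'] is missing: ", paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}
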