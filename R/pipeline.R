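# End-to-end orchestration: one complex -> descriptor panel -> class ->
# druggability comparison; a set of complexes -> panel table -> group
# statistics, PCA and k-means clustering.

#' Default pipeline configuration
#'
#' All tunable thresholds in one place, echoed into every report for
#' provenance.  Defaults follow the reference methodology where stated:
#' 1.4 A solvent probe, 3.2 A hydrogen-acceptor cutoff, 4.0 A salt-bridge
#' cutoff, 4.5 A ligand neighbourhood, k = 3 clusters.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(probe_radius = 1.4, n_sphere_points = 960L,
              atom_burial_threshold = 0.1,
              h_acceptor_cutoff = 3.2, min_donor_angle = 90,
              salt_bridge_cutoff = 4.0, max_gap = 4L,
              ligand_cutoff = 4.5,
              gap_grid_spacing = 1.0, gap_shell_cutoff = 5.0,
              pocket_grid_spacing = 0.9, pocket_energy_cutoff = -3.5,
              pocket_cluster_dist = 1.6, pocket_overlap_dist = 2.0,
              max_pockets = 10L, k = 3L, kmeans_restarts = 50L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config keys: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Profile one protein-protein complex
#'
#' Runs the full descriptor pipeline: delta-ASA interface definition,
#' geometry (planarity, eccentricity, gap volume/index), contacts (hydrogen
#' bonds, salt bridges, segments, secondary-structure classes), interface
#' pockets, class assignment and druggability comparison.  The unbound
#' receptor adds the CA rmsd; the ligand complex adds inhibitor coverage
#' (H_ASA), ligand-occupied pocket volume, and the descriptor block of the
#' 4.5 A ligand neighbourhood.  Stages that cannot run are reported as
#' explicit gaps, never silently dropped.
#'
#' @param pp A `ppi_structure` of the protein/protein complex.
#' @param selection A `partner_selection` (side A = target/receptor).
#' @param unbound Optional `ppi_structure` of the unbound receptor.
#' @param ligand_complex Optional `ppi_structure` of receptor + inhibitor
#'   (HETATM ligand named in `selection$ligand`).
#' @param config A [pipeline_config()].
#' @param compare Also compare the panel to the bundled reference set
#'   (default TRUE).
#' @return List of class `complex_report` with elements `panel`
#'   (descriptor list), `ppi_class`, `comparison`, `details`, `gaps`,
#'   `provenance`.
#' @export
profile_complex <- function(pp, selection, unbound = NULL,
                            ligand_complex = NULL,
                            config = pipeline_config(), compare = TRUE) {
  gaps <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  interface <- stage("interface", define_interface(
    pp, selection, atom_burial_threshold = config$atom_burial_threshold,
    probe = config$probe_radius, n_points = config$n_sphere_points))
  int_idx <- c(interface$interface_atoms_a, interface$interface_atoms_b)
  if (length(int_idx) < 3) stop("stage 'interface': interface too small")
  int_xyz <- coords(pp, int_idx)
  plan <- stage("geometry", planarity(int_xyz))
  ecc <- stage("geometry", eccentricity(int_xyz))
  gv <- stage("gap_volume", gap_volume(
    pp, selection, interface, grid_spacing = config$gap_grid_spacing,
    shell_cutoff = config$gap_shell_cutoff))
  hb <- stage("contacts", hydrogen_bonds(
    pp, interface, h_acceptor_cutoff = config$h_acceptor_cutoff,
    min_donor_angle = config$min_donor_angle))
  sb <- stage("contacts", salt_bridges(pp, interface,
                                       cutoff = config$salt_bridge_cutoff))
  seg <- stage("segments", count_interface_segments(
    pp, selection, interface, max_gap = config$max_gap))
  ssc <- stage("secondary_structure",
               ss_interface_class(pp, selection, interface))
  # pockets are detected on the free receptor surface (side A alone), then
  # filtered by inhibitor occupancy: the partner would otherwise fill them
  pock <- stage("pockets", find_pockets(
    subset_chains(pp, selection$side_a),
    grid_spacing = config$pocket_grid_spacing,
    energy_cutoff = config$pocket_energy_cutoff,
    cluster_dist = config$pocket_cluster_dist,
    max_pockets = config$max_pockets))
  rmsd_unbound <- NA_real_
  if (!is.null(unbound)) {
    rmsd_unbound <- stage("rmsd",
                          superpose_ca(unbound, pp,
                                       chains = selection$side_a)$rmsd)
  } else {
    gaps$rmsd_unbound <- "input absent: no unbound structure supplied"
  }
  h_asa <- NA_real_
  pocket_block <- list(count = NA_integer_, total_volume = NA_real_)
  subset_block <- NULL
  if (!is.null(ligand_complex)) {
    lig <- stage("ligand", extract_ligand(ligand_complex, selection))
    h_asa <- stage("ligand_coverage", ligand_coverage(
      ligand_complex, selection, interface, pp,
      probe = config$probe_radius, n_points = config$n_sphere_points))
    pocket_block <- stage("pockets", interface_pockets(
      pock, as.matrix(lig[, c("x", "y", "z")]),
      overlap_dist = config$pocket_overlap_dist))
    nb <- stage("ligand_neighborhood", ligand_neighborhood(
      ligand_complex, lig, cutoff = config$ligand_cutoff))
    subset_block <- list(n_atoms = length(nb$atom_idx),
                         n_residues = nrow(nb$residues))
  } else {
    gaps$h_asa_percent <- "input absent: no ligand complex supplied"
    gaps$pocket_volume <- "input absent: interface pockets need a ligand"
  }
  pct_charged <- stage("composition", pct_charged_interface(interface))
  panel <- list(
    asa_mean_side = interface$asa_mean_side,
    n_segments = seg$n_segments,
    gap_volume = gv$gap_volume,
    gap_index = gv$gap_index,
    planarity = plan,
    eccentricity = ecc,
    hb_per_100A2 = hb_density(nrow(hb), interface),
    salt_bridges = nrow(sb),
    pct_charged_residues = pct_charged,
    ss_class_pair = ssc$pair,
    pocket_volume = pocket_block$total_volume,
    n_interface_pockets = pocket_block$count,
    h_asa_percent = h_asa,
    rmsd_unbound = rmsd_unbound)
  comparison <- NULL
  if (compare) {
    q <- panel
    # pockets need a ligand; compare with 0 volume when absent is wrong, so
    # only compare when the full six-descriptor panel exists
    if (!is.na(q$pocket_volume)) {
      comparison <- compare_to_reference(q, seed = config$seed)
    } else {
      gaps$comparison <- "pocket volume unavailable: comparison skipped"
    }
  }
  structure(list(id = pp$id,
                 panel = panel,
                 ppi_class = assign_class(seg$n_segments),
                 comparison = comparison,
                 details = list(interface = interface, hydrogen_bonds = hb,
                                salt_bridges = sb, segments = seg,
                                ss = ssc, gap = gv,
                                ligand_subset = subset_block),
                 gaps = gaps,
                 provenance = config),
            class = "complex_report")
}

#' @export
print.complex_report <- function(x, ...) {
  cat(sprintf("complex report '%s' (class %s)\n", x$id, x$ppi_class))
  p <- x$panel
  cat(sprintf("  ASA %.0f A^2 | %d segments | GV %.0f A^3 (GVi %.2f)\n",
              p$asa_mean_side, p$n_segments, p$gap_volume, p$gap_index))
  cat(sprintf("  planarity %.2f A | eccentricity %.2f | Hb/100A^2 %.2f | %d salt bridges\n",
              p$planarity, p$eccentricity, p$hb_per_100A2, p$salt_bridges))
  cat(sprintf("  %.1f%% charged | SS %s | pocket vol %s | H_ASA %s | rmsd %s\n",
              p$pct_charged_residues, p$ss_class_pair,
              if (is.na(p$pocket_volume)) "-" else sprintf("%.0f", p$pocket_volume),
              if (is.na(p$h_asa_percent)) "-" else sprintf("%.0f%%", p$h_asa_percent),
              if (is.na(p$rmsd_unbound)) "-" else sprintf("%.2f", p$rmsd_unbound)))
  if (length(x$gaps) > 0) {
    cat("  gaps:", paste(names(x$gaps), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Profile a set of complexes and cluster their descriptor panels
#'
#' Profiles every entry of a manifest, assembles the panel table, and (with
#' at least three successful panels) standardises the six key descriptors,
#' runs PCA and k-means, and reports per-class group statistics.
#'
#' @param manifest List of entries, each a list with `pp`, `selection` and
#'   optional `unbound` / `ligand_complex` (a `toy_complex` works as-is).
#' @param config A [pipeline_config()].
#' @return List of class `dataset_report`: `panel` (data.frame), `reports`,
#'   `failures`, `pca`, `clustering`, `class_stats`.
#' @export
profile_dataset <- function(manifest, config = pipeline_config()) {
  reports <- list(); failures <- list()
  for (i in seq_along(manifest)) {
    m <- manifest[[i]]
    res <- tryCatch(
      profile_complex(m$pp, m$selection, unbound = m$unbound,
                      ligand_complex = m$ligand_complex, config = config,
                      compare = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(index = i, message = conditionMessage(res))
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  if (length(reports) == 0L) stop("no complex could be profiled")
  panel <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r$panel[c("asa_mean_side", "n_segments", "gap_volume",
                            "pocket_volume", "hb_per_100A2",
                            "pct_charged_residues", "gap_index",
                            "planarity", "eccentricity", "salt_bridges",
                            "h_asa_percent", "rmsd_unbound")])))
  panel$ppi_class <- vapply(reports, `[[`, character(1), "ppi_class")
  pca <- NULL; clustering <- NULL
  if (nrow(panel) >= 3L) {
    keys <- key_descriptors()
    X <- panel[, keys]
    # pocket volume needs a ligand; drop the column if any row lacks it
    if (anyNA(X$pocket_volume)) X$pocket_volume <- NULL
    usable <- vapply(X, function(col) stats::sd(col) > 0, logical(1))
    pca <- descriptor_pca(as.matrix(X[, usable, drop = FALSE]))
    # cluster on the two leading component scores (the 2D map used to
    # visualise and group the reference set)
    npc <- min(2L, ncol(pca$scores))
    clustering <- descriptor_kmeans(pca$scores[, seq_len(npc), drop = FALSE],
                                    k = min(config$k, nrow(panel)),
                                    restarts = config$kmeans_restarts,
                                    seed = config$seed)
  }
  class_stats <- NULL
  if (all(c("I", "II") %in% panel$ppi_class)) {
    num_cols <- names(panel)[vapply(panel, is.numeric, logical(1))]
    class_stats <- lapply(stats::setNames(num_cols, num_cols), function(d) {
      tryCatch(list(classI = aggregate_descriptor(panel, d, "classI"),
                    classII = aggregate_descriptor(panel, d, "classII")),
               error = function(e) NULL)
    })
  }
  structure(list(panel = panel, reports = reports, failures = failures,
                 pca = pca, clustering = clustering,
                 class_stats = class_stats, config = config),
            class = "dataset_report")
}

#' Serialise a report to JSON
#'
#' @param report A `complex_report` or `dataset_report`.
#' @param file Optional path; when NULL the JSON string is returned.
#' @return JSON text (invisibly when written to file).
#' @export
report_json <- function(report, file = NULL) {
  x <- if (inherits(report, "complex_report")) {
    list(id = report$id, panel = report$panel, ppi_class = report$ppi_class,
         gaps = report$gaps, provenance = report$provenance)
  } else {
    list(panel = report$panel,
         clustering = if (!is.null(report$clustering))
           list(labels = report$clustering$labels,
                seed = report$clustering$seed),
         explained_variance = if (!is.null(report$pca))
           report$pca$explained_variance,
         provenance = report$config)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    invisible(js)
  } else js
}
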