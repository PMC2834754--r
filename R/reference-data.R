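#' Load the bundled reference panel of druggable protein-protein interfaces
#'
#' The package ships a curated table of 17 protein/protein complexes (14
#' families) with known small-molecule interface inhibitors, together with
#' their interface descriptor panel: planarity, eccentricity,
#' secondary-structure pair, gap volume and gap-volume index, hydrogen bonds
#' per 100 A^2, salt bridges, one-side-equivalent buried ASA, percentage of
#' the interface hidden by the inhibitor, CA rmsd between unbound and
#' complexed forms, interface pocket volume and number of interface segments.
#'
#' Complexes are split into class I (protein/peptide-like, fewer than six
#' interface segments) and class II (globular/globular, more segments).
#' Missing affinities are `NA`, never zero; inhibition constants are flagged
#' `affinity_kind = "Ki"`.
#'
#' @param file Optional path to an alternative reference CSV with the same
#'   columns; defaults to the bundled table.
#' @return A data.frame of class `ppi_reference` with one row per complex.
#' @export
#' @examples
#' ref <- load_reference()
#' nrow(ref)                     # 17 complexes
#' length(unique(ref$family_id)) # 14 families
load_reference <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "ppi_reference_panel.csv",
                        package = "ppiprofiler")
  }
  if (!nzchar(file) || !file.exists(file)) {
    stop("bundled reference panel not found: package installation is corrupt")
  }
  ref <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("family_id", "family_name", "ppi_class", "pdb_pp_complex",
                "n_inhibitors", "affinity_nM", "affinity_kind",
                "planarity", "eccentricity", "ss_class_pair", "gap_volume",
                "gap_index", "hb_per_100A2", "salt_bridges", "asa_mean_side",
                "h_asa_percent", "rmsd_unbound", "pocket_volume", "n_segments")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols) > 0) {
    stop("reference panel is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(ref) != 17L) {
    stop("reference panel must contain exactly 17 complexes, found ", nrow(ref))
  }
  if (!all(ref$ppi_class %in% c("I", "II"))) {
    stop("ppi_class must be 'I' or 'II'")
  }
  # class rule: class I iff fewer than six interface segments
  stopifnot(all((ref$ppi_class == "I") == (ref$n_segments < 6)))
  class(ref) <- c("ppi_reference", "data.frame")
  ref
}

#' Number of inhibitors in the reference set
#'
#' Inhibitor counts are recorded per complex family (several PDB entries can
#' share a family), so the dataset total sums each family once.
#'
#' @param ref A reference panel from [load_reference()].
#' @return Integer total number of bundled inhibitors.
#' @export
n_reference_inhibitors <- function(ref) {
  per_family <- ref$n_inhibitors[!duplicated(ref$family_id)]
  sum(per_family)
}

#' Numeric descriptor columns of the reference panel
#' @keywords internal
reference_descriptor_names <- function() {
  c("planarity", "eccentricity", "gap_volume", "gap_index", "hb_per_100A2",
    "salt_bridges", "asa_mean_side", "h_asa_percent", "rmsd_unbound",
    "pocket_volume", "n_segments")
}

#' Group statistics (mean, variance, n) for a reference descriptor
#'
#' Computes the unweighted arithmetic mean and the sample variance
#' (n - 1 denominator) of one descriptor over the whole panel or one
#' interface class.  These triples feed [t_value()].
#'
#' @param dataset A reference panel (or any data.frame with a `ppi_class`
#'   column and the descriptor column).
#' @param descriptor Name of a numeric descriptor column.
#' @param subset One of `"all"`, `"classI"`, `"classII"`.
#' @return A `group_stats` list with elements `mean`, `variance`, `sd`, `n`.
#' @export
#' @examples
#' ref <- load_reference()
#' aggregate_descriptor(ref, "asa_mean_side", "classI")  # mean 532, sd 198
aggregate_descriptor <- function(dataset, descriptor,
                                 subset = c("all", "classI", "classII")) {
  subset <- match.arg(subset)
  if (!descriptor %in% names(dataset)) {
    stop("unknown descriptor: ", descriptor)
  }
  x <- switch(subset,
              all     = dataset[[descriptor]],
              classI  = dataset[[descriptor]][dataset$ppi_class == "I"],
              classII = dataset[[descriptor]][dataset$ppi_class == "II"])
  if (!is.numeric(x)) stop("descriptor is not numeric: ", descriptor)
  if (anyNA(x)) stop("descriptor has missing values in subset: ", descriptor)
  if (length(x) < 2L) {
    stop("insufficient group size (n = ", length(x),
         ") for variance of ", descriptor)
  }
  group_stats(mean(x), stats::var(x), length(x))
}

#' Construct a group-statistics triple
#'
#' @param mean Group mean.
#' @param variance Sample variance (n - 1 denominator); must be >= 0.
#' @param n Group size (>= 2 for the variance to be defined).
#' @return A list of class `group_stats`.
#' @export
group_stats <- function(mean, variance, n) {
  stopifnot(is.finite(mean), is.finite(variance), variance >= 0, n >= 2)
  structure(list(mean = mean, variance = variance,
                 sd = sqrt(variance), n = as.integer(n)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group stats: mean %.4g, sd %.4g (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Check a measured descriptor panel against a reference row
#'
#' Extended-validation comparator: flags whether a measured panel agrees with
#' a reference complex within stated tolerances (relative for ASA, absolute
#' for planarity, eccentricity and segment count).
#'
#' @param measured Named list/vector with at least `asa_mean_side`,
#'   `planarity`, `eccentricity`, `n_segments`.
#' @param reference_row One row of the reference panel.
#' @param tol_asa_rel Relative ASA tolerance (default 0.15).
#' @param tol_planarity Absolute planarity tolerance in Angstrom (default 0.3).
#' @param tol_eccentricity Absolute eccentricity tolerance (default 0.10).
#' @param tol_segments Absolute segment-count tolerance (default 1).
#' @return Named logical vector, one flag per compared descriptor.
#' @export
check_against_reference <- function(measured, reference_row,
                                    tol_asa_rel = 0.15,
                                    tol_planarity = 0.3,
                                    tol_eccentricity = 0.10,
                                    tol_segments = 1) {
  m <- as.list(measured)
  r <- as.list(reference_row)
  c(asa_mean_side =
      abs(m$asa_mean_side - r$asa_mean_side) <= tol_asa_rel * r$asa_mean_side,
    planarity    = abs(m$planarity - r$planarity) <= tol_planarity,
    eccentricity = abs(m$eccentricity - r$eccentricity) <= tol_eccentricity,
    n_segments   = abs(m$n_segments - r$n_segments) <= tol_segments)
}
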