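# Druggability comparison: a query interface's six key descriptors against
# the reference distribution of interfaces with known inhibitors.

#' Assemble the six-key-descriptor matrix of the reference panel
#'
#' Five of the six descriptors come straight from the bundled table; the
#' percentage of charged interface residues is not tabulated per complex,
#' so it is drawn per complex from a truncated Gaussian with the published
#' overall moments (18.9 +/- 13.8 \%, clipped to [0, 100]), seeded for
#' reproducibility.
#'
#' @param ref Reference panel from [load_reference()].
#' @param seed Seed for the simulated charged-residue column.
#' @param pct_charged_mean,pct_charged_sd Moments of the simulated column.
#' @return Numeric matrix, 17 x 6, columns [key_descriptors()].
#' @export
reference_key_matrix <- function(ref, seed = 1L,
                                 pct_charged_mean = 18.9,
                                 pct_charged_sd = 13.8) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  pct <- pmin(100, pmax(0, stats::rnorm(nrow(ref), pct_charged_mean,
                                        pct_charged_sd)))
  X <- cbind(asa_mean_side = ref$asa_mean_side,
             n_segments = ref$n_segments,
             gap_volume = ref$gap_volume,
             pocket_volume = ref$pocket_volume,
             hb_per_100A2 = ref$hb_per_100A2,
             pct_charged_residues = pct)
  rownames(X) <- ref$pdb_pp_complex
  X
}

#' Compare a query interface to the reference distribution
#'
#' Each of the six key descriptors is scored by its standardised distance
#' to the reference mean, `z = |x - mean| / sd`; descriptors with z <= 0.5
#' are "very close", z <= 1 "close", else "far".  The overall score is the
#' mean z-distance: lower values indicate interfaces resembling those with
#' known inhibitors, i.e. higher druggability potential.  An affinity
#' indication is derived from which class centroid (in standardised space)
#' the query is nearer: class I interfaces bind weakly (micromolar), class
#' II strongly (nano/sub-nanomolar).
#'
#' @param query Named list/vector with the six [key_descriptors()].
#' @param reference Reference panel from [load_reference()].
#' @param seed Seed for the simulated charged-residue reference column.
#' @param thresholds Proximity thresholds `c(very_close, close)` in sd
#'   units (default 0.5, 1.0).
#' @return List of class `comparison_report`: per-descriptor `z` and
#'   `proximity`, `n_close_or_very_close`, `overall_score`,
#'   `affinity_indication`.
#' @export
compare_to_reference <- function(query, reference = load_reference(),
                                 seed = 1L, thresholds = c(0.5, 1.0)) {
  keys <- key_descriptors()
  query <- as.list(query)
  q <- vapply(keys, function(k) {
    v <- suppressWarnings(as.numeric(query[[k]]))
    if (length(v) != 1L) NA_real_ else v
  }, numeric(1))
  if (anyNA(q)) {
    stop("query is missing descriptor(s): ",
         paste(keys[is.na(q)], collapse = ", "))
  }
  X <- reference_key_matrix(reference, seed = seed)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("reference sd is zero for: ",
         paste(keys[sdv == 0], collapse = ", "))
  }
  z <- abs(q - mu) / sdv
  proximity <- ifelse(z <= thresholds[1], "very_close",
                      ifelse(z <= thresholds[2], "close", "far"))
  # class centroids in standardised space
  Zref <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  zq <- (q - mu) / sdv
  cI <- colMeans(Zref[reference$ppi_class == "I", , drop = FALSE])
  cII <- colMeans(Zref[reference$ppi_class == "II", , drop = FALSE])
  dI <- sqrt(sum((zq - cI)^2)); dII <- sqrt(sum((zq - cII)^2))
  affinity <- if (abs(dI - dII) < 1e-9) "indeterminate"
              else if (dI < dII) "weak_like" else "strong_like"
  structure(list(z = z, proximity = proximity,
                 n_close_or_very_close = sum(proximity != "far"),
                 overall_score = mean(z),
                 affinity_indication = affinity,
                 thresholds = thresholds),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("druggability comparison to the reference interface set\n")
  for (k in names(x$z)) {
    cat(sprintf("  %-22s z = %5.2f  (%s)\n", k, x$z[[k]], x$proximity[[k]]))
  }
  cat(sprintf("  close or very close: %d / 6\n", x$n_close_or_very_close))
  cat(sprintf("  overall score: %.3f (lower = more reference-like)\n",
              x$overall_score))
  cat(sprintf("  affinity indication: %s\n", x$affinity_indication))
  invisible(x)
}
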