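# Probe-energy pocket detection: a united-atom methyl probe is evaluated on
# a regular grid over the protein surface; grid points with a favourable
# Lennard-Jones interaction energy are clustered into pockets.  This
# re-implements the energy-based binding-site mapping approach behind the
# pocket-volume descriptor; energy constants are configuration values, not
# claims of bit-compatibility with any server.

# per-element Lennard-Jones parameters (sigma in A, epsilon in kcal/mol)
LJ_PARAMS <- list(
  C = c(3.40, 0.086), N = c(3.25, 0.170), O = c(2.96, 0.210),
  S = c(3.56, 0.250), P = c(3.74, 0.200), H = c(2.50, 0.030))
LJ_DEFAULT <- c(3.40, 0.100)

PROBE_SIGMA <- 3.6
PROBE_EPS <- 0.16

#' Probe-energy pockets of a structure
#'
#' Evaluates a methyl-like probe on a grid spanning the structure's surface
#' shell.  The probe-atom interaction is a 12-6 Lennard-Jones potential with
#' Lorentz-Berthelot combination, summed over heavy atoms within 8 A.
#' Probes at or below `energy_cutoff` are kept and single-linkage clustered;
#' clusters are ranked by ascending total energy (most favourable first).
#'
#' @param structure A `ppi_structure`.
#' @param grid_spacing Grid cell edge in Angstrom (default 0.9).
#' @param energy_cutoff Keep probes with energy <= cutoff kcal/mol
#'   (default -3.5, below the reach of convex/flat model surfaces with the
#'   bundled probe parameters, so only enclosed cavities qualify).
#' @param cluster_dist Single-linkage distance in Angstrom (default 1.6).
#' @param max_pockets Return at most this many top-ranked pockets
#'   (default 10).
#' @return List of `pocket` objects, each with `probe_points` (m x 3),
#'   `energies`, `total_energy` (kcal/mol), `volume` (A^3 =
#'   points x spacing^3) and `rank`.
#' @export
find_pockets <- function(structure, grid_spacing = 0.9,
                         energy_cutoff = -3.5, cluster_dist = 1.6,
                         max_pockets = 10L) {
  a <- structure$atoms
  heavy <- a$element != "H"
  A <- as.matrix(a[heavy, c("x", "y", "z")])
  el <- toupper(a$element[heavy])
  lj <- t(vapply(el, function(e)
    if (!is.null(LJ_PARAMS[[e]])) LJ_PARAMS[[e]] else LJ_DEFAULT,
    numeric(2)))
  sig <- (lj[, 1] + PROBE_SIGMA) / 2
  eps <- sqrt(lj[, 2] * PROBE_EPS)
  box_min <- apply(A, 2, min) - 4
  box_max <- apply(A, 2, max) + 4
  gx <- seq(box_min[1], box_max[1], by = grid_spacing)
  gy <- seq(box_min[2], box_max[2], by = grid_spacing)
  gz <- seq(box_min[3], box_max[3], by = grid_spacing)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keepE <- numeric(0)
  keepG <- matrix(0, 0, 3)
  step <- 15000L
  for (s in seq(1, nrow(G), by = step)) {
    ii <- s:min(s + step - 1L, nrow(G))
    g <- G[ii, , drop = FALSE]
    d2 <- cross_dist2(g, A)
    d2[d2 < 1e-6] <- 1e-6
    E <- numeric(nrow(g))
    within <- d2 <= 64  # 8 A interaction cutoff
    sr2 <- sweep(1 / d2, 2, sig^2, "*")  # (sigma/r)^2
    sr6 <- sr2^3
    contrib <- sweep(4 * (sr6^2 - sr6), 2, eps, "*")
    contrib[!within] <- 0
    E <- rowSums(contrib)
    sel <- E <= energy_cutoff
    if (any(sel)) {
      keepE <- c(keepE, E[sel])
      keepG <- rbind(keepG, g[sel, , drop = FALSE])
    }
  }
  if (length(keepE) == 0L) return(list())
  # single-linkage clustering on the grid: with cluster_dist >= spacing*sqrt3
  # this is connected components over the 26-neighbourhood
  comp <- grid_components(keepG, grid_spacing, cluster_dist)
  pockets <- lapply(split(seq_along(keepE), comp), function(idx) {
    list(probe_points = keepG[idx, , drop = FALSE],
         energies = keepE[idx],
         total_energy = sum(keepE[idx]),
         volume = length(idx) * grid_spacing^3)
  })
  ord <- order(vapply(pockets, `[[`, numeric(1), "total_energy"))
  pockets <- pockets[ord]
  pockets <- pockets[seq_len(min(length(pockets), max_pockets))]
  for (i in seq_along(pockets)) {
    pockets[[i]]$rank <- i
    class(pockets[[i]]) <- "pocket"
  }
  pockets
}

# connected components of grid points under a linkage distance
grid_components <- function(G, spacing, cluster_dist) {
  n <- nrow(G)
  key <- round(sweep(G, 2, apply(G, 2, min)) / spacing)
  span <- apply(key, 2, max) + 2
  id <- key[, 1] + span[1] * (key[, 2] + span[2] * key[, 3])
  lut <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(id[i]), i, envir = lut)
  reach <- ceiling(cluster_dist / spacing)
  offs <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                                dz = -reach:reach))
  offs <- offs[rowSums(offs^2) > 0 &
               sqrt(rowSums((offs * spacing)^2)) <= cluster_dist + 1e-9, ,
               drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (o in seq_len(nrow(offs))) {
      nb_id <- (key[i, 1] + offs[o, 1]) +
        span[1] * ((key[i, 2] + offs[o, 2]) +
                   span[2] * (key[i, 3] + offs[o, 3]))
      j <- get0(as.character(nb_id), envir = lut, inherits = FALSE)
      if (!is.null(j) && j > i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Interface pockets: those at least partly occupied by the inhibitor
#'
#' Retains the pockets with at least one probe point within `overlap_dist`
#' of any (superposed) ligand atom, operationalising "at least partly
#' occupied by the inhibitor", and reports their count and summed volume.
#'
#' @param pockets List of pockets from [find_pockets()].
#' @param ligand_xyz m x 3 ligand atom coordinates in the pocket
#'   structure's frame (superpose first if the ligand comes from a
#'   different crystal form).
#' @param overlap_dist Overlap distance in Angstrom (default 2.0).
#' @return List: `count`, `total_volume` (A^3), `kept` (indices into
#'   `pockets`).
#' @export
interface_pockets <- function(pockets, ligand_xyz, overlap_dist = 2.0) {
  if (is.null(ligand_xyz) || nrow(as.matrix(ligand_xyz)) == 0L) {
    stop("ligand coordinates required to select occupied pockets")
  }
  L <- as.matrix(ligand_xyz)
  kept <- which(vapply(pockets, function(p) {
    d2 <- cross_dist2(p$probe_points, L)
    min(d2) <= overlap_dist^2
  }, logical(1)))
  list(count = length(kept),
       total_volume = sum(vapply(pockets[kept], `[[`, numeric(1), "volume")),
       kept = kept)
}

#' Write pocket probe points as PDB pseudo-atoms for inspection
#'
#' @param pockets List of pockets.
#' @param file Output path.
#' @return Invisibly the lines written.
#' @export
write_pockets_pdb <- function(pockets, file) {
  lines <- character(0)
  serial <- 0L
  for (p in pockets) {
    for (i in seq_len(nrow(p$probe_points))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C   PKT %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, "P", p$rank, p$probe_points[i, 1], p$probe_points[i, 2],
        p$probe_points[i, 3], 1, 0, "C"))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(lines)
}
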