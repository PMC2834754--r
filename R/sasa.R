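# Solvent-accessible surface area (Shrake-Rupley) and the delta-ASA
# definition of the protein-protein interface.  Heavy atoms only; a water
# probe of 1.4 A; areas in A^2.

#' Bondi van der Waals radii used for surface and volume calculations
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CU = 1.40, "NA" = 2.27,
    CA = 2.31, SE = 1.90, CO = 2.00, NI = 1.63, CD = 1.58, MO = 2.00)
}

# deterministic quasi-uniform sphere points (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over the heavy atoms using a fixed deterministic
#' Fibonacci point lattice: each atom's accessible area is the fraction of
#' lattice points on its probe-expanded sphere lying outside every other
#' atom's probe-expanded sphere, times 4*pi*(r + probe)^2.  Hydrogens are
#' excluded, matching the heavy-atom convention of standard surface tools.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param element Element symbol per atom.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Lattice points per atom (default 960).
#' @return List of class `sasa_result`: `per_atom` (A^2, 0 for hydrogens),
#'   `total`, `probe_radius`, `n_sphere_points`, `radii_set_name`.
#' @export
shrake_rupley <- function(xyz, element, probe = 1.4, n_points = 960L) {
  stopifnot(nrow(xyz) == length(element))
  radii <- vdw_radii()
  el <- toupper(element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  heavy <- el != "H"
  if (!any(heavy)) stop("no heavy atoms")
  hxyz <- xyz[heavy, , drop = FALSE]
  r <- radii[el[heavy]] + probe
  n <- nrow(hxyz)
  pts <- sphere_points(n_points)
  per_atom_h <- numeric(n)
  # neighbour search via cell lists would be overkill at pipeline scale;
  # a radius query against all atoms per atom is fast enough in R
  max_r <- max(r)
  for (i in seq_len(n)) {
    d2 <- colSums((t(hxyz) - hxyz[i, ])^2)
    nb <- which(d2 < (r[i] + max_r)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (length(nb) == 0L) {
      per_atom_h[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, hxyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[, 1] - hxyz[j, 1])^2 + (p[, 2] - hxyz[j, 2])^2 +
        (p[, 3] - hxyz[j, 3])^2
      exposed <- exposed & dj2 > r[j]^2
    }
    per_atom_h[i] <- sum(exposed) / n_points * 4 * pi * r[i]^2
  }
  per_atom <- numeric(length(el))
  per_atom[heavy] <- per_atom_h
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_sphere_points = as.integer(n_points),
                 radii_set_name = "bondi"),
            class = "sasa_result")
}

#' SASA of a structure (or atom subset)
#'
#' @param structure A `ppi_structure`.
#' @param idx Optional atom row indices.
#' @inheritParams shrake_rupley
#' @return A `sasa_result`.
#' @export
structure_sasa <- function(structure, idx = NULL, probe = 1.4,
                           n_points = 960L) {
  a <- structure$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  shrake_rupley(as.matrix(a[, c("x", "y", "z")]), a$element,
                probe = probe, n_points = n_points)
}

#' Define the interface of a two-sided complex by buried surface area
#'
#' The interface size is the difference in accessible surface area between
#' each partner alone and in the complex.  Atoms losing more than
#' `atom_burial_threshold` A^2 are interface atoms; residues with at least
#' one such atom are interface residues.  The headline `asa_mean_side`
#' descriptor is the mean of the two sides' delta-ASA.
#'
#' @param complex A `ppi_structure` holding both partners.
#' @param selection A `partner_selection`.
#' @param atom_burial_threshold Per-atom burial cutoff in A^2 (default 0.1).
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return List of class `interface_definition`: `delta_asa_side_a/b`,
#'   `asa_mean_side`, per-side interface atom indices (rows of the complex
#'   atom table), per-side interface residue tables, per-atom delta-ASA.
#' @export
define_interface <- function(complex, selection, atom_burial_threshold = 0.1,
                             probe = 1.4, n_points = 960L) {
  ia <- side_indices(complex, selection, "a")
  ib <- side_indices(complex, selection, "b")
  if (length(ia) == 0L) stop("side A is empty")
  if (length(ib) == 0L) stop("side B is empty")
  both <- c(ia, ib)
  s_ab <- structure_sasa(complex, both, probe, n_points)
  s_a <- structure_sasa(complex, ia, probe, n_points)
  s_b <- structure_sasa(complex, ib, probe, n_points)
  n_a <- length(ia)
  dasa_a <- s_a$per_atom - s_ab$per_atom[seq_len(n_a)]
  dasa_b <- s_b$per_atom - s_ab$per_atom[n_a + seq_along(ib)]
  # numerically the lattice can give tiny negative burials; clip at zero
  dasa_a <- pmax(dasa_a, 0)
  dasa_b <- pmax(dasa_b, 0)
  int_a <- ia[dasa_a > atom_burial_threshold]
  int_b <- ib[dasa_b > atom_burial_threshold]
  res_of <- function(idx) {
    a <- complex$atoms[idx, , drop = FALSE]
    unique(a[, c("chain", "resno", "insert", "resname")])
  }
  structure(list(
    delta_asa_side_a = sum(dasa_a),
    delta_asa_side_b = sum(dasa_b),
    asa_mean_side = (sum(dasa_a) + sum(dasa_b)) / 2,
    interface_atoms_a = int_a,
    interface_atoms_b = int_b,
    interface_residues_a = res_of(int_a),
    interface_residues_b = res_of(int_b),
    delta_per_atom_a = stats::setNames(dasa_a, ia),
    delta_per_atom_b = stats::setNames(dasa_b, ib),
    atom_burial_threshold = atom_burial_threshold),
    class = "interface_definition")
}

#' @export
print.interface_definition <- function(x, ...) {
  cat(sprintf(
    "interface: dASA A %.1f, B %.1f (mean side %.1f A^2); %d + %d atoms\n",
    x$delta_asa_side_a, x$delta_asa_side_b, x$asa_mean_side,
    length(x$interface_atoms_a), length(x$interface_atoms_b)))
  invisible(x)
}

#' Fraction of the protein-protein interface hidden by an inhibitor
#'
#' Computes, on the target side of the interface, the ASA those interface
#' atoms lose to the bound small molecule, as a percentage of the ASA the
#' same atoms lose to the protein partner.  Atoms are matched between the
#' two structures by (chain, residue number, insertion code, atom name).
#' Values above 100 (the ligand buries slightly more than the partner did)
#' are reported as 100.
#'
#' @param target_with_ligand A `ppi_structure` of the target protein bound
#'   to the inhibitor.
#' @param selection A `partner_selection` whose `side_a` chains are the
#'   target and whose `ligand` identifies the inhibitor.
#' @param pp_interface The `interface_definition` of the protein-protein
#'   complex, with side A the target.
#' @param pp_complex The protein-protein `ppi_structure` the interface was
#'   defined on (for atom identity).
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return Percentage in [0, 100].
#' @export
ligand_coverage <- function(target_with_ligand, selection, pp_interface,
                            pp_complex, probe = 1.4, n_points = 960L) {
  lig <- extract_ligand(target_with_ligand, selection)
  tgt_idx <- which(target_with_ligand$atoms$chain %in% selection$side_a &
                   !target_with_ligand$atoms$het)
  if (length(tgt_idx) == 0L) stop("target side is empty")
  # map the pp-interface atoms of side A onto the ligand-complex target
  key <- function(a) paste(a$chain, a$resno, a$insert, a$name, sep = "|")
  pp_a <- pp_complex$atoms[pp_interface$interface_atoms_a, , drop = FALSE]
  tgt <- target_with_ligand$atoms[tgt_idx, , drop = FALSE]
  m <- match(key(pp_a), key(tgt))
  if (anyNA(m)) {
    miss <- unique(paste(pp_a$chain[is.na(m)], pp_a$resno[is.na(m)]))
    stop("interface residues not mappable onto ligand complex: ",
         paste(miss, collapse = ", "))
  }
  # delta-ASA of the mapped target atoms caused by the ligand
  lig_rows <- as.integer(rownames(lig))
  a_l <- target_with_ligand$atoms[c(tgt_idx, lig_rows), , drop = FALSE]
  s_with <- shrake_rupley(as.matrix(a_l[, c("x", "y", "z")]), a_l$element,
                          probe, n_points)
  s_alone <- shrake_rupley(as.matrix(tgt[, c("x", "y", "z")]), tgt$element,
                           probe, n_points)
  d_lig <- pmax(s_alone$per_atom - s_with$per_atom[seq_along(tgt_idx)], 0)
  num <- sum(d_lig[m])
  den <- sum(pp_interface$delta_per_atom_a[
    as.character(pp_interface$interface_atoms_a)])
  if (den <= 0) stop("protein-protein interface has zero buried area")
  min(100, 100 * num / den)
}

#' Protein atoms and residues within a cutoff of a ligand
#'
#' The 4.5-Angstrom neighbourhood of the inhibitor defines the subset of the
#' interface in direct contact with the ligand, on which the descriptor
#' panel can be recomputed.
#'
#' @param complex A `ppi_structure`.
#' @param ligand_atoms Atom table rows of the ligand (see [extract_ligand()]).
#' @param cutoff Inclusion distance in Angstrom (default 4.5, closed
#'   interval: an atom exactly at the cutoff is included).
#' @return List with `atom_idx` (rows of the complex atom table) and
#'   `residues` (residue table of residues with >= 1 such atom).
#' @export
ligand_neighborhood <- function(complex, ligand_atoms, cutoff = 4.5) {
  if (nrow(ligand_atoms) == 0L) stop("empty ligand")
  a <- complex$atoms
  prot <- which(!a$het)
  if (length(prot) == 0L) {
    return(list(atom_idx = integer(0),
                residues = a[integer(0), c("chain", "resno", "insert",
                                           "resname")]))
  }
  P <- as.matrix(a[prot, c("x", "y", "z")])
  L <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  keep <- logical(length(prot))
  for (i in seq_len(nrow(L))) {
    d2 <- (P[, 1] - L[i, 1])^2 + (P[, 2] - L[i, 2])^2 + (P[, 3] - L[i, 3])^2
    keep <- keep | d2 <= cutoff^2
  }
  idx <- prot[keep]
  res <- unique(a[idx, c("chain", "resno", "insert", "resname")])
  list(atom_idx = idx, residues = res)
}
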