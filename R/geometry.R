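# Shape descriptors of the interface atom cloud and least-squares
# superposition.  All operations are invariant under rigid motion of the
# input (tested as a property).

#' Least-squares plane through a set of atoms
#'
#' Principal-component decomposition of the centred coordinates: the plane
#' is spanned by the two largest-eigenvalue axes, the normal is the
#' smallest-eigenvalue axis.
#'
#' @param xyz n x 3 coordinate matrix; at least 3 non-collinear points.
#' @return List of class `interface_plane`: `centroid`, `axes` (3 x 3,
#'   columns = major in-plane, minor in-plane, normal), `eigenvalues`
#'   (descending, A^2).
#' @export
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms to fit a plane")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], 1e-12)) {
    stop("atoms are collinear: plane is undefined")
  }
  structure(list(centroid = ctr, axes = e$vectors,
                 eigenvalues = pmax(e$values, 0)),
            class = "interface_plane")
}

#' Planarity of an interface
#'
#' Root-mean-square perpendicular distance of the atoms to their
#' least-squares plane, in Angstrom.  Flat interfaces give small values;
#' the reference druggable interfaces average 2.8 A.
#'
#' @inheritParams fit_plane
#' @return RMS deviation in Angstrom.
#' @export
planarity <- function(xyz) {
  pl <- fit_plane(xyz)
  X <- sweep(as.matrix(xyz), 2, pl$centroid)
  d <- X %*% pl$axes[, 3]
  sqrt(mean(d^2))
}

#' Eccentricity of an interface
#'
#' Ratio of the in-plane principal axis lengths of the interface atom
#' cloud, `sqrt(lambda_minor / lambda_major)`: 1 for a circular footprint,
#' approaching 0 for an elongated one.
#'
#' @inheritParams fit_plane
#' @return Ratio in [0, 1].
#' @export
eccentricity <- function(xyz) {
  pl <- fit_plane(xyz)
  if (pl$eigenvalues[1] <= 0) stop("degenerate interface: zero major axis")
  sqrt(pl$eigenvalues[2] / pl$eigenvalues[1])
}

#' Gap volume between the two partners of a complex
#'
#' Grid estimator of the empty volume enclosed between the partners'
#' van der Waals surfaces: grid cells whose centre lies outside every
#' atom's vdW sphere but within `shell_cutoff` of at least one heavy atom
#' of EACH partner are counted as gap.  The gap-volume index (GVi) divides
#' by the total two-side interface delta-ASA, giving a tightness measure in
#' Angstrom.
#'
#' @param complex A `ppi_structure`.
#' @param selection A `partner_selection`.
#' @param interface Optional precomputed `interface_definition` (computed if
#'   missing; needed for the GVi denominator).
#' @param grid_spacing Grid cell edge in Angstrom (default 1.0).
#' @param shell_cutoff Max distance to each partner in Angstrom (default 5.0).
#' @return List of class `gap_volume_result`: `gap_volume` (A^3),
#'   `gap_index` (A), `n_cells`, `grid_spacing`, `shell_cutoff`.
#' @export
gap_volume <- function(complex, selection, interface = NULL,
                       grid_spacing = 1.0, shell_cutoff = 5.0) {
  if (is.null(interface)) interface <- define_interface(complex, selection)
  total_dasa <- interface$delta_asa_side_a + interface$delta_asa_side_b
  if (total_dasa <= 0) stop("zero interface: gap index undefined")
  ia <- side_indices(complex, selection, "a", heavy_only = TRUE)
  ib <- side_indices(complex, selection, "b", heavy_only = TRUE)
  A <- coords(complex, ia); B <- coords(complex, ib)
  radii <- vdw_radii()
  rA <- radii[toupper(complex$atoms$element[ia])]
  rB <- radii[toupper(complex$atoms$element[ib])]
  # restrict each side to atoms near the other side to bound the grid
  nearA <- cross_within(A, B, shell_cutoff + max(rA))
  nearB <- cross_within(B, A, shell_cutoff + max(rB))
  if (!any(nearA) || !any(nearB)) {
    return(structure(list(gap_volume = 0, gap_index = 0, n_cells = 0L,
                          grid_spacing = grid_spacing,
                          shell_cutoff = shell_cutoff),
                     class = "gap_volume_result"))
  }
  box <- rbind(pmin(apply(A[nearA, , drop = FALSE], 2, min),
                    apply(B[nearB, , drop = FALSE], 2, min)) - grid_spacing,
               pmax(apply(A[nearA, , drop = FALSE], 2, max),
                    apply(B[nearB, , drop = FALSE], 2, max)) + grid_spacing)
  gx <- seq(box[1, 1], box[2, 1], by = grid_spacing)
  gy <- seq(box[1, 2], box[2, 2], by = grid_spacing)
  gz <- seq(box[1, 3], box[2, 3], by = grid_spacing)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- logical(nrow(G))
  step <- 20000L
  for (s in seq(1, nrow(G), by = step)) {
    ii <- s:min(s + step - 1L, nrow(G))
    g <- G[ii, , drop = FALSE]
    dA2 <- cross_dist2(g, A)
    dB2 <- cross_dist2(g, B)
    outside <- apply(sweep(dA2, 2, rA^2, ">"), 1, all) &
      apply(sweep(dB2, 2, rB^2, ">"), 1, all)
    near_both <- apply(dA2, 1, min) <= shell_cutoff^2 &
      apply(dB2, 1, min) <= shell_cutoff^2
    keep[ii] <- outside & near_both
  }
  gv <- sum(keep) * grid_spacing^3
  structure(list(gap_volume = gv, gap_index = gv / total_dasa,
                 n_cells = sum(keep), grid_spacing = grid_spacing,
                 shell_cutoff = shell_cutoff),
            class = "gap_volume_result")
}

# squared distances between rows of X (m x 3) and rows of Y (n x 3)
cross_dist2 <- function(X, Y) {
  outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
}

# which rows of X lie within d of any row of Y
cross_within <- function(X, Y, d) {
  keep <- logical(nrow(X))
  step <- 5000L
  for (s in seq(1, nrow(X), by = step)) {
    ii <- s:min(s + step - 1L, nrow(X))
    d2 <- cross_dist2(X[ii, , drop = FALSE], Y)
    keep[ii] <- apply(d2, 1, min) <= d^2
  }
  keep
}

#' Optimal least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinates, via singular value decomposition with the
#' determinant sign correction.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates (same order).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_pairs`.  The fitted mobile set is
#'   `mobile %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("coordinate sets must pair 1:1")
  if (nrow(mobile) < 3L) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- cr - as.vector(R %*% cm)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_pairs = nrow(mobile)),
            class = "superposition")
}

#' CA-based RMSD between two structures
#'
#' Pairs alpha carbons by (chain, residue number, insertion code), Kabsch-fits
#' them, and reports the RMSD, reproducing the unbound-versus-complex
#' comparison of the reference dataset.
#'
#' @param mobile,reference `ppi_structure` objects.
#' @param chains Optional chain subset applied to both.
#' @return A `superposition`.
#' @export
superpose_ca <- function(mobile, reference, chains = NULL) {
  pick <- function(s) {
    a <- s$atoms
    a <- a[a$name == "CA" & !a$het, , drop = FALSE]
    if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
    a
  }
  am <- pick(mobile); ar <- pick(reference)
  key <- function(a) paste(a$chain, a$resno, a$insert, sep = "|")
  m <- match(key(ar), key(am))
  ok <- !is.na(m)
  if (sum(ok) < 3L) stop("fewer than 3 paired CA atoms")
  superpose(as.matrix(am[m[ok], c("x", "y", "z")]),
            as.matrix(ar[ok, c("x", "y", "z")]))
}
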