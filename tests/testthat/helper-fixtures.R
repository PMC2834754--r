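# fixtures are built in code: pseudo-atom structures, plates, cavities

# quick structure from coordinates (carbon pseudo-atoms by default)
make_structure <- function(xyz, chain = "A", element = "C", name = "C",
                           resname = "ALA", resno = NULL, het = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = rep_len(name, n), altloc = "",
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else rep_len(resno, n),
    insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, het = rep_len(het, n), element = rep_len(element, n),
    stringsAsFactors = FALSE))
}

# merge several atom tables into one structure
bind_structures <- function(...) {
  atoms <- do.call(rbind, lapply(list(...), function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

# flat plate of pseudo-atoms at height z
plate_xyz <- function(z, extent = 18, spacing = 1.5) {
  as.matrix(expand.grid(x = seq(0, extent, spacing),
                        y = seq(0, extent, spacing), z = z))
}

# slab with spherical cavities carved at `centers`
cavity_slab <- function(centers, radius = 4, x_extent = 18, spacing = 1.5) {
  g <- as.matrix(expand.grid(x = seq(0, x_extent, spacing),
                             y = seq(0, 18, spacing),
                             z = seq(-4.5, 0, spacing)))
  keep <- rep(TRUE, nrow(g))
  for (i in seq_len(nrow(centers))) {
    keep <- keep & sqrt(rowSums(sweep(g, 2, centers[i, ])^2)) > radius
  }
  g[keep, , drop = FALSE]
}

# analytic SASA for spheres with only pairwise overlaps (cap formula):
# accessible area of sphere i = 4 pi R^2 minus one spherical cap per
# overlapping neighbour; caps must not overlap each other
cap_sasa <- function(xyz, radius_expanded) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  R <- rep_len(radius_expanded, n)
  areas <- 4 * pi * R^2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < R[i] + R[j]) {
        # height of the cap cut off sphere i by sphere j
        h <- R[i] - (d^2 + R[i]^2 - R[j]^2) / (2 * d)
        areas[i] <- areas[i] - 2 * pi * R[i] * h
      }
    }
  }
  areas
}

# brute-force interface segment splitter over an explicit residue walk
brute_segments <- function(mask, max_gap) {
  pos <- which(mask)
  if (length(pos) == 0) return(0L)
  n_seg <- 1L
  for (k in seq_along(pos)[-1]) {
    if (pos[k] - pos[k - 1] - 1 > max_gap) n_seg <- n_seg + 1L
  }
  n_seg
}

# reduced-size configuration used for dataset-scale tests (coarser SASA
# lattice and pocket grid keep the suite fast; results stay well inside the
# tolerances tested)
fast_config <- function(...) {
  pipeline_config(n_sphere_points = 240L, pocket_grid_spacing = 1.2,
                  gap_grid_spacing = 1.2, kmeans_restarts = 20L, ...)
}
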