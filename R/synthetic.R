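# Synthetic toy complexes.  Chains are built from ideal backbone templates
# (NeRF chaining of bond lengths/angles and phi/psi dihedrals: alpha helix
# -57/-47, strand -120/+120) arranged as contacting runs across a planar
# interface, with pseudo side chains and explicitly placed polar/charged
# functional-atom sites.  The generator emulates the two interface classes
# of the reference set: class-I-like complexes bind a single
# helical/extended peptide segment in a groove (few segments, small
# interface); class-II-like complexes pair two multi-run "globular" faces
# (7-10 segments, larger interface).  Structures are deterministic under a
# seed and are valid input to every descriptor stage.

# place atom d given reference atoms a-b-c, bond |cd|, angle b-c-d and
# dihedral a-b-c-d (degrees)
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180  # sign matches the measurement convention
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  if (sum(n^2) < 1e-12) n <- pracma_cross(c(0, 0, 1), bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal peptide backbone from phi/psi dihedrals
#'
#' Builds N, CA, C, O and a CB pseudo side chain per residue with ideal
#' bond geometry (NeRF chaining); trans peptide bonds.
#'
#' @param n Number of residues.
#' @param phi,psi Backbone dihedrals in degrees (recycled).
#' @return data.frame with resno, name, element, x, y, z.
#' @keywords internal
build_peptide <- function(n, phi = -57, psi = -47) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.0, 180)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 117.2, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.0, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi[i] + 180)
    CB <- nerf_place(C[i, ], N[i, ], CA[i, ], 1.530, 110.4, 122.7)
    rows[[i]] <- data.frame(
      resno = i,
      name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = c(N[i, 1], CA[i, 1], C[i, 1], O[1], CB[1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2], O[2], CB[2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3], O[3], CB[3]))
  }
  do.call(rbind, rows)
}

# rigidly place a fragment: principal CA axis along `axis`, atom cloud
# flattened toward the xy-plane, centroid at `at`
place_fragment <- function(frag, at = c(0, 0, 0), axis = c(1, 0, 0)) {
  xyz <- as.matrix(frag[, c("x", "y", "z")])
  ca <- xyz[frag$name == "CA", , drop = FALSE]
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  e <- eigen(crossprod(sweep(ca, 2, colMeans(ca))), symmetric = TRUE)
  R <- e$vectors  # columns: major, mid, minor
  if (det(R) < 0) R[, 3] <- -R[, 3]
  X <- X %*% R    # major axis -> x, minor (flattest) -> z
  axis <- axis / sqrt(sum(axis^2))
  # rotate x onto the requested axis about z when needed
  if (abs(axis[1] - 1) > 1e-9) {
    th <- atan2(axis[2], axis[1])
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    X <- X %*% t(Rz)
  }
  xyz2 <- sweep(X, 2, at, "+")
  frag$x <- xyz2[, 1]; frag$y <- xyz2[, 2]; frag$z <- xyz2[, 3]
  frag
}

# a serpentine multi-run face: `n_runs` strand runs of `run_len` residues
# along x at y spacing `y_step`, joined by `loop_len` coil residues bowed
# away from the interface (z_away); returns atom rows with sequential resno
build_face <- function(n_runs, run_len, loop_len, z_plane, z_away,
                       y_step = 4.8, resname = "ALA") {
  rows <- list()
  resno <- 0L
  for (r in seq_len(n_runs)) {
    frag <- build_peptide(run_len, phi = -120, psi = 120)
    frag <- place_fragment(frag, at = c(0, (r - 1) * y_step, z_plane))
    frag$resno <- frag$resno + resno
    resno <- resno + run_len
    rows[[length(rows) + 1L]] <- frag
    if (r < n_runs && loop_len > 0) {
      # CA-only loop arcing away from the interface
      ts <- seq_len(loop_len) / (loop_len + 1)
      loop <- data.frame(
        resno = resno + seq_len(loop_len),
        name = "CA", element = "C",
        x = (1 - ts) * max(frag$x) + ts * 0,
        y = (r - 1) * y_step + ts * y_step,
        z = z_away)
      resno <- resno + loop_len
      rows[[length(rows) + 1L]] <- loop
    }
  }
  out <- do.call(rbind, rows)
  out$resname <- resname
  out
}

finish_chain <- function(atoms, chain) {
  atoms$chain <- chain
  atoms$altloc <- ""
  atoms$insert <- ""
  atoms$occ <- 1
  atoms$het <- FALSE
  atoms
}

# rename `n_rename` run residues of a chain to charged types (no functional
# atoms attached: truncated side chains only change composition)
apply_charged <- function(atoms, candidate_resnos, n_rename) {
  if (n_rename <= 0 || length(candidate_resnos) == 0) return(atoms)
  pick <- candidate_resnos[seq(1, length(candidate_resnos),
                               length.out = min(n_rename,
                                                length(candidate_resnos)))]
  types <- rep_len(c("ASP", "LYS", "ARG", "GLU", "HIS"), length(pick))
  for (i in seq_along(pick)) {
    atoms$resname[atoms$resno == pick[i]] <- types[i]
  }
  atoms
}

# attach a functional site atom to a residue: rename the residue and add
# the named atom at an explicit position
attach_site <- function(atoms, resno, resname, atom_name, element, pos) {
  atoms$resname[atoms$resno == resno] <- resname
  rbind(atoms, data.frame(resno = resno, name = atom_name,
                          element = element, x = pos[1], y = pos[2],
                          z = pos[3], resname = resname,
                          stringsAsFactors = FALSE))
}

#' Specification of a synthetic toy complex
#'
#' @param kind One of `"class_I_helix_groove"`, `"class_I_strand"`,
#'   `"class_II_globular"`, `"zipA_like_flat"`.
#' @param pct_charged Target percentage of charged interface residues.
#' @param n_hbond_sites Number of engineered cross-interface hydrogen-bond
#'   site pairs.
#' @param n_salt_bridge_pairs Number of engineered salt-bridge pairs.
#' @param pocket_depth Groove wall height in Angstrom (class I groove).
#' @param seed Integer seed (jitter of the unbound form, charged placement).
#' @return List of class `toy_spec`.
#' @export
toy_spec <- function(kind = c("class_I_helix_groove", "class_I_strand",
                              "class_II_globular", "zipA_like_flat"),
                     pct_charged = 19, n_hbond_sites = NULL,
                     n_salt_bridge_pairs = NULL, pocket_depth = 3.0,
                     seed = 1L) {
  kind <- match.arg(kind)
  class_I <- kind != "class_II_globular"
  if (is.null(n_hbond_sites)) n_hbond_sites <- if (class_I) 1L else 8L
  if (is.null(n_salt_bridge_pairs)) {
    n_salt_bridge_pairs <- if (class_I) 0L else 1L
  }
  stopifnot(pct_charged >= 0, pct_charged <= 100, n_hbond_sites >= 0,
            n_salt_bridge_pairs >= 0, pocket_depth >= 0)
  structure(list(kind = kind, pct_charged = pct_charged,
                 n_hbond_sites = n_hbond_sites,
                 n_salt_bridge_pairs = n_salt_bridge_pairs,
                 pocket_depth = pocket_depth, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build a synthetic two-partner complex with ground truth
#'
#' Generates three coordinate sets: the protein/protein complex, the
#' unbound receptor (coordinates perturbed by a small seeded jitter, so the
#' unbound-vs-complex rmsd is realistic), and the receptor bound to a
#' ligand (a truncated fragment of the partner, or a surface-lying fragment
#' for the flat kind).  A manifest records the engineered ground truth.
#'
#' @param spec A [toy_spec()].
#' @return List of class `toy_complex`: `pp`, `unbound`, `ligand_complex`
#'   (`ppi_structure`s), `selection` (`partner_selection` incl. ligand) and
#'   `manifest`.
#' @export
build_toy_complex <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  class_I <- spec$kind != "class_II_globular"
  run_len <- 10L
  # receptor: contact face + body layer; short loops merge face runs into
  # few segments for class I, long loops keep class II runs separate
  loop_len <- if (class_I) 2L else 8L
  n_runs <- if (class_I) 3L else 4L
  # the flat kind mimics a smooth surface: denser rows, no atomic crevices
  y_step <- if (spec$kind == "zipA_like_flat") 3.2 else 4.8
  if (spec$kind == "zipA_like_flat") n_runs <- 4L
  face <- build_face(n_runs, run_len, loop_len, z_plane = 0, z_away = -6,
                     y_step = y_step)
  nres_face <- max(face$resno)
  body <- build_face(n_runs, run_len, loop_len, z_plane = -4.6, z_away = -9,
                     y_step = y_step)
  body$resno <- body$resno + nres_face
  body$y <- body$y + y_step / 2
  recA <- rbind(face, body)
  # groove walls flanking the peptide (class I groove kinds only)
  if (spec$kind == "class_I_helix_groove" && spec$pocket_depth > 0) {
    nres0 <- max(recA$resno)
    for (w in c(-1, 1)) {
      wall <- build_peptide(run_len, phi = -120, psi = 120)
      wall <- place_fragment(wall,
                             at = c(0, 4.8 + w * 5.6, spec$pocket_depth))
      wall$resno <- wall$resno + nres0
      wall$resname <- "ALA"
      nres0 <- nres0 + run_len
      recA <- rbind(recA, wall)
    }
  }
  # partner
  mid_y <- 4.8
  if (spec$kind == "class_II_globular") {
    partner <- build_face(n_runs, run_len, loop_len, z_plane = 4.0,
                          z_away = 10)
    partner$y <- partner$y + 2.4
  } else {
    if (spec$kind == "class_I_helix_groove") {
      partner <- build_peptide(14L, phi = -57, psi = -47)
    } else {
      partner <- build_peptide(10L, phi = -120, psi = 120)
    }
    partner$resname <- "ALA"
    partner <- place_fragment(partner, at = c(0, mid_y, 0))
    # drop onto the receptor face: lowest heavy atom at vdW contact height
    # (strands interdigitate with the face lattice, so they sit higher)
    drop_z <- if (spec$kind == "class_I_helix_groove") 2.6 else 3.1
    partner$z <- partner$z - min(partner$z) + drop_z
  }
  # engineered polar sites: pair face-run residues with partner residues at
  # matching x
  face_res <- seq_len(run_len * n_runs + loop_len * (n_runs - 1))
  face_run_res <- face$resno[face$name == "CA" & face$resno <= nres_face &
                             face$z > -1]
  partner_res <- sort(unique(partner$resno))
  n_sites <- spec$n_hbond_sites + spec$n_salt_bridge_pairs
  if (n_sites > 0) {
    a_pick <- face_run_res[seq(2, length(face_run_res),
                               length.out = n_sites)]
    b_pick <- partner_res[seq(2, length(partner_res),
                              length.out = n_sites)]
    for (s in seq_len(n_sites)) {
      ca_a <- recA[recA$resno == a_pick[s] & recA$name == "CA", ]
      site_a <- c(ca_a$x[1], ca_a$y[1], ca_a$z[1] + 2.9)
      if (s <= spec$n_hbond_sites) {
        recA <- attach_site(recA, a_pick[s], "SER", "OG", "O", site_a)
        partner <- attach_site(partner, b_pick[s], "ASN", "OD1", "O",
                               site_a + c(0, 0, 2.75))
      } else {
        recA <- attach_site(recA, a_pick[s], "GLU", "OE1", "O", site_a)
        partner <- attach_site(partner, b_pick[s], "LYS", "NZ", "N",
                               site_a + c(0, 0, 3.5))
      }
    }
  } else {
    a_pick <- integer(0); b_pick <- integer(0)
  }
  # charged composition: rename plain run residues (truncated side chains)
  n_interface_guess <- length(face_run_res) + length(partner_res)
  n_charged <- round(spec$pct_charged / 100 * n_interface_guess) -
    spec$n_salt_bridge_pairs * 2L
  cand_a <- setdiff(face_run_res, a_pick)
  cand_b <- setdiff(partner_res, b_pick)
  half <- ceiling(max(0, n_charged) / 2)
  recA <- apply_charged(recA, cand_a, half)
  partner <- apply_charged(partner, cand_b, max(0, n_charged) - half)
  recA <- finish_chain(recA, "A")
  partner <- finish_chain(partner, "B")
  assemble <- function(chains, id) {
    atoms <- do.call(rbind, chains)
    atoms$serial <- seq_len(nrow(atoms))
    new_structure(atoms[, c("serial", "name", "altloc", "resname", "chain",
                            "resno", "insert", "x", "y", "z", "occ", "het",
                            "element")], id = id)
  }
  pp <- assemble(list(recA, partner), paste0(spec$kind, "_pp"))
  # unbound receptor: seeded coordinate jitter (sd 0.4 A)
  unb <- recA
  jit <- matrix(stats::rnorm(3 * nrow(unb), sd = 0.4), ncol = 3)
  unb$x <- unb$x + jit[, 1]; unb$y <- unb$y + jit[, 2]
  unb$z <- unb$z + jit[, 3]
  unbound <- assemble(list(unb), paste0(spec$kind, "_unbound"))
  # ligand: truncated central fragment of the partner (heavy atoms), or the
  # same surface-lying fragment for the flat kind
  lig_res <- partner_res[seq(ceiling(length(partner_res) / 2) - 2,
                             length.out = 5)]
  lig <- partner[partner$resno %in% lig_res, , drop = FALSE]
  lig$resname <- "LIG"; lig$chain <- "X"; lig$resno <- 1L
  lig$het <- TRUE
  ligc <- assemble(list(recA, lig), paste0(spec$kind, "_ligand"))
  manifest <- list(
    kind = spec$kind, seed = spec$seed,
    class_label = if (class_I) "I" else "II",
    receptor_face_runs = n_runs, loop_len = loop_len,
    hbond_pairs = if (spec$n_hbond_sites > 0)
      cbind(a = a_pick[seq_len(spec$n_hbond_sites)],
            b = b_pick[seq_len(spec$n_hbond_sites)]) else NULL,
    salt_bridge_pairs = if (spec$n_salt_bridge_pairs > 0)
      cbind(a = a_pick[spec$n_hbond_sites + seq_len(spec$n_salt_bridge_pairs)],
            b = b_pick[spec$n_hbond_sites + seq_len(spec$n_salt_bridge_pairs)])
      else NULL,
    pct_charged_requested = spec$pct_charged,
    pocket_depth = spec$pocket_depth)
  structure(list(pp = pp, unbound = unbound, ligand_complex = ligc,
                 selection = partner_selection("A", "B",
                                               ligand = list(resname = "LIG")),
                 manifest = manifest),
            class = "toy_complex")
}

#' Simulate class-conditional descriptor tables
#'
#' Draws independent truncated Gaussians per descriptor with
#' class-conditional moments (defaults: the reference panel's class I/II
#' mean and sd; the charged-residue column uses the published overall
#' moments for both classes).  Counts are rounded, percentages clipped to
#' [0, 100], non-negative descriptors clipped at zero.
#'
#' @param n_per_class Named vector `c(I = , II = )` of rows per class.
#' @param class_params Optional list `list(I = data.frame(descriptor, mean,
#'   sd), II = ...)`; defaults to moments of the bundled reference panel.
#' @param seed Integer seed.
#' @return List: `panel` (data.frame of the six key descriptors),
#'   `class` (true labels).
#' @export
simulate_descriptor_table <- function(n_per_class = c(I = 6L, II = 11L),
                                      class_params = NULL, seed = 1L) {
  stopifnot(all(n_per_class >= 1))
  if (is.null(class_params)) {
    ref <- load_reference()
    moments <- function(cls) {
      ds <- c("asa_mean_side", "n_segments", "gap_volume", "pocket_volume",
              "hb_per_100A2")
      out <- do.call(rbind, lapply(ds, function(d) {
        g <- aggregate_descriptor(ref, d, cls)
        data.frame(descriptor = d, mean = g$mean, sd = g$sd)
      }))
      rbind(out, data.frame(descriptor = "pct_charged_residues",
                            mean = 18.9, sd = 13.8))
    }
    class_params <- list(I = moments("classI"), II = moments("classII"))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  draw <- function(cls, n) {
    p <- class_params[[cls]]
    cols <- lapply(seq_len(nrow(p)), function(i) {
      x <- stats::rnorm(n, p$mean[i], p$sd[i])
      d <- p$descriptor[i]
      x <- pmax(x, 0)
      if (d == "pct_charged_residues") x <- pmin(x, 100)
      if (d == "n_segments") x <- round(x)
      x
    })
    names(cols) <- p$descriptor
    as.data.frame(cols)
  }
  panel <- rbind(draw("I", n_per_class[["I"]]),
                 draw("II", n_per_class[["II"]]))
  list(panel = panel,
       class = rep(c("I", "II"), times = c(n_per_class[["I"]],
                                           n_per_class[["II"]])))
}
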