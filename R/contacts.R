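# Cross-interface polar contacts (hydrogen bonds, salt bridges), the
# interface segment counter, and the coarse secondary-structure interface
# classes.

# donor heavy atoms (with number of polar hydrogens) and acceptors, per
# residue; backbone N (except proline) donates, backbone O (and OXT) accepts
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"))
SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = character(0))

hb_roles <- function(atoms) {
  nm <- atoms$name; rn <- atoms$resname; el <- atoms$element
  donor <- (nm == "N" & el == "N" & rn != "PRO")
  acceptor <- (nm %in% c("O", "OXT") & el == "O")
  for (r in names(SIDECHAIN_DONORS)) {
    donor <- donor | (rn == r & nm %in% SIDECHAIN_DONORS[[r]])
  }
  for (r in names(SIDECHAIN_ACCEPTORS)) {
    acceptor <- acceptor | (rn == r & nm %in% SIDECHAIN_ACCEPTORS[[r]])
  }
  list(donor = which(donor), acceptor = which(acceptor))
}

# covalent antecedent of a donor: nearest heavy atom (used for the donor
# angle sanity filter)
donor_antecedent <- function(xyz, heavy_idx, donor_idx) {
  vapply(donor_idx, function(i) {
    cand <- setdiff(heavy_idx, i)
    d2 <- colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2)
    cand[which.min(d2)]
  }, integer(1))
}

#' Cross-interface hydrogen bonds
#'
#' Detects hydrogen bonds between the two sides of an interface using a
#' distance cutoff between the hydrogen atom and the acceptor.  When the
#' structure carries explicit hydrogens those are used; otherwise a polar
#' hydrogen is modelled on each donor at ideal bond length (1.0 A for N-H,
#' 0.96 A for O-H) directed at the candidate acceptor, subject to a >= 90
#' degree antecedent-donor-acceptor angle filter.  Each donor hydrogen
#' counts at most one bond (its nearest acceptor).
#'
#' @param complex A `ppi_structure`.
#' @param interface An `interface_definition` (sides define "across").
#' @param h_acceptor_cutoff H...acceptor cutoff in Angstrom (default 3.2).
#' @param min_donor_angle Donor angle sanity filter in degrees (default 90;
#'   set to 0 to disable).
#' @return data.frame, one row per bond: donor/acceptor atom rows, residue
#'   labels, `h_a_dist`, `d_a_dist`, `explicit_h`.
#' @export
hydrogen_bonds <- function(complex, interface, h_acceptor_cutoff = 3.2,
                           min_donor_angle = 90) {
  a <- complex$atoms
  xyz <- coords(complex)
  sides <- list(a = interface$interface_atoms_a,
                b = interface$interface_atoms_b)
  # work on whole chains of each side so donors just outside the buried set
  # still count only via cross-side geometry; restrict to interface residues
  res_key <- function(idx) paste(a$chain[idx], a$resno[idx], a$insert[idx])
  ires <- list(
    a = unique(paste(interface$interface_residues_a$chain,
                     interface$interface_residues_a$resno,
                     interface$interface_residues_a$insert)),
    b = unique(paste(interface$interface_residues_b$chain,
                     interface$interface_residues_b$resno,
                     interface$interface_residues_b$insert)))
  side_of <- rep(NA_character_, nrow(a))
  akey <- paste(a$chain, a$resno, a$insert)
  side_of[akey %in% ires$a & !a$het] <- "a"
  side_of[akey %in% ires$b & !a$het] <- "b"
  roles <- hb_roles(a)
  heavy_idx <- which(a$element != "H")
  has_h <- any(a$element == "H")
  bonds <- list()
  for (dside in c("a", "b")) {
    aside <- setdiff(c("a", "b"), dside)
    don <- roles$donor[which(side_of[roles$donor] == dside)]
    acc <- roles$acceptor[which(side_of[roles$acceptor] == aside)]
    if (length(don) == 0L || length(acc) == 0L) next
    ante <- donor_antecedent(xyz, heavy_idx, don)
    for (k in seq_along(don)) {
      i <- don[k]
      hd <- if (a$element[i] == "O") 0.96 else 1.0
      # explicit hydrogens bonded to this donor
      hyd <- integer(0)
      if (has_h) {
        hcand <- which(a$element == "H" & a$chain == a$chain[i] &
                       a$resno == a$resno[i])
        if (length(hcand) > 0) {
          d2 <- colSums((t(xyz[hcand, , drop = FALSE]) - xyz[i, ])^2)
          hyd <- hcand[d2 < 1.25^2]
        }
      }
      dvec <- xyz[acc, , drop = FALSE]
      d_a <- sqrt(colSums((t(dvec) - xyz[i, ])^2))
      if (length(hyd) > 0) {
        # one bond per explicit hydrogen: nearest acceptor within cutoff
        for (h in hyd) {
          h_a <- sqrt(colSums((t(dvec) - xyz[h, ])^2))
          j <- which.min(h_a)
          if (h_a[j] <= h_acceptor_cutoff) {
            bonds[[length(bonds) + 1L]] <-
              data.frame(donor = i, hydrogen = h, acceptor = acc[j],
                         h_a_dist = h_a[j], d_a_dist = d_a[j],
                         explicit_h = TRUE)
          }
        }
      } else {
        # modelled hydrogen along donor->acceptor: H...A = d(D,A) - bond
        h_a <- d_a - hd
        ok <- h_a <= h_acceptor_cutoff & d_a > 2.0
        if (min_donor_angle > 0) {
          v1 <- xyz[ante[k], ] - xyz[i, ]
          ang <- vapply(seq_along(acc), function(j) {
            v2 <- xyz[acc[j], ] - xyz[i, ]
            cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          }, numeric(1))
          ok <- ok & ang >= min_donor_angle
        }
        if (any(ok)) {
          j <- which(ok)[which.min(h_a[ok])]
          bonds[[length(bonds) + 1L]] <-
            data.frame(donor = i, hydrogen = NA_integer_, acceptor = acc[j],
                       h_a_dist = h_a[j], d_a_dist = d_a[j],
                       explicit_h = FALSE)
        }
      }
    }
  }
  if (length(bonds) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), h_a_dist = numeric(0),
                      d_a_dist = numeric(0), explicit_h = logical(0)))
  }
  out <- do.call(rbind, bonds)
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond density of an interface
#'
#' Number of cross-interface hydrogen bonds per 100 A^2 of interface
#' (one-side-equivalent buried area).
#'
#' @param n_bonds Number of hydrogen bonds.
#' @param interface An `interface_definition` (or a number, the
#'   `asa_mean_side` itself).
#' @return Bonds per 100 A^2.
#' @export
hb_density <- function(n_bonds, interface) {
  asa <- if (is.numeric(interface)) interface else interface$asa_mean_side
  if (asa <= 0) stop("zero interface: hydrogen-bond density undefined")
  100 * n_bonds / asa
}

SALT_ACID_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SALT_BASE_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))

#' Cross-interface salt bridges
#'
#' A salt bridge pairs an acidic residue (Asp/Glu) on one side of the
#' interface with a basic residue (Arg/His/Lys) on the other when their
#' side-chain functional atoms approach below the cutoff.  Each residue
#' pair counts once (minimum over its functional-atom pairs).
#'
#' @param complex A `ppi_structure`.
#' @param interface An `interface_definition`.
#' @param cutoff Distance cutoff in Angstrom, strict (default 4.0).
#' @return data.frame, one row per bridge: acidic and basic residue labels
#'   and the minimum functional-atom distance.
#' @export
salt_bridges <- function(complex, interface, cutoff = 4.0) {
  a <- complex$atoms
  xyz <- coords(complex)
  akey <- paste(a$chain, a$resno, a$insert)
  ires_a <- unique(paste(interface$interface_residues_a$chain,
                         interface$interface_residues_a$resno,
                         interface$interface_residues_a$insert))
  ires_b <- unique(paste(interface$interface_residues_b$chain,
                         interface$interface_residues_b$resno,
                         interface$interface_residues_b$insert))
  func_atoms <- function(res_keys, table) {
    idx <- which(akey %in% res_keys & !a$het &
                 a$resname %in% names(table))
    if (length(idx) == 0L) return(integer(0))
    idx[vapply(idx, function(i) a$name[i] %in% table[[a$resname[i]]],
               logical(1))]
  }
  bridges <- list()
  for (acid_side in c("a", "b")) {
    acid_keys <- if (acid_side == "a") ires_a else ires_b
    base_keys <- if (acid_side == "a") ires_b else ires_a
    ai <- func_atoms(acid_keys, SALT_ACID_ATOMS)
    bi <- func_atoms(base_keys, SALT_BASE_ATOMS)
    if (length(ai) == 0L || length(bi) == 0L) next
    D <- cross_dist2(xyz[ai, , drop = FALSE], xyz[bi, , drop = FALSE])
    D[D < 0] <- 0
    D <- sqrt(D)
    hit <- which(D < cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    pair_key <- paste(akey[ai[hit[, 1]]], akey[bi[hit[, 2]]], sep = " / ")
    for (p in unique(pair_key)) {
      rows <- which(pair_key == p)
      dmin <- min(D[hit[rows, , drop = FALSE]])
      i1 <- ai[hit[rows[1], 1]]; i2 <- bi[hit[rows[1], 2]]
      bridges[[length(bridges) + 1L]] <- data.frame(
        acidic = sprintf("%s %s%d%s", a$resname[i1], a$chain[i1],
                         a$resno[i1], a$insert[i1]),
        basic = sprintf("%s %s%d%s", a$resname[i2], a$chain[i2],
                        a$resno[i2], a$insert[i2]),
        min_dist = dmin)
    }
  }
  if (length(bridges) == 0L) {
    return(data.frame(acidic = character(0), basic = character(0),
                      min_dist = numeric(0)))
  }
  out <- unique(do.call(rbind, bridges))
  rownames(out) <- NULL
  out
}

#' Count interface segments along a chain
#'
#' An interface segment is a stretch of residues starting and ending with
#' interface residues, possibly containing intervening non-interface
#' residues; only interface residues count toward its length.  Two
#' interface residues belong to the same segment when separated by at most
#' `max_gap` consecutive non-interface residues.
#'
#' @param interface_mask Logical vector along the (ordered) chain residues.
#' @param max_gap Maximum intervening non-interface residues (default 4).
#' @return List: `n_segments`, `segment_lengths` (interface residues per
#'   segment), `segments` (list of interface residue positions).
#' @export
interface_segments <- function(interface_mask, max_gap = 4L) {
  pos <- which(interface_mask)
  if (length(pos) == 0L) {
    return(list(n_segments = 0L, segment_lengths = integer(0),
                segments = list()))
  }
  breaks <- which(diff(pos) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pos))
  segs <- mapply(function(s, e) pos[s:e], starts, ends, SIMPLIFY = FALSE)
  list(n_segments = length(segs),
       segment_lengths = vapply(segs, length, integer(1)),
       segments = segs)
}

#' Total interface segment count of a complex
#'
#' Applies [interface_segments()] to every chain of both partners and sums
#' the counts; complexes with fewer than six total segments are the
#' peptide-like class I.
#'
#' @param complex A `ppi_structure`.
#' @param selection A `partner_selection`.
#' @param interface An `interface_definition`.
#' @param max_gap Passed to [interface_segments()].
#' @return List: `n_segments` and per-chain counts.
#' @export
count_interface_segments <- function(complex, selection, interface,
                                     max_gap = 4L) {
  per_chain <- list()
  for (side in c("a", "b")) {
    chains <- if (side == "a") selection$side_a else selection$side_b
    ires <- if (side == "a") interface$interface_residues_a else
      interface$interface_residues_b
    ikey <- paste(ires$chain, ires$resno, ires$insert)
    for (ch in chains) {
      rt <- residue_table(complex, ch)
      rt <- rt[!rt$het, , drop = FALSE]
      if (nrow(rt) == 0L) next
      mask <- paste(rt$chain, rt$resno, rt$insert) %in% ikey
      per_chain[[ch]] <- interface_segments(mask, max_gap)$n_segments
    }
  }
  list(n_segments = sum(unlist(per_chain)),
       per_chain = unlist(per_chain))
}

#' Backbone dihedral angles of a chain
#' @keywords internal
backbone_dihedrals <- function(complex, chain) {
  a <- complex$atoms
  a <- a[a$chain == chain & !a$het & a$name %in% c("N", "CA", "C"), ,
         drop = FALSE]
  rt <- unique(a[, c("resno", "insert")])
  rt <- rt[order(rt$resno, rt$insert), ]
  get_atom <- function(resno, insert, name) {
    i <- which(a$resno == resno & a$insert == insert & a$name == name)
    if (length(i) == 0L) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  n <- nrow(rt)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get_atom(rt$resno[i], rt$insert[i], "N")
    CAi <- get_atom(rt$resno[i], rt$insert[i], "CA")
    Ci <- get_atom(rt$resno[i], rt$insert[i], "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1) {
      Cp <- get_atom(rt$resno[i - 1], rt$insert[i - 1], "C")
      # chain-break check: peptide bond C(i-1)-N(i) must be ~1.33 A
      if (!is.null(Cp) && sqrt(sum((Cp - Ni)^2)) < 2.0) {
        phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n) {
      Nn <- get_atom(rt$resno[i + 1], rt$insert[i + 1], "N")
      if (!is.null(Nn) && sqrt(sum((Ci - Nn)^2)) < 2.0) {
        psi[i] <- dihedral(Ni, CAi, Ci, Nn)
      }
    }
  }
  data.frame(chain = chain, resno = rt$resno, insert = rt$insert,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Per-residue secondary structure of a chain (H/E/C)
#'
#' Dihedral-window assignment: helix for phi in (-120, -20) and psi in
#' (-100, 10); strand for phi in (-180, -60) and psi in (60, 180) or below
#' -150.  Runs shorter than 3 residues revert to coil; residues at chain
#' breaks or without complete backbones are coil.
#'
#' @param complex A `ppi_structure`.
#' @param chain Chain identifier.
#' @return data.frame with chain, resno, insert, ss (`"H"`, `"E"`, `"C"`).
#' @export
assign_secondary_structure <- function(complex, chain) {
  dh <- backbone_dihedrals(complex, chain)
  ss <- rep("C", nrow(dh))
  helix <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi > -120 & dh$phi < -20 & dh$psi > -100 & dh$psi < 10
  strand <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi > -180 & dh$phi < -60 & (dh$psi > 60 | dh$psi < -150)
  ss[strand] <- "E"
  ss[helix] <- "H"
  # suppress runs shorter than 3
  r <- rle(ss)
  r$values[r$lengths < 3 & r$values != "C"] <- "C"
  dh$ss <- inverse.rle(r)
  dh[, c("chain", "resno", "insert", "ss")]
}

#' Four-way secondary-structure label from helix/strand percentages
#'
#' `H` if helix > 30\% and strand < 30\%; `S` if strand > 30\% and helix
#' < 30\%; `HS` if both exceed 30\%; `Coil` otherwise.
#'
#' @param helix_pct,strand_pct Percentages in [0, 100].
#' @return One of `"H"`, `"S"`, `"HS"`, `"Coil"`.
#' @export
ss_label <- function(helix_pct, strand_pct) {
  if (helix_pct > 30 && strand_pct < 30) "H"
  else if (helix_pct < 30 && strand_pct > 30) "S"
  else if (helix_pct > 30 && strand_pct > 30) "HS"
  else "Coil"
}

#' Secondary-structure class of each interface side
#'
#' Computes helix/strand fractions over the interface residues of each side
#' and applies the 30\% rule, yielding labels like `"H/H"` (helical
#' epitope on both sides).
#'
#' @param complex A `ppi_structure`.
#' @param selection A `partner_selection`.
#' @param interface An `interface_definition`.
#' @return List: per-side `helix_pct`, `strand_pct`, `label`, and the
#'   combined `pair` string (side A / side B).
#' @export
ss_interface_class <- function(complex, selection, interface) {
  side_class <- function(chains, ires) {
    ikey <- paste(ires$chain, ires$resno, ires$insert)
    ss_all <- do.call(rbind, lapply(chains, function(ch)
      assign_secondary_structure(complex, ch)))
    ss_int <- ss_all[paste(ss_all$chain, ss_all$resno, ss_all$insert)
                     %in% ikey, , drop = FALSE]
    if (nrow(ss_int) == 0L) {
      return(list(helix_pct = 0, strand_pct = 0, label = "Coil"))
    }
    h <- 100 * mean(ss_int$ss == "H")
    s <- 100 * mean(ss_int$ss == "E")
    list(helix_pct = h, strand_pct = s, label = ss_label(h, s))
  }
  sa <- side_class(selection$side_a, interface$interface_residues_a)
  sb <- side_class(selection$side_b, interface$interface_residues_b)
  list(side_a = sa, side_b = sb,
       pair = paste(sa$label, sb$label, sep = "/"))
}

#' Percentage of charged residues at the interface
#'
#' @param interface An `interface_definition`.
#' @return Percentage of interface residues (both sides pooled) classified
#'   as charged (Asp, Glu, Lys, Arg, His).
#' @export
pct_charged_interface <- function(interface) {
  res <- rbind(interface$interface_residues_a,
               interface$interface_residues_b)
  if (nrow(res) == 0L) stop("zero interface: no residues")
  cls <- classify_residue(res$resname)
  100 * mean(cls == "charged")
}
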