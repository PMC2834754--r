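# helper: a minimal two-sided complex with one engineered donor/acceptor
# pair at distance d (N-H donor on A with antecedent CA; backbone O on B)
hb_toy <- function(d) {
  a <- data.frame(
    serial = 1:4,
    name = c("CA", "N", "C", "O"),
    altloc = "", resname = c("GLY", "GLY", "GLY", "GLY"),
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L), insert = "",
    x = c(-1.5, 0, d + 1.5, d),
    y = 0, z = 0, occ = 1, het = FALSE,
    element = c("C", "N", "C", "O"))
  new_structure(a)
}

fake_interface <- function(s) {
  # treat every atom as interface for contact tests
  a <- s$atoms
  ia <- which(a$chain == "A"); ib <- which(a$chain == "B")
  res <- function(idx) unique(a[idx, c("chain", "resno", "insert",
                                       "resname")])
  structure(list(delta_asa_side_a = 100, delta_asa_side_b = 100,
                 asa_mean_side = 100,
                 interface_atoms_a = ia, interface_atoms_b = ib,
                 interface_residues_a = res(ia),
                 interface_residues_b = res(ib),
                 delta_per_atom_a = stats::setNames(rep(1, length(ia)), ia),
                 delta_per_atom_b = stats::setNames(rep(1, length(ib)), ib),
                 atom_burial_threshold = 0.1),
            class = "interface_definition")
}

test_that("a linear N-H...O pair at 2.9 A gives one bond, at 6 A none", {
  s <- hb_toy(2.9)
  hb <- hydrogen_bonds(s, fake_interface(s))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$h_a_dist, 2.9 - 1.0, tolerance = 1e-9)
  expect_equal(hb$d_a_dist, 2.9, tolerance = 1e-9)
  far <- hb_toy(6)
  expect_equal(nrow(hydrogen_bonds(far, fake_interface(far))), 0L)
})

test_that("explicit hydrogens are used when present", {
  a <- data.frame(
    serial = 1:5,
    name = c("CA", "N", "H", "C", "O"),
    altloc = "", resname = "GLY",
    chain = c("A", "A", "A", "B", "B"),
    resno = c(1L, 1L, 1L, 1L, 1L), insert = "",
    x = c(-1.5, 0, 1.0, 4.4, 2.9),
    y = 0, z = 0, occ = 1, het = FALSE,
    element = c("C", "N", "H", "C", "O"))
  s <- new_structure(a)
  hb <- hydrogen_bonds(s, fake_interface(s))
  expect_equal(nrow(hb), 1L)
  expect_true(hb$explicit_h)
  expect_equal(hb$h_a_dist, 1.9, tolerance = 1e-9)
})

test_that("hydrogen bonds match a brute-force donor/acceptor scan on a toy", {
  toy <- build_toy_complex(toy_spec("class_II_globular", seed = 3))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  hb <- hydrogen_bonds(toy$pp, idef, min_donor_angle = 0)
  # brute-force double loop: per donor (no explicit H), nearest acceptor
  # across the interface with d(D,A) - bond <= 3.2
  a <- toy$pp$atoms
  xyz <- coords(toy$pp)
  akey <- paste(a$chain, a$resno, a$insert)
  ikey_a <- paste(idef$interface_residues_a$chain,
                  idef$interface_residues_a$resno,
                  idef$interface_residues_a$insert)
  ikey_b <- paste(idef$interface_residues_b$chain,
                  idef$interface_residues_b$resno,
                  idef$interface_residues_b$insert)
  don_names <- list(SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
                    TRP = "NE1", ASN = "ND2", GLN = "NE2",
                    ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
  acc_names <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1",
                    GLN = "OE1", ASP = c("OD1", "OD2"),
                    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))
  is_don <- function(i) {
    (a$name[i] == "N" & a$resname[i] != "PRO") ||
      (a$resname[i] %in% names(don_names) &&
         a$name[i] %in% don_names[[a$resname[i]]])
  }
  is_acc <- function(i) {
    a$name[i] %in% c("O", "OXT") ||
      (a$resname[i] %in% names(acc_names) &&
         a$name[i] %in% acc_names[[a$resname[i]]])
  }
  count <- 0L
  for (i in seq_len(nrow(a))) {
    if (!is_don(i)) next
    dside <- if (akey[i] %in% ikey_a) "a" else
      if (akey[i] %in% ikey_b) "b" else next
    bond <- if (a$element[i] == "O") 0.96 else 1.0
    best <- Inf
    for (j in seq_len(nrow(a))) {
      if (!is_acc(j)) next
      aside <- if (akey[j] %in% ikey_a) "a" else
        if (akey[j] %in% ikey_b) "b" else next
      if (aside == dside) next
      dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dd > 2.0 && dd - bond < best) best <- dd - bond
    }
    if (best <= 3.2) count <- count + 1L
  }
  expect_equal(nrow(hb), count)
})

test_that("hydrogen-bond density is bonds per 100 A^2 of one-side area", {
  expect_equal(hb_density(6, 550), 100 * 6 / 550, tolerance = 1e-12)
  expect_equal(round(hb_density(6, 550), 2), 1.09)
  expect_equal(hb_density(0, 550), 0)
  expect_equal(hb_density(4, 400), 2 * hb_density(4, 800))
  expect_error(hb_density(3, 0), "zero interface")
})

test_that("salt bridges follow the strict 4.0 A acid/base rule", {
  mk_pair <- function(d) {
    a <- data.frame(
      serial = 1:6,
      name = c("CA", "CB", "OE2", "CA", "CB", "NZ"),
      altloc = "",
      resname = c("GLU", "GLU", "GLU", "LYS", "LYS", "LYS"),
      chain = c("A", "A", "A", "B", "B", "B"),
      resno = c(1L, 1L, 1L, 1L, 1L, 1L), insert = "",
      x = c(-3, -1.5, 0, d + 3, d + 1.5, d),
      y = 0, z = 0, occ = 1, het = FALSE,
      element = c("C", "C", "O", "C", "C", "N"))
    new_structure(a)
  }
  s35 <- mk_pair(3.5)
  sb <- salt_bridges(s35, fake_interface(s35))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_dist, 3.5, tolerance = 1e-9)
  s45 <- mk_pair(4.5)
  expect_equal(nrow(salt_bridges(s45, fake_interface(s45))), 0L)
  s40 <- mk_pair(4.0)  # strict inequality at the cutoff
  expect_equal(nrow(salt_bridges(s40, fake_interface(s40))), 0L)
})

test_that("multiple close atom pairs still count as one bridge per residue pair", {
  a <- data.frame(
    serial = 1:4,
    name = c("OE1", "OE2", "NZ", "NH1"),
    altloc = "",
    resname = c("GLU", "GLU", "LYS", "LYS"),
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 2L, 2L), insert = "",
    x = c(0, 1.2, 3.2, 3.6), y = 0, z = 0, occ = 1, het = FALSE,
    element = c("O", "O", "N", "N"))
  a$resname[3:4] <- "LYS"   # NH1 on LYS is ignored (not a Lys base atom)
  s <- new_structure(a)
  sb <- salt_bridges(s, fake_interface(s))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_dist, 3.2 - 1.2, tolerance = 1e-9)
})

test_that("segment counting follows the bounded-gap rule", {
  expect_equal(interface_segments(c(TRUE, TRUE, TRUE))$n_segments, 1L)
  expect_equal(interface_segments(c(TRUE, TRUE, TRUE))$segment_lengths, 3L)
  # five intervening non-interface residues exceed max_gap = 4
  m <- c(TRUE, rep(FALSE, 5), TRUE)
  expect_equal(interface_segments(m, max_gap = 4)$n_segments, 2L)
  m4 <- c(TRUE, rep(FALSE, 4), TRUE)
  expect_equal(interface_segments(m4, max_gap = 4)$n_segments, 1L)
  expect_equal(interface_segments(logical(5))$n_segments, 0L)
  # only interface residues count toward segment length
  expect_equal(interface_segments(m4, max_gap = 4)$segment_lengths, 2L)
})

test_that("segment counter equals the brute-force splitter on random masks", {
  set.seed(11)
  for (rep in 1:50) {
    mask <- runif(sample(3:30, 1)) < 0.4
    for (g in 0:6) {
      expect_equal(interface_segments(mask, max_gap = g)$n_segments,
                   brute_segments(mask, g))
    }
  }
})

test_that("segment count is non-increasing in max_gap", {
  set.seed(12)
  for (rep in 1:20) {
    mask <- runif(40) < 0.35
    counts <- vapply(0:6, function(g)
      interface_segments(mask, max_gap = g)$n_segments, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("contacts are symmetric under swapping the two sides", {
  toy <- build_toy_complex(toy_spec("class_II_globular", seed = 4))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  swapped <- idef
  swapped$interface_atoms_a <- idef$interface_atoms_b
  swapped$interface_atoms_b <- idef$interface_atoms_a
  swapped$interface_residues_a <- idef$interface_residues_b
  swapped$interface_residues_b <- idef$interface_residues_a
  expect_equal(nrow(salt_bridges(toy$pp, idef)),
               nrow(salt_bridges(toy$pp, swapped)))
  expect_equal(nrow(hydrogen_bonds(toy$pp, idef)),
               nrow(hydrogen_bonds(toy$pp, swapped)))
})

test_that("salt-bridge residues are interface residues", {
  toy <- build_toy_complex(toy_spec("class_II_globular", seed = 5))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  sb <- salt_bridges(toy$pp, idef)
  expect_gte(nrow(sb), 1L)
  ires <- c(paste(idef$interface_residues_a$resname,
                  paste0(idef$interface_residues_a$chain,
                         idef$interface_residues_a$resno,
                         idef$interface_residues_a$insert)),
            paste(idef$interface_residues_b$resname,
                  paste0(idef$interface_residues_b$chain,
                         idef$interface_residues_b$resno,
                         idef$interface_residues_b$insert)))
  expect_true(all(c(sb$acidic, sb$basic) %in% ires))
})

test_that("the four-way 30 percent secondary-structure rule labels correctly", {
  expect_equal(ss_label(100, 0), "H")
  expect_equal(ss_label(10, 60), "S")
  expect_equal(ss_label(40, 40), "HS")
  expect_equal(ss_label(10, 10), "Coil")
})

test_that("ideal helix and strand chains are assigned H and E", {
  toy <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 7))
  ssb <- assign_secondary_structure(toy$pp, "B")
  expect_gt(mean(ssb$ss == "H"), 0.7)   # helix interior is H
  ssa <- assign_secondary_structure(toy$pp, "A")
  expect_gt(sum(ssa$ss == "E"), 10)     # strand runs are E
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  cls <- ss_interface_class(toy$pp, toy$selection, idef)
  expect_equal(cls$side_b$label, "H")
})
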