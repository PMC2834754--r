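test_that("SASA of an isolated sphere matches the analytic area", {
  s <- shrake_rupley(matrix(0, 1, 3), "C")
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(s$total, analytic, tolerance = 0.01)
  expect_equal(s$radii_set_name, "bondi")
  # far-apart atoms are additive
  s2 <- shrake_rupley(rbind(c(0, 0, 0), c(50, 0, 0)), c("C", "C"))
  expect_equal(s2$total, 2 * analytic, tolerance = 0.01)
  expect_error(shrake_rupley(matrix(0, 1, 3), "QQ"), "radius")
})

test_that("SASA of a collinear triple matches the spherical-cap oracle", {
  # spacing chosen so only adjacent probe-expanded spheres (R = 3.1)
  # overlap and opposing caps stay disjoint: closed-form solution exists
  xyz <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(6.4, 0, 0))
  s <- shrake_rupley(xyz, c("C", "C", "C"))
  oracle <- cap_sasa(xyz, 1.70 + 1.4)
  expect_equal(s$per_atom, oracle, tolerance = 0.02)
  expect_equal(s$total, sum(oracle), tolerance = 0.02)
})

test_that("adding atoms never increases any existing atom's area", {
  set.seed(42)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  el <- rep("C", 10)
  base <- shrake_rupley(xyz, el)
  for (k in 1:5) {
    extra <- rbind(xyz, matrix(rnorm(3, sd = 3), 1, 3))
    grown <- shrake_rupley(extra, c(el, "C"))
    expect_true(all(grown$per_atom[1:10] <= base$per_atom + 1e-9))
  }
})

test_that("delta-ASA identity dA + dB = A + B - AB holds exactly", {
  set.seed(7)
  A <- make_structure(matrix(rnorm(36, sd = 2.5), 12, 3), chain = "A")
  B <- make_structure(sweep(matrix(rnorm(36, sd = 2.5), 12, 3), 2,
                            c(4, 0, 0), "+"), chain = "B")
  cx <- bind_structures(A, B)
  sel <- partner_selection("A", "B")
  idef <- define_interface(cx, sel)
  sasa_a <- structure_sasa(A)$total
  sasa_b <- structure_sasa(B)$total
  sasa_ab <- structure_sasa(cx)$total
  expect_equal(idef$delta_asa_side_a + idef$delta_asa_side_b,
               sasa_a + sasa_b - sasa_ab, tolerance = 1e-9)
  expect_equal(idef$asa_mean_side,
               (idef$delta_asa_side_a + idef$delta_asa_side_b) / 2)
})

test_that("disjoint partners give a valid zero interface", {
  A <- make_structure(plate_xyz(0, 6, 3), chain = "A")
  B <- make_structure(plate_xyz(50, 6, 3), chain = "B")
  cx <- bind_structures(A, B)
  idef <- define_interface(cx, partner_selection("A", "B"))
  expect_equal(idef$delta_asa_side_a, 0)
  expect_equal(idef$delta_asa_side_b, 0)
  expect_equal(length(idef$interface_atoms_a), 0L)
  expect_equal(nrow(idef$interface_residues_b), 0L)
})

test_that("mirror-symmetric dimers bury the same area on both sides", {
  half <- matrix(c(0, 0, 0,  3, 0, 0,  0, 3, 0,  3, 3, 0), 4, 3,
                 byrow = TRUE)
  A <- make_structure(cbind(half[, 1:2], -2), chain = "A")
  B <- make_structure(cbind(half[, 1:2], +2), chain = "B")
  cx <- bind_structures(A, B)
  idef <- define_interface(cx, partner_selection("A", "B"))
  expect_gt(idef$delta_asa_side_a, 0)
  # the deterministic point lattice is not mirror-symmetric, so the two
  # sides agree only to the lattice resolution (<1%)
  expect_equal(idef$delta_asa_side_a, idef$delta_asa_side_b,
               tolerance = 0.01)
})

test_that("interface atom sets shrink as the burial threshold grows", {
  toy <- build_toy_complex(toy_spec("class_I_strand", seed = 2))
  sizes <- vapply(c(0.1, 1, 5, 20), function(thr) {
    idef <- define_interface(toy$pp, toy$selection,
                             atom_burial_threshold = thr,
                             n_points = 240L)
    length(idef$interface_atoms_a) + length(idef$interface_atoms_b)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_gt(sizes[1], 0)
})

test_that("ligand neighbourhood uses a closed 4.5 A cutoff", {
  lig <- make_structure(matrix(0, 1, 3), chain = "X", resname = "LIG",
                        het = TRUE)
  prot <- make_structure(rbind(c(4.4, 0, 0), c(4.6, 0, 0)), chain = "A")
  cx <- bind_structures(prot, lig)
  nb <- ligand_neighborhood(cx, cx$atoms[cx$atoms$het, ], cutoff = 4.5)
  picked <- cx$atoms$x[nb$atom_idx]
  expect_true(4.4 %in% picked)
  expect_false(4.6 %in% picked)
})

test_that("ligand neighbourhood equals the brute-force pairwise scan", {
  toy <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 5))
  lc <- toy$ligand_complex
  lig <- extract_ligand(lc, toy$selection)
  nb <- ligand_neighborhood(lc, lig, cutoff = 4.5)
  # O(n^2) double loop oracle
  prot <- which(!lc$atoms$het)
  P <- coords(lc, prot); L <- as.matrix(lig[, c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(P)), function(i) {
    any(sqrt(colSums((t(L) - P[i, ])^2)) <= 4.5)
  }, logical(1))
  expect_equal(sort(nb$atom_idx), sort(prot[keep]))
})

test_that("inhibitor coverage is 0 for a distant ligand, 100 for the partner copy", {
  toy <- build_toy_complex(toy_spec("class_I_strand", seed = 3))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  rec <- subset_chains(toy$pp, "A")
  # far ligand: no coverage
  far <- make_structure(matrix(c(0, 0, 90), 1, 3), chain = "X",
                        resname = "LIG", resno = 1, het = TRUE)
  cx_far <- bind_structures(rec, far)
  expect_equal(ligand_coverage(cx_far, toy$selection, idef, toy$pp,
                               n_points = 240L), 0)
  # ligand = exact copy of the partner's atoms: full self-coverage
  partner <- toy$pp$atoms[toy$pp$atoms$chain == "B", ]
  partner$chain <- "X"; partner$resname <- "LIG"; partner$resno <- 1L
  partner$het <- TRUE
  cx_self <- bind_structures(rec, new_structure(partner))
  expect_equal(ligand_coverage(cx_self, toy$selection, idef, toy$pp,
                               n_points = 240L), 100, tolerance = 1e-6)
})

test_that("partial ligands cover the per-atom delta-ASA bookkeeping ratio", {
  toy <- build_toy_complex(toy_spec("class_I_strand", seed = 4))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  h <- ligand_coverage(toy$ligand_complex, toy$selection, idef, toy$pp,
                       n_points = 240L)
  expect_gt(h, 0); expect_lte(h, 100)
  # direct per-atom bookkeeping oracle
  lc <- toy$ligand_complex
  lig <- extract_ligand(lc, toy$selection)
  rec_idx <- which(lc$atoms$chain == "A" & !lc$atoms$het)
  rec <- lc$atoms[rec_idx, ]
  with_idx <- c(rec_idx, as.integer(rownames(lig)))
  aw <- lc$atoms[with_idx, ]
  s_alone <- shrake_rupley(as.matrix(rec[, c("x", "y", "z")]), rec$element,
                           n_points = 240L)
  s_with <- shrake_rupley(as.matrix(aw[, c("x", "y", "z")]), aw$element,
                          n_points = 240L)
  d_lig <- pmax(s_alone$per_atom - s_with$per_atom[seq_along(rec_idx)], 0)
  key <- function(a) paste(a$chain, a$resno, a$insert, a$name)
  ia <- toy$pp$atoms[idef$interface_atoms_a, ]
  m <- match(key(ia), key(rec))
  num <- sum(d_lig[m])
  den <- sum(idef$delta_per_atom_a[as.character(idef$interface_atoms_a)])
  expect_equal(h, min(100, 100 * num / den), tolerance = 1e-9)
})
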