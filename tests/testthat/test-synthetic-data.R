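test_that("toy generation is deterministic under a seed", {
  t1 <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 11))
  t2 <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 11))
  expect_identical(write_structure(t1$pp), write_structure(t2$pp))
  expect_identical(write_structure(t1$unbound), write_structure(t2$unbound))
  expect_identical(write_structure(t1$ligand_complex),
                   write_structure(t2$ligand_complex))
  t3 <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 12))
  expect_false(identical(write_structure(t1$unbound),
                         write_structure(t3$unbound)))
})

test_that("generated structures survive the PDB round trip (schema validity)", {
  for (kind in c("class_I_helix_groove", "class_II_globular")) {
    toy <- build_toy_complex(toy_spec(kind, seed = 2))
    s2 <- read_structure(write_structure(toy$pp))
    expect_equal(nrow(s2$atoms), nrow(toy$pp$atoms))
    expect_equal(coords(s2), round(coords(toy$pp), 3),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_setequal(unique(s2$atoms$chain), c("A", "B"))
  }
})

test_that("class-I toys bind a helical peptide with few segments", {
  toy <- build_toy_complex(toy_spec("class_I_helix_groove", seed = 7))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  seg <- count_interface_segments(toy$pp, toy$selection, idef)
  expect_lte(seg$n_segments, 5L)
  cls <- ss_interface_class(toy$pp, toy$selection, idef)
  expect_equal(cls$side_b$label, "H")   # the peptide side is helical
  expect_equal(assign_class(seg$n_segments), "I")
})

test_that("class-II toys present globular multi-segment interfaces", {
  toy <- build_toy_complex(toy_spec("class_II_globular", seed = 7))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  seg <- count_interface_segments(toy$pp, toy$selection, idef)
  expect_gte(seg$n_segments, 7L)
  expect_lte(seg$n_segments, 10L)
  expect_equal(assign_class(seg$n_segments), "II")
})

test_that("engineered salt bridges and infeasible specs behave as declared", {
  toy <- build_toy_complex(toy_spec("class_II_globular", seed = 3))
  idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
  sb <- salt_bridges(toy$pp, idef)
  expect_gte(nrow(sb), toy$manifest$salt_bridge_pairs |> nrow())
  expect_error(toy_spec("class_I_strand", pct_charged = 150))
})

test_that("class directions match the reference dataset: ASA, segments, Hb", {
  measure <- function(kind, seed) {
    toy <- build_toy_complex(toy_spec(kind, seed = seed))
    idef <- define_interface(toy$pp, toy$selection, n_points = 240L)
    seg <- count_interface_segments(toy$pp, toy$selection, idef)
    hb <- hydrogen_bonds(toy$pp, idef)
    c(asa = idef$asa_mean_side, seg = seg$n_segments,
      hb = hb_density(nrow(hb), idef))
  }
  I <- rbind(measure("class_I_helix_groove", 1),
             measure("class_I_strand", 2))
  II <- rbind(measure("class_II_globular", 1),
              measure("class_II_globular", 2))
  # class I: smaller interfaces, fewer segments, lower H-bond density
  expect_lt(mean(I[, "asa"]), mean(II[, "asa"]))
  expect_lt(mean(I[, "seg"]), mean(II[, "seg"]))
  expect_lt(mean(I[, "hb"]), mean(II[, "hb"]))
})

test_that("simulated descriptor tables reproduce their input moments", {
  sim <- simulate_descriptor_table(n_per_class = c(I = 10000L, II = 10000L),
                                   seed = 5)
  ref <- load_reference()
  gI <- aggregate_descriptor(ref, "asa_mean_side", "classI")
  xI <- sim$panel$asa_mean_side[sim$class == "I"]
  se <- gI$sd / sqrt(length(xI))
  expect_lt(abs(mean(xI) - gI$mean), 3 * se + 1e-9)
  gII <- aggregate_descriptor(ref, "hb_per_100A2", "classII")
  xII <- sim$panel$hb_per_100A2[sim$class == "II"]
  # truncation at zero biases the small-mean positive column slightly up;
  # allow the bias plus 3 standard errors
  expect_lt(abs(mean(xII) - gII$mean),
            3 * gII$sd / sqrt(length(xII)) + 0.05 * gII$mean)
  # percentages clipped, counts rounded
  expect_true(all(sim$panel$pct_charged_residues >= 0 &
                  sim$panel$pct_charged_residues <= 100))
  expect_true(all(sim$panel$n_segments == round(sim$panel$n_segments)))
  sim2 <- simulate_descriptor_table(n_per_class = c(I = 10000L,
                                                    II = 10000L), seed = 5)
  expect_identical(sim$panel, sim2$panel)
})

test_that("simulated class ASA separates with the printed t threshold", {
  ref <- load_reference()
  hits <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    sim <- simulate_descriptor_table(n_per_class = c(I = 6L, II = 11L),
                                     seed = r)
    x <- sim$panel$asa_mean_side
    gI <- group_stats(mean(x[sim$class == "I"]),
                      var(x[sim$class == "I"]), 6)
    gII <- group_stats(mean(x[sim$class == "II"]),
                       var(x[sim$class == "II"]), 11)
    if (abs(t_value(gI, gII)$t) > 1.34) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.5)
})
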