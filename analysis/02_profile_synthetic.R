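#!/usr/bin/env Rscript
# Run the full descriptor pipeline end to end on synthetic complexes: one
# class-I helix-in-groove triplet (complex, unbound receptor, receptor +
# inhibitor fragment) and one class-II globular pair, plus the flat-surface
# control whose ligand lies on the surface without any pocket.
#
# Writes results/synthetic_reports.csv (one descriptor row per complex).

suppressMessages(library(ppiprofiler))
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config(n_sphere_points = 480L)
kinds <- c("class_I_helix_groove", "class_I_strand",
           "class_II_globular", "zipA_like_flat")
rows <- list()
for (kind in kinds) {
  toy <- build_toy_complex(toy_spec(kind, seed = 7))
  rep <- profile_complex(toy$pp, toy$selection, unbound = toy$unbound,
                         ligand_complex = toy$ligand_complex, config = cfg)
  cat("\n==", kind, "==\n")
  print(rep)
  rows[[kind]] <- data.frame(kind = kind,
                             expected_class = toy$manifest$class_label,
                             assigned_class = rep$ppi_class,
                             as.data.frame(rep$panel[
                               vapply(rep$panel, is.numeric, logical(1))]))
}
panel <- do.call(rbind, rows)
write.csv(panel, "results/synthetic_reports.csv", row.names = FALSE)

cat("\nclass assignment matches the generator ground truth:",
    all(panel$expected_class == panel$assigned_class), "\n")
cat("flat-surface control has zero ligand-occupied pocket volume:",
    panel["zipA_like_flat", "pocket_volume"] == 0, "\n")
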