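#!/usr/bin/env Rscript
# Druggability comparison: score example query interfaces against the
# reference distribution of interfaces with known inhibitors, the way the
# interactive comparison of the reference web resource behaves: per-
# descriptor standardised distances, close/very-close counts, an overall
# score (lower = more reference-like) and a weak/strong affinity
# indication.
#
# Writes results/druggability_examples.csv.

suppressMessages(library(ppiprofiler))
dir.create("results", showWarnings = FALSE)

ref <- load_reference()
X <- reference_key_matrix(ref, seed = 1)

queries <- list(
  reference_like = as.list(colMeans(X)),
  classI_like = as.list(colMeans(X[ref$ppi_class == "I", ])),
  classII_like = as.list(colMeans(X[ref$ppi_class == "II", ])),
  atypical = as.list(colMeans(X) + 3 * apply(X, 2, sd)))

rows <- list()
for (nm in names(queries)) {
  rep <- compare_to_reference(queries[[nm]], ref, seed = 1)
  cat("\n==", nm, "==\n"); print(rep)
  rows[[nm]] <- data.frame(query = nm,
                           overall_score = rep$overall_score,
                           n_close_or_very_close = rep$n_close_or_very_close,
                           affinity_indication = rep$affinity_indication)
}
write.csv(do.call(rbind, rows), "results/druggability_examples.csv",
          row.names = FALSE)
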