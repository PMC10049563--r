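#!/usr/bin/env Rscript
# Stage 5: source apportionment — correlations, adequacy tests,
# varimax-rotated PCA, hierarchical clustering of elements.

suppressPackageStartupMessages(library(metalrisk))
samples <- read_samples("results/samples.csv")

for (a in sort(unique(samples$area))) {
  s <- samples[samples$area == a, ]
  cm <- pearson_matrix(s)
  write_correlation(cm, sprintf("results/correlation_%s.csv", a))
  cat("\n=== Area", a, "(n =", cm$n, ") ===\n")
  pc <- pca_varimax(cm)
  print(pc)
  write.csv(round(pc$loadings_rotated, 3),
            sprintf("results/pca_loadings_%s.csv", a))
  cl <- cluster_elements(s, k = 3)
  cat("Element clusters (1 - r distance, average linkage, k = 3):\n")
  print(split(names(cl$clusters), cl$clusters))
}
cat("\nCorrelation and loading tables written under results/\n")
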