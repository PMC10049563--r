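#!/usr/bin/env Rscript
# Stage 4: IDW concentration surfaces and classified risk surfaces.

suppressPackageStartupMessages(library(metalrisk))
samples <- read_samples("results/samples.csv")
dir.create("results/surfaces", showWarnings = FALSE)

for (a in sort(unique(samples$area))) {
  s <- samples[samples$area == a, ]
  g <- grid_over_points(s$x, s$y, n_cells = 60)
  for (el in hm_elements()) {
    surf <- idw_interpolate(s$x, s$y, s[[el]], g, power = 2)
    write_esri_ascii(surf, sprintf("results/surfaces/%s_%s.asc", a, el))
  }
  rs <- risk_surface(s, g)
  write_esri_ascii(rs$surface, sprintf("results/surfaces/%s_PRI.asc", a))
  write_esri_ascii(rs$classes, sprintf("results/surfaces/%s_PRI_class.asc", a))
  cls <- factor(rs$classes$labels[rs$classes$values],
                levels = rs$classes$labels)
  cat(sprintf("Area %s: PRI surface %.0f-%.0f; cells by risk class:\n",
              a, min(rs$surface$values), max(rs$surface$values)))
  print(round(100 * prop.table(table(cls)), 1))
}
cat("Surfaces written under results/surfaces/ (ESRI ASCII grids)\n")
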