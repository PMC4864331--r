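#!/usr/bin/env Rscript
# Stage 5: principal coordinates analysis of the city x habitat centroid
# distance matrices (community, diet guilds, habitat guilds), with
# correlation vectors for items whose |r| with a plotted axis exceeds
# 0.75.

suppressPackageStartupMessages(library(urbfilter))

study <- read_survey("results/data/survey.csv", "results/data/cells.csv",
                     "results/data/traits.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
grp <- interaction(study$cells$city, study$cells$habitat, drop = TRUE,
                   sep = "_")

mats <- list(
  community = fourth_root(study$abund),
  diet_guilds = fourth_root(aggregate_guilds(study$abund, study$traits,
                                             "diet")),
  habitat_guilds = fourth_root(aggregate_guilds(study$abund,
                                                study$traits, "habitat")))

for (lvl in names(mats)) {
  D <- bray_curtis(mats[[lvl]])
  Dc <- suppressWarnings(centroid_distances(D, grp))
  ord <- pcoa_ord(Dc, n_axes = 2)
  means <- rowsum(mats[[lvl]], grp) / as.vector(table(grp))
  means <- means[rownames(as.matrix(Dc)), , drop = FALSE]
  vf <- vector_fit(ord, means, threshold = 0.75)
  write.csv(data.frame(group = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            sprintf("results/tables/pcoa_%s_coordinates.csv", lvl),
            row.names = FALSE)
  write.csv(vf, sprintf("results/tables/pcoa_%s_vectors.csv", lvl),
            row.names = FALSE)
  cat("\n==", lvl, "==\n")
  print(ord)
  cat("Items with |r| > 0.75:",
      paste(vf$item[vf$shown], collapse = ", "), "\n")
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(sprintf("results/figures/pcoa_%s.png", lvl),
                    plot_ordination(ord, vf), width = 6, height = 5,
                    dpi = 150)
  }
}
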