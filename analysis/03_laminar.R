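#!/usr/bin/env Rscript
# Stage 3: laminar profiles of the saliency-sensitive CBV response.
#
# Per subject and ROI the voxel betas were unmixed into 5 compartments by the
# partial-volume regression Y = X B + U; cortical-layer responses were RMS
# normalized across subjects and contrasted (90 minus 15 degrees). A one-way
# repeated-measures ANOVA across depths tests the laminar profile per ROI.

suppressPackageStartupMessages(library(lamsal))
bundle <- readRDS("results/bundle.rds")

layers <- c("deep", "middle", "superficial")
rows <- list()
for (roi in names(bundle$laminar$contrasts)) {
  SS <- bundle$laminar$contrasts[[roi]]$SS
  gm <- colMeans(SS)
  long <- data.frame(subject = rep(seq_len(nrow(SS)), 3),
                     depth = rep(layers, each = nrow(SS)),
                     SS = as.numeric(SS))
  av <- suppressWarnings(rm_anova(long, "SS", "depth"))
  cat(sprintf("%-3s  SS by depth: %s  peak: %s  F(%d,%d) = %.3f, p = %.3g\n",
              roi, paste(sprintf("%s %.3f", layers, gm), collapse = ", "),
              layers[which.max(gm)], av$df1, av$df2, av$F, av$p))
  rows[[roi]] <- data.frame(roi = roi, depth = layers, mean_SS = gm,
                            F = av$F, df1 = av$df1, df2 = av$df2, p = av$p)
}
write.csv(do.call(rbind, rows), "results/laminar_stats.csv", row.names = FALSE)
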