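#!/usr/bin/env Rscript
# Stage 5: visual-field reconstruction of the saliency signal.
#
# Node responses are back-projected through corrected pRFs (localizer peak
# mapped to the stimulus location at polar angle 127.88 deg, eccentricity
# 4.28 deg) and summed per cortical depth; maps share one normalization
# across depths and are averaged over subjects.

suppressPackageStartupMessages(library(lamsal))
bundle <- readRDS("results/bundle.rds")

fm <- bundle$retinotopy$group_map
target <- lamsal:::prf_center_xy(127.88, 4.28, "left")
for (depth in names(fm$maps)) {
  m <- fm$maps[[depth]]
  peak <- which(m == max(m), arr.ind = TRUE)[1, ]
  cat(sprintf("%-11s map max %.3f at (%.1f, %.1f) deg  [stimulus at (%.1f, %.1f)]\n",
              depth, max(m), fm$grid$x[peak[2]], fm$grid$y[peak[1]],
              target$x, target$y))
  write.csv(m, sprintf("results/fieldmap_%s.csv", depth), row.names = FALSE)
}
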