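#!/usr/bin/env Rscript
# Stage 4: layer-dependent effective connectivity (gPPI without
# deconvolution).
#
# Feedforward pathway: V1 superficial seed -> IPS middle target; feedback:
# IPS deep -> V1 deep. Per subject and hemisphere the PPI betas of the three
# conditions were estimated and averaged over hemispheres; the saliency-
# dependent connectivity is the 90-minus-15 PPI beta difference.

suppressPackageStartupMessages(library(lamsal))
bundle <- readRDS("results/bundle.rds")

dff <- bundle$connectivity$delta_ff
dfb <- bundle$connectivity$delta_fb
t_ff <- paired_t(dff, rep(0, length(dff)))
t_fb <- paired_t(dfb, rep(0, length(dfb)))
p_holm <- holm_correct(c(ff = t_ff$p, fb = t_fb$p))
tt <- paired_t(dff, dfb)

cat(sprintf("feedforward delta: mean %.3f, t(%d) = %.3f, p_holm = %.3g\n",
            mean(dff), t_ff$df, t_ff$t, p_holm["ff"]))
cat(sprintf("feedback    delta: mean %.3f, t(%d) = %.3f, p_holm = %.3g\n",
            mean(dfb), t_fb$df, t_fb$t, p_holm["fb"]))
cat(sprintf("feedforward vs feedback: t(%d) = %.3f, p = %.3g\n", tt$df, tt$t, tt$p))

write.csv(data.frame(quantity = c("mean_delta_ff", "mean_delta_fb",
                                  "t_ff", "p_ff_holm", "t_fb", "p_fb_holm",
                                  "t_ff_vs_fb", "p_ff_vs_fb"),
                     value = c(mean(dff), mean(dfb), t_ff$t, p_holm["ff"],
                               t_fb$t, p_holm["fb"], tt$t, tt$p)),
          "results/connectivity_stats.csv", row.names = FALSE)
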