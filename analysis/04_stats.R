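#!/usr/bin/env Rscript
# Stage 4 - statistics.
#
# Runs the study's statistical layer over the per-mouse densities: cube-
# root variance-stabilizing transform, factorial ANOVA (region x TAM
# class) with all pairwise post-hoc linear contrasts, and the two-stage
# Benjamini-Krieger-Yekutieli FDR at q < 0.05.

library(tamscape)

cfg <- run_config(overrides = list(out_dir = "results"))
sim <- run_simulate(cfg)
qc <- run_quantify(cfg, sim)
st <- run_stats(cfg, qc)

cat("ANOVA (", cfg$stats$transform, "-transformed densities):\n", sep = "")
print(st$anova)
sig <- st$contrasts[st$contrasts$significant, c("contrast", "estimate",
                                                "p", "q_adjusted")]
cat("\n", nrow(sig), "of", nrow(st$contrasts),
    "contrasts significant at q < 0.05:\n")
print(sig, digits = 3, row.names = FALSE)
cat("Wrote stats_contrasts.csv\n")
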