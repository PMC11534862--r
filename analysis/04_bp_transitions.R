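#!/usr/bin/env Rscript
# Stage 4: clinical blood-pressure arm.
#
# Paired pre/post comparison per class and component, guideline
# categorization (normal < 130/85, high-normal 130-139/85-89,
# hypertension >= 140/90 mmHg) and the Sankey-ready category transition
# matrices, per class and combined.

suppressMessages(library(vegfpv))

records <- read_bp_csv("results/synthetic/bp_records.csv")
cfg <- default_run_config()
cfg$seed <- 20240101L

res <- run_bp(records, out_dir = "results/bp", cfg = cfg)
cat("paired pre/post summaries:\n")
print(as.data.frame(res$summary))
cat("\ncombined transition matrix:\n")
print(unclass(res$matrices$combined))
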