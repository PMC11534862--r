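#!/usr/bin/env Rscript
# Stage 2: disproportionality signal detection.
#
# Reads the simulated reports, runs the preprocessing chain
# (deduplication, malignancy filter, class assignment) and computes the
# per-drug/class x per-PT ROR/IC signal table with the three-part signal
# criterion (a >= 3, ROR CI lower bound > 1, IC025 > 0).

suppressMessages(library(vegfpv))

rs <- read_simple_csv("results/synthetic/reports.csv")
cfg <- default_run_config()
cfg$seed <- 20240101L

st <- run_signals(rs, out_dir = "results/signals", cfg = cfg)
cat("signal table:", nrow(st), "drug x PT pairs,",
    sum(st$is_signal), "flagged signals\n")
cls <- st[st$drug %in% c("VEGFi", "VEGFRi") & st$pt_group == "Hypertension", ]
print(as.data.frame(cls[, c("drug", "pt_group", "a", "ror", "ci_low",
                            "ci_high", "ic", "ic025", "is_signal")]))
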