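#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emits every input the downstream stages consume, in the same formats a
# real analysis would use: the simplified report CSV, the clinical BP
# CSV, and the expression matrix with its GMT gene sets, cancer-type
# sidecar and per-cancer ROR table. All stages share one seed.

suppressMessages(library(vegfpv))

seed <- 20240101L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_reports(faers_sim_config(n_reports = 20000, seed = seed))
write_simple_csv(sim$reports, file.path(out, "reports.csv"))
jsonlite::write_json(
  sim$truth[c("n_injected_duplicates", "n_retained", "n_malignant",
              "n_missing_dates")],
  file.path(out, "reports_truth.json"), auto_unbox = TRUE, pretty = TRUE)
cat("reports:", length(sim$reports), "written;",
    sim$truth$n_injected_duplicates, "injected duplicates,",
    sim$truth$n_malignant, "malignant indications\n")

clin <- simulate_clinical(clinical_sim_config(seed = seed))
readr::write_csv(clin$records, file.path(out, "bp_records.csv"))
cat("clinical cohort:", nrow(clin$records), "patients\n")

expr <- simulate_expression(expression_sim_config(seed = seed))
mat <- tibble::as_tibble(expr$matrix$values, rownames = "gene")
readr::write_csv(mat, file.path(out, "expression_fpkm.csv"))
readr::write_csv(tibble::tibble(sample = colnames(expr$matrix$values),
                                cancer_type = unname(expr$matrix$cancer_type)),
                 file.path(out, "expression_samples.csv"))
write_gmt(expr$gene_sets, file.path(out, "gene_sets.gmt"))
readr::write_csv(expr$rors, file.path(out, "per_cancer_ror.csv"))
cat("expression:", nrow(mat), "genes x", ncol(mat) - 1, "samples;",
    length(expr$gene_sets), "planted gene sets\n")
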