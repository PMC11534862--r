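# End-to-end stage runners chaining the modules on synthetic or user
# data. Each stage writes its plot-ready tables plus a machine-readable
# manifest (config hash, seed, package version) to the output directory;
# two runs with identical configs produce identical files.

write_manifest <- function(out_dir, stage, cfg, seed) {
  manifest <- list(
    stage = stage,
    seed = seed,
    config_hash = rlang::hash(cfg),
    package = "vegfpv",
    version = as.character(utils::packageVersion("vegfpv"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

preprocess_reports <- function(rs, cfg) {
  rs |>
    deduplicate() |>
    filter_malignancy(terms = cfg$malignancy_terms) |>
    assign_class(catalog = cfg$drug_catalog,
                 primary_suspect_only = cfg$primary_suspect_only)
}

#' Run the disproportionality signal stage
#'
#' Preprocesses the reports (deduplication, malignancy filter, class
#' assignment), computes the per-drug/class x per-PT signal table and
#' writes `signals.csv`, the heatmap-ready `signals_ror_pivot.csv`, a
#' JSON summary, the stage log of per-filter counts, and a manifest.
#'
#' @param rs A `report_set`; if `NULL`, data are simulated from `sim_cfg`.
#' @param out_dir Output directory (created if needed).
#' @param cfg A run configuration, see [default_run_config()].
#' @param sim_cfg A [faers_sim_config()] used when `rs` is `NULL`.
#' @return The signal table, invisibly.
#' @export
run_signals <- function(rs = NULL, out_dir, cfg = default_run_config(),
                        sim_cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(rs)) {
    if (is.null(sim_cfg)) sim_cfg <- faers_sim_config(seed = cfg$seed)
    rs <- simulate_reports(sim_cfg)$reports
  }
  rs <- preprocess_reports(rs, cfg)

  catalog_drugs <- intersect(c(default_vegfi(), default_vegfri()),
                             unique(rs$reports$drug_name))
  drugs <- c("VEGFi", "VEGFRi", catalog_drugs)
  pts_present <- unique(unlist(rs$reports$reactions))
  bp_pts <- intersect(cfg$pt_catalog$bp_related, pts_present)
  if (length(bp_pts) == 0) stop("no blood-pressure PT present in the data")

  st <- signal_table(rs, drugs = drugs, pt_groups = bp_pts,
                     literal_ic = cfg$literal_ic)
  readr::write_csv(st, file.path(out_dir, "signals.csv"), progress = FALSE)
  readr::write_csv(signal_pivot(st, "ror"),
                   file.path(out_dir, "signals_ror_pivot.csv"),
                   progress = FALSE)
  readr::write_csv(rs$log, file.path(out_dir, "signals_filter_log.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(n_reports = nrow(rs$reports), n_pairs = nrow(st),
         n_signals = sum(st$is_signal)),
    file.path(out_dir, "signals_summary.json"), auto_unbox = TRUE)
  write_manifest(out_dir, "signals", cfg, cfg$seed)
  invisible(st)
}

#' Run the time-to-onset stage
#'
#' Extracts onset records for the blood-pressure PTs, writes per-class
#' and per-drug median/IQR summaries, ECDF long tables and the pairwise
#' drug p-value matrix.
#'
#' @inheritParams run_signals
#' @return A list of the stage tables, invisibly.
#' @export
run_tto <- function(rs = NULL, out_dir, cfg = default_run_config(),
                    sim_cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(rs)) {
    if (is.null(sim_cfg)) sim_cfg <- faers_sim_config(seed = cfg$seed)
    rs <- simulate_reports(sim_cfg)$reports
  }
  rs <- preprocess_reports(rs, cfg)
  rec <- extract_tto(rs, pts = cfg$pt_catalog$bp_related)

  by_class <- summarize_tto(rec[rec$drug_class %in% c("VEGFi", "VEGFRi"), ],
                            group_by = "class")
  by_drug <- summarize_tto(rec[rec$drug_class %in% c("VEGFi", "VEGFRi"), ],
                           group_by = "drug")
  ecdfs <- dplyr::bind_rows(lapply(
    c("VEGFi", "VEGFRi"),
    function(cl) ecdf_curve(rec$tto_days[rec$drug_class == cl], group = cl)))

  drugs_with_n <- names(which(table(rec$drug_name[
    rec$drug_class %in% c("VEGFi", "VEGFRi")]) >= 2))
  pmat <- if (length(drugs_with_n) >= 2) {
    pairwise_drug_comparison(rec, drugs = drugs_with_n,
                             holm_adjust = cfg$holm_adjust)
  } else NULL

  readr::write_csv(by_class, file.path(out_dir, "tto_by_class.csv"),
                   progress = FALSE)
  readr::write_csv(by_drug, file.path(out_dir, "tto_by_drug.csv"),
                   progress = FALSE)
  readr::write_csv(ecdfs, file.path(out_dir, "tto_ecdf.csv"),
                   progress = FALSE)
  if (!is.null(pmat)) {
    readr::write_csv(tibble::as_tibble(pmat, rownames = "drug"),
                     file.path(out_dir, "tto_pairwise_p.csv"),
                     progress = FALSE)
  }
  write_manifest(out_dir, "tto", cfg, cfg$seed)
  invisible(list(by_class = by_class, by_drug = by_drug, ecdf = ecdfs,
                 pairwise = pmat))
}

#' Run the clinical blood-pressure stage
#'
#' Per class: paired pre/post comparison for both pressure components
#' and the category transition matrix; the per-class matrices are then
#' combined. Writes the summary CSV and the Sankey-ready long transition
#' tables.
#'
#' @param records A `bp_records` tibble; if `NULL`, simulated from
#'   `sim_cfg`.
#' @inheritParams run_signals
#' @param sim_cfg A [clinical_sim_config()] used when `records` is `NULL`.
#' @return A list with the summary table and transition matrices,
#'   invisibly.
#' @export
run_bp <- function(records = NULL, out_dir, cfg = default_run_config(),
                   sim_cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(records)) {
    if (is.null(sim_cfg)) sim_cfg <- clinical_sim_config(seed = cfg$seed)
    records <- simulate_clinical(sim_cfg)$records
  }
  classes <- sort(unique(records$drug_class))
  method <- if (cfg$paired_test == "t") "t" else "wilcoxon"

  summary_rows <- list()
  matrices <- list()
  for (cl in classes) {
    cohort <- records[records$drug_class == cl, ]
    for (comp in c("sbp", "dbp")) {
      r <- paired_pre_post_test(cohort, component = comp, method = method)
      summary_rows[[paste(cl, comp)]] <- tibble::tibble(
        cohort = cl, component = comp, n = r$n,
        median_pre = r$median_pre, iqr_pre_low = r$iqr_pre[1],
        iqr_pre_high = r$iqr_pre[2], median_post = r$median_post,
        iqr_post_low = r$iqr_post[1], iqr_post_high = r$iqr_post[2],
        median_shift = r$median_shift, p_value = r$p_value)
    }
    matrices[[cl]] <- transition_matrix(cohort, label = cl)
  }
  combined <- combine_matrices(matrices, label = "combined")
  matrices$combined <- combined

  summary_tab <- dplyr::bind_rows(summary_rows)
  readr::write_csv(summary_tab, file.path(out_dir, "bp_summary.csv"),
                   progress = FALSE)
  trans_long <- dplyr::bind_rows(lapply(names(matrices), function(nm) {
    out <- transition_long(matrices[[nm]])
    out$cohort <- nm
    out[, c("cohort", "pre_cat", "post_cat", "count")]
  }))
  readr::write_csv(trans_long, file.path(out_dir, "bp_transitions.csv"),
                   progress = FALSE)
  write_manifest(out_dir, "bp", cfg, cfg$seed)
  invisible(list(summary = summary_tab, matrices = matrices))
}

#' Run the pan-cancer enrichment stage
#'
#' FPKM -> TPM conversion, ssGSEA scoring, per-cancer aggregation, and
#' Spearman correlation of pathway activity with the per-cancer ROR.
#' Writes the per-cancer score table and the correlation results.
#'
#' @param expr An `expression_matrix` (FPKM); `gene_sets` a named list of
#'   `gene_set`; `rors` a tibble (cancer_type, ror). If `expr` is `NULL`
#'   all three are simulated from `sim_cfg`.
#' @inheritParams run_signals
#' @param gene_sets,rors See `expr`.
#' @param sim_cfg An [expression_sim_config()] used when `expr` is `NULL`.
#' @return A list with the score and correlation tables, invisibly.
#' @export
run_pancancer <- function(expr = NULL, gene_sets = NULL, rors = NULL,
                          out_dir, cfg = default_run_config(),
                          sim_cfg = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(expr)) {
    if (is.null(sim_cfg)) sim_cfg <- expression_sim_config(seed = cfg$seed)
    sim <- simulate_expression(sim_cfg)
    expr <- sim$matrix
    gene_sets <- sim$gene_sets
    rors <- sim$rors
  }
  tpm <- if (expr$scale == "FPKM") fpkm_to_tpm(expr) else expr
  scores <- ssgsea_score(tpm, gene_sets, alpha = cfg$alpha)
  per_cancer <- per_cancer_pathway_score(scores)
  corr <- correlate_with_ror(per_cancer, rors)

  readr::write_csv(per_cancer, file.path(out_dir, "pancancer_scores.csv"),
                   progress = FALSE)
  readr::write_csv(corr, file.path(out_dir, "pancancer_correlations.csv"),
                   progress = FALSE)
  write_manifest(out_dir, "pancancer", cfg, cfg$seed)
  invisible(list(scores = per_cancer, correlations = corr))
}

#' Run every stage end to end on synthetic data
#'
#' @param out_dir Output directory; stage files are written beneath it.
#' @param cfg A run configuration (its `seed` drives all generators).
#' @return A named list of the stage results, invisibly.
#' @export
run_paper_pipeline <- function(out_dir, cfg = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- faers_sim_config(seed = cfg$seed)
  sim <- simulate_reports(sim_cfg)
  res <- list(
    signals = run_signals(sim$reports, out_dir = out_dir, cfg = cfg),
    tto = run_tto(sim$reports, out_dir = out_dir, cfg = cfg),
    bp = run_bp(NULL, out_dir = out_dir, cfg = cfg),
    pancancer = run_pancancer(NULL, out_dir = out_dir, cfg = cfg)
  )
  invisible(res)
}
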