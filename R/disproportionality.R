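#' 2x2 contingency table for disproportionality analysis
#'
#' Cell `a` counts reports with the target drug (or class) and the target
#' event, `b` the target drug with other events, `c` other drugs with the
#' target event, and `d` the remainder; `N = a + b + c + d`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("contingency table is all zero")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), N = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      " N=", x$N, "\n", sep = "")
  invisible(x)
}

#' Build the drug x event contingency table from a report set
#'
#' A report falls in the exposed margin when its drug name or annotated
#' drug class is in `target_drugs`, and in the event margin when any of
#' its reaction PTs is in `target_pts`.
#'
#' @param rs A preprocessed `report_set`.
#' @param target_drugs Character vector of drug names and/or class labels
#'   (`"VEGFi"`, `"VEGFRi"`).
#' @param target_pts Character vector of event PTs.
#' @return A `contingency_table` with `a + b + c + d == length(rs)`.
#' @export
build_contingency <- function(rs, target_drugs, target_pts) {
  stopifnot(inherits(rs, "report_set"))
  if (nrow(rs$reports) == 0) stop("report set is empty")
  drug_hit <- rs$reports$drug_name %in% target_drugs
  if ("drug_class" %in% names(rs$reports)) {
    drug_hit <- drug_hit | rs$reports$drug_class %in% target_drugs
  }
  pt_hit <- vapply(rs$reports$reactions,
                   function(x) any(x %in% target_pts), logical(1))
  contingency_table(
    a = sum(drug_hit & pt_hit),
    b = sum(drug_hit & !pt_hit),
    c = sum(!drug_hit & pt_hit),
    d = sum(!drug_hit & !pt_hit)
  )
}

#' Vectorized disproportionality statistics
#'
#' The core computation shared by [ror_with_ci()], [ic_with_ic025()] and
#' [signal_table()], operating on parallel vectors of cell counts.
#' Zero-cell policy: with any zero cell, CI / IC / IC025 come from the
#' Haldane-Anscombe +0.5-corrected table; the ROR point estimate is the
#' raw 0 when `a == 0` (the convention of reporting ROR = 0 for an
#' unobserved drug-event pair) and the corrected ratio otherwise.
#'
#' @param a,b,c,d Non-negative integer vectors of equal length.
#' @param z Normal quantile (default 1.96).
#' @param literal_ic Use the league-table IC denominator variant.
#' @return A tibble with columns a, b, c, d, ror, ci_low, ci_high, ic,
#'   ic025, zero_cell_policy_used.
#' @export
disprop_stats <- function(a, b, c, d, z = 1.96, literal_ic = FALSE) {
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a))
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  ca <- a + 0.5 * zero
  cb <- b + 0.5 * zero
  cc <- c + 0.5 * zero
  cd <- d + 0.5 * zero
  n <- ca + cb + cc + cd
  se <- sqrt(1 / ca + 1 / cb + 1 / cc + 1 / cd)

  ror_corr <- (ca * cd) / (cb * cc)
  ror <- ifelse(zero, ifelse(a == 0, 0, ror_corr), (a * d) / (b * c))
  ci_low <- exp(log(ror_corr) - z * se)
  ci_high <- exp(log(ror_corr) + z * se)

  ic <- if (literal_ic) {
    # the league-table expression as printed: log2( a*N / (a+b) / (c+d) )
    log2(ca * n / (ca + cb) / (cc + cd))
  } else {
    # observed / expected under row-column independence
    log2(ca * n / ((ca + cb) * (ca + cc)))
  }
  ic025 <- ic - z * se

  tibble::tibble(a = a, b = b, c = c, d = d, ror = ror,
                 ci_low = ci_low, ci_high = ci_high, ic = ic, ic025 = ic025,
                 zero_cell_policy_used = ifelse(zero, "haldane_anscombe_0.5",
                                                "none"))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a/c)/(b/d) = ad/(bc)`; the Woolf interval is
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z = 1.96`.
#' With a zero cell the interval is computed on a +0.5-corrected table;
#' the point estimate for `a = 0` is reported as 0.
#'
#' @param t A `contingency_table`.
#' @param z Normal quantile for the interval (default 1.96).
#' @return A list with `ror`, `ci_low`, `ci_high`, `zero_cell_policy_used`.
#' @export
ror_with_ci <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_table"))
  s <- disprop_stats(t$a, t$b, t$c, t$d, z = z)
  list(ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
       zero_cell_policy_used = s$zero_cell_policy_used)
}

#' Information component with its lower bound
#'
#' `IC = log2( a N / ((a+b)(a+c)) )`, the log2 ratio of the observed
#' co-reporting count to the count expected under independence; the lower
#' bound is `IC025 = IC - 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)` on the log2
#' scale. `literal_ic = TRUE` instead evaluates the league-table variant
#' `log2( a N / (a+b) / (c+d) )` for auditability; see the package
#' vignette for why the expected-count form is the default.
#'
#' @inheritParams ror_with_ci
#' @param literal_ic Use the league-table variant of the IC denominator.
#' @return A list with `ic`, `ic025`, `zero_cell_policy_used`.
#' @export
ic_with_ic025 <- function(t, z = 1.96, literal_ic = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  s <- disprop_stats(t$a, t$b, t$c, t$d, z = z, literal_ic = literal_ic)
  list(ic = s$ic, ic025 = s$ic025,
       zero_cell_policy_used = s$zero_cell_policy_used)
}

#' Compute the full signal result for one contingency table
#'
#' @inheritParams ic_with_ic025
#' @return An object of class `signal_result`: the table plus `ror`,
#'   `ci_low`, `ci_high`, `ic`, `ic025`, `z`, `is_signal` and the
#'   zero-cell policy used.
#' @export
signal_stats <- function(t, z = 1.96, literal_ic = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  s <- disprop_stats(t$a, t$b, t$c, t$d, z = z, literal_ic = literal_ic)
  res <- structure(
    list(table = t, ror = s$ror, ror_ci_low = s$ci_low,
         ror_ci_high = s$ci_high, ic = s$ic, ic025 = s$ic025, z = z,
         zero_cell_policy_used = s$zero_cell_policy_used,
         is_signal = NA),
    class = "signal_result"
  )
  res$is_signal <- flag_signal(res)
  res
}

#' The three-part disproportionality signal criterion
#'
#' A drug-event pair is a signal when the co-reporting count is at least
#' `min_a` (default 3) AND the lower 95% CI bound of the ROR exceeds 1
#' AND IC025 exceeds 0 — strict inequalities on both bounds.
#'
#' @param r A `signal_result` (or any list with `table$a`, `ror_ci_low`,
#'   `ic025`).
#' @param min_a Minimum co-reporting count.
#' @return Logical.
#' @export
flag_signal <- function(r, min_a = 3) {
  (r$table$a >= min_a) & (r$ror_ci_low > 1) & (r$ic025 > 0)
}

#' Per-drug x per-PT-group signal table
#'
#' Runs the full contingency -> ROR/CI -> IC/IC025 -> signal pipeline for
#' every (drug-or-class, PT-group) pair and returns one long-format row
#' per pair, ordered lexicographically by drug then PT group.
#'
#' @param rs A preprocessed `report_set`.
#' @param drugs Character vector of drug names and/or class labels.
#' @param pt_groups Named list of character PT vectors (a bare character
#'   vector is treated as one single-PT group per element).
#' @param z,literal_ic Passed to the statistic computations.
#' @param min_a Signal-criterion minimum count.
#' @return A tibble with columns drug, pt_group, a, b, c, d, ror, ci_low,
#'   ci_high, ic, ic025, is_signal, zero_cell_policy_used.
#' @export
signal_table <- function(rs, drugs, pt_groups, z = 1.96, literal_ic = FALSE,
                         min_a = 3) {
  stopifnot(inherits(rs, "report_set"))
  if (length(drugs) == 0 || length(pt_groups) == 0) {
    stop("drugs and pt_groups must be non-empty")
  }
  if (!is.list(pt_groups)) {
    pt_groups <- setNames(as.list(pt_groups), pt_groups)
  }
  if (is.null(names(pt_groups)) || any(!nzchar(names(pt_groups)))) {
    stop("pt_groups must be named")
  }
  drugs <- sort(unique(drugs))
  groups <- sort(names(pt_groups))

  grid <- expand.grid(pt_group = groups, drug = drugs,
                      stringsAsFactors = FALSE)[, c("drug", "pt_group")]
  cells <- mapply(function(dg, gp) {
    t <- build_contingency(rs, dg, pt_groups[[gp]])
    c(t$a, t$b, t$c, t$d)
  }, grid$drug, grid$pt_group, USE.NAMES = FALSE)
  s <- disprop_stats(cells[1, ], cells[2, ], cells[3, ], cells[4, ], z = z,
                     literal_ic = literal_ic)
  out <- dplyr::bind_cols(tibble::as_tibble(grid), s)
  out$is_signal <- (out$a >= min_a) & (out$ci_low > 1) & (out$ic025 > 0)
  out
}

#' Pivot a long signal table to a heatmap-ready wide matrix
#'
#' @param st A tibble from [signal_table()].
#' @param value Column to pivot (default `"ror"`).
#' @return A tibble, drugs in rows, PT groups in columns.
#' @export
signal_pivot <- function(st, value = "ror") {
  tidyr::pivot_wider(st[, c("drug", "pt_group", value)],
                     names_from = "pt_group",
                     values_from = dplyr::all_of(value))
}

#' Per-cancer-type reporting odds ratio
#'
#' Stratifies the report set by an indication-derived cancer type and
#' computes, within each stratum, the ROR of the target event for the
#' target drugs versus all other drugs in the stratum. Strata whose
#' exposed-case count `a` falls below `min_cases` are omitted from the
#' result and listed in the `excluded` attribute.
#'
#' @param rs A preprocessed `report_set`.
#' @param cancer_label Named character vector mapping indication strings
#'   to cancer-type labels; unmapped indications are dropped.
#' @param target_drugs Drug names/classes defining the exposed margin
#'   (default both inhibitor classes).
#' @param target_pts Event PTs (default the hypertension-related PT set).
#' @param min_cases Minimum `a` for a stratum to be reported (default 5;
#'   "fewer than `min_cases`" is strict, so `a == min_cases` is kept).
#' @param z,literal_ic Passed through to the statistics.
#' @return A tibble (cancer_type, a, b, c, d, ror, ci_low, ci_high, ic,
#'   ic025) with attribute `excluded` naming the omitted strata.
#' @export
per_cancer_ror <- function(rs, cancer_label,
                           target_drugs = c("VEGFi", "VEGFRi"),
                           target_pts = default_hypertension_pts(),
                           min_cases = 5, z = 1.96, literal_ic = FALSE) {
  stopifnot(inherits(rs, "report_set"), min_cases >= 1)
  ctype <- unname(cancer_label[rs$reports$indication])
  keep <- !is.na(ctype)
  reports <- rs$reports[keep, ]
  ctype <- ctype[keep]

  drug_hit <- reports$drug_name %in% target_drugs
  if ("drug_class" %in% names(reports)) {
    drug_hit <- drug_hit | reports$drug_class %in% target_drugs
  }
  pt_hit <- vapply(reports$reactions, function(x) any(x %in% target_pts),
                   logical(1))

  per_type <- tibble::tibble(cancer_type = ctype, drug_hit = drug_hit,
                             pt_hit = pt_hit) |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      a = sum(.data$drug_hit & .data$pt_hit),
      b = sum(.data$drug_hit & !.data$pt_hit),
      c = sum(!.data$drug_hit & .data$pt_hit),
      d = sum(!.data$drug_hit & !.data$pt_hit),
      .groups = "drop") |>
    dplyr::arrange(.data$cancer_type)

  excluded <- per_type$cancer_type[per_type$a < min_cases]
  kept <- per_type[per_type$a >= min_cases, ]
  s <- disprop_stats(kept$a, kept$b, kept$c, kept$d, z = z,
                     literal_ic = literal_ic)
  out <- dplyr::bind_cols(kept["cancer_type"], s)
  attr(out, "excluded") <- excluded
  out
}
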