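#' Extract time-to-onset records from a report set
#'
#' Time to onset (TTO) is the whole-day difference between the event date
#' and the first therapy start date. One record is produced per report x
#' matching PT when both dates are present; reports with a missing date
#' or a negative difference are excluded and counted in the attributes
#' `n_missing_dates` and `n_negative`. Same-day onset (0 days) is kept.
#'
#' @param rs A preprocessed `report_set` (with `drug_class` if grouping
#'   by class is wanted downstream).
#' @param pts Character vector of event PTs to match.
#' @return A tibble (report_id, drug_name, drug_class, pt, tto_days).
#' @export
extract_tto <- function(rs, pts) {
  stopifnot(inherits(rs, "report_set"))
  r <- rs$reports
  if (!"drug_class" %in% names(r)) r$drug_class <- NA_character_
  hits <- lapply(r$reactions, function(x) x[x %in% pts])
  n_hit <- lengths(hits)
  idx <- rep(seq_len(nrow(r)), n_hit)
  rec <- tibble::tibble(
    report_id = r$report_id[idx],
    drug_name = r$drug_name[idx],
    drug_class = r$drug_class[idx],
    pt = unlist(hits),
    tto_days = as.numeric(r$event_date[idx] - r$therapy_start_date[idx])
  )
  missing <- is.na(rec$tto_days)
  negative <- !missing & rec$tto_days < 0
  out <- rec[!missing & !negative, ]
  attr(out, "n_missing_dates") <- sum(missing)
  attr(out, "n_negative") <- sum(negative)
  out
}

#' Median and interquartile range of onset time per group
#'
#' Quantiles use the linear-interpolation convention between order
#' statistics (`stats::quantile` type 7). Empty groups are omitted with
#' a warning.
#'
#' @param records Tibble from [extract_tto()].
#' @param group_by `"class"` or `"drug"`.
#' @return A tibble (group, n, median_days, iqr_low, iqr_high).
#' @export
summarize_tto <- function(records, group_by = c("class", "drug")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "class") records$drug_class else records$drug_name
  keep <- !is.na(key)
  if (any(!keep)) warning(sum(!keep), " record(s) without a group label omitted")
  tibble::tibble(group = key[keep], tto_days = records$tto_days[keep]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_days = median(.data$tto_days),
      iqr_low = quantile(.data$tto_days, 0.25, type = 7, names = FALSE),
      iqr_high = quantile(.data$tto_days, 0.75, type = 7, names = FALSE),
      .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Empirical CDF of onset times for one group
#'
#' @param values Numeric vector of onset times (or a tibble from
#'   [extract_tto()], in which case `tto_days` is used).
#' @param group Label attached to the output rows.
#' @return A tibble (group, t, F): the right-continuous step function
#'   evaluated at the distinct values, with `F` reaching 1 at the maximum.
#' @export
ecdf_curve <- function(values, group = "all") {
  if (is.data.frame(values)) values <- values$tto_days
  if (length(values) == 0) stop("group is empty")
  tab <- table(values)
  t <- as.numeric(names(tab))
  tibble::tibble(group = group, t = t,
                 F = cumsum(as.numeric(tab)) / length(values))
}

mann_whitney_u <- function(x, y) {
  # U for x = #{x_i > y_j} + 0.5 * #{ties}; computed from pooled ranks
  n1 <- length(x)
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Reports the U statistic for `x` (number of pairs with `x > y`, ties
#' counting one half) and a two-sided p-value: exact enumeration of all
#' assignments of the pooled values to the two groups when that
#' enumeration is small (covers any design with a group below 8), and
#' the tie-corrected normal approximation otherwise. Two identical
#' samples give p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param max_enumeration Largest `choose(n1+n2, n1)` for the exact path.
#' @return A list with `U`, `p_value` and `method`.
#' @export
compare_groups <- function(x, y, max_enumeration = 1e5) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  u <- mann_whitney_u(x, y)
  mu <- n1 * n2 / 2

  if (choose(n1 + n2, n1) <= max_enumeration) {
    pooled <- c(x, y)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) mann_whitney_u(pooled[i], pooled[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(U = u, p_value = p, method = "exact_enumeration"))
  }

  pooled <- c(x, y)
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = u, p_value = 1, method = "normal_approx"))
  }
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * pnorm(-abs(z))),
       method = "normal_approx")
}

#' Pairwise onset-time comparisons between drugs
#'
#' All unordered drug pairs are compared with [compare_groups()]; the
#' diagonal is 1. Raw p-values are reported by default, matching common
#' pharmacovigilance practice; Holm adjustment is available by flag.
#'
#' @param records Tibble from [extract_tto()].
#' @param drugs Drugs to include (default: all with at least one record).
#' @param holm_adjust Apply Holm correction across the pairs.
#' @return A symmetric matrix of p-values with drug names as dimnames.
#' @export
pairwise_drug_comparison <- function(records, drugs = NULL,
                                     holm_adjust = FALSE) {
  if (is.null(drugs)) drugs <- sort(unique(records$drug_name))
  drugs <- drugs[drugs %in% records$drug_name]
  if (length(drugs) < 2) stop("need at least two drugs with records")
  groups <- split(records$tto_days, factor(records$drug_name, levels = drugs))
  k <- length(drugs)
  p <- matrix(1, k, k, dimnames = list(drugs, drugs))
  pairs <- combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    compare_groups(groups[[ij[1]]], groups[[ij[2]]])$p_value
  })
  if (holm_adjust) raw <- stats::p.adjust(raw, method = "holm")
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1, j], pairs[2, j]] <- raw[j]
    p[pairs[2, j], pairs[1, j]] <- raw[j]
  }
  p
}
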