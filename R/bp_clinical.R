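bp_category_levels <- c("normal", "high_normal", "hypertension")

#' Construct a clinical blood-pressure cohort
#'
#' One row per patient with the maximum systolic and corresponding
#' diastolic pressure recorded before and after the first dose. Values
#' must lie in the (30, 300) mmHg plausibility window and systolic must
#' exceed diastolic at each timepoint.
#'
#' @param df Data frame with columns patient_id, drug_class, sbp_pre,
#'   dbp_pre, sbp_post, dbp_post.
#' @return A tibble of class `bp_records`.
#' @export
bp_records <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("patient_id", "drug_class", "sbp_pre", "dbp_pre",
              "sbp_post", "dbp_post")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("bp_records is missing column(s): ", paste(missing, collapse = ", "))
  }
  press <- as.matrix(df[, c("sbp_pre", "dbp_pre", "sbp_post", "dbp_post")])
  if (any(is.na(press)) || any(press <= 30) || any(press >= 300)) {
    stop("blood pressures must lie in the (30, 300) mmHg plausibility window")
  }
  if (any(df$sbp_pre <= df$dbp_pre) || any(df$sbp_post <= df$dbp_post)) {
    stop("systolic pressure must exceed diastolic at each timepoint")
  }
  class(df) <- c("bp_records", class(df))
  df
}

#' @rdname bp_records
#' @param path CSV file with the `bp_records` columns.
#' @export
read_bp_csv <- function(path) {
  bp_records(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    drug_class = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
}

#' Categorize a blood pressure reading
#'
#' Applies the European guideline cutpoints: normal below 130/85 mmHg,
#' high-normal at 130-139 or 85-89 mmHg, hypertension at or above 140/90
#' mmHg. A reading is assigned the higher of its systolic-implied and
#' diastolic-implied categories, so hypertension holds iff `sbp >= 140`
#' or `dbp >= 90`, and high-normal iff `sbp >= 130` or `dbp >= 85`
#' otherwise.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg (vectorized).
#' @return An ordered factor with levels normal < high_normal <
#'   hypertension.
#' @export
bp_categorize <- function(sbp, dbp) {
  if (any(sbp <= 30 | sbp >= 300 | dbp <= 30 | dbp >= 300)) {
    stop("pressure outside the (30, 300) mmHg plausibility window")
  }
  cat <- ifelse(sbp >= 140 | dbp >= 90, "hypertension",
                ifelse(sbp >= 130 | dbp >= 85, "high_normal", "normal"))
  factor(cat, levels = bp_category_levels, ordered = TRUE)
}

#' Paired pre/post blood-pressure comparison for one cohort
#'
#' Wilcoxon signed-rank test on the post - pre differences of the chosen
#' component (paired t-test available via `method = "t"`), with pre and
#' post medians and IQRs. All-zero differences give p = 1.
#'
#' @param cohort A `bp_records` tibble (already restricted to the cohort
#'   of interest).
#' @param component `"sbp"` or `"dbp"`.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return A list with `statistic`, `p_value`, `n`, `median_pre`,
#'   `iqr_pre`, `median_post`, `iqr_post`, `median_shift`, `method`.
#' @export
paired_pre_post_test <- function(cohort, component = c("sbp", "dbp"),
                                 method = c("wilcoxon", "t")) {
  component <- match.arg(component)
  method <- match.arg(method)
  pre <- cohort[[paste0(component, "_pre")]]
  post <- cohort[[paste0(component, "_post")]]
  if (length(pre) < 2) stop("cohort must contain at least 2 patients")
  diffs <- post - pre
  if (all(diffs == 0)) {
    stat <- 0
    p <- 1
  } else if (method == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                       exact = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- t.test(post, pre, paired = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  q <- function(v, probs) quantile(v, probs, type = 7, names = FALSE)
  list(statistic = stat, p_value = p, n = length(pre),
       median_pre = median(pre), iqr_pre = q(pre, c(0.25, 0.75)),
       median_post = median(post), iqr_post = q(post, c(0.25, 0.75)),
       median_shift = median(diffs), method = method)
}

#' Blood-pressure category transition matrix
#'
#' Counts patients per (pre-category, post-category) cell; the matrix
#' total equals the cohort size, the row totals the pre-treatment
#' category mix.
#'
#' @param cohort A `bp_records` tibble.
#' @param label Cohort label stored on the result.
#' @return A 3x3 integer matrix of class `transition_matrix` (rows = pre,
#'   columns = post).
#' @export
transition_matrix <- function(cohort, label = "cohort") {
  pre <- bp_categorize(cohort$sbp_pre, cohort$dbp_pre)
  post <- bp_categorize(cohort$sbp_post, cohort$dbp_post)
  m <- table(pre = pre, post = post)
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(pre = bp_category_levels,
                              post = bp_category_levels))
  structure(m, class = c("transition_matrix", "matrix"), cohort = label)
}

#' @rdname transition_matrix
#' @param counts 3x3 matrix of counts (rows = pre, columns = post).
#' @export
as_transition_matrix <- function(counts, label = "cohort") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 3x3 matrix of non-negative integers")
  }
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(pre = bp_category_levels,
                              post = bp_category_levels))
  structure(m, class = c("transition_matrix", "matrix"), cohort = label)
}

#' Combine cohort transition matrices
#'
#' Elementwise sum over cohorts sharing the same category scheme; the
#' combined total is the sum of the cohort totals. Associative and
#' commutative.
#'
#' @param ms A list of `transition_matrix` objects.
#' @param label Label for the combined matrix.
#' @return A `transition_matrix`.
#' @export
combine_matrices <- function(ms, label = "combined") {
  stopifnot(length(ms) >= 1,
            all(vapply(ms, inherits, logical(1), "transition_matrix")))
  out <- Reduce(`+`, lapply(ms, unclass))
  as_transition_matrix(out, label = label)
}

#' Long-format transition table for Sankey rendering
#'
#' @param m A `transition_matrix`.
#' @return A tibble (pre_cat, post_cat, count).
#' @export
transition_long <- function(m) {
  stopifnot(inherits(m, "transition_matrix"))
  grid <- expand.grid(pre_cat = bp_category_levels,
                      post_cat = bp_category_levels,
                      stringsAsFactors = FALSE)
  grid$count <- as.integer(unclass(m)[cbind(grid$pre_cat, grid$post_cat)])
  tibble::as_tibble(grid[order(grid$pre_cat, grid$post_cat), ])
}
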