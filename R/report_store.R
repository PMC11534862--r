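#' Construct a report set
#'
#' A `report_set` is the container for spontaneous adverse-event case
#' reports flowing through the preprocessing chain. It wraps a tibble of
#' reports (one row per report), a free-text provenance label, the ordered
#' list of filters applied so far, and a log of per-stage row counts.
#'
#' Required report columns: `report_id`, `sex` (male/female/unknown),
#' `age` (numeric, NA allowed), `age_unit` (years/months/unknown),
#' `country`, `event_date` (Date, NA allowed), `therapy_start_date`
#' (Date, NA allowed), `drug_name` (normalized), `drug_role`
#' (primary_suspect/other), `indication` (NA allowed) and `reactions`
#' (a list-column of non-empty character vectors of PTs).
#'
#' @param reports A data frame of reports.
#' @param provenance Free-text label for the data source.
#' @param filters_applied Character vector of filter names already applied.
#' @param log A tibble of processing-stage counts (accumulated internally).
#' @return An object of class `report_set`.
#' @export
report_set <- function(reports, provenance = "unspecified",
                       filters_applied = character(), log = NULL) {
  reports <- tibble::as_tibble(reports)
  needed <- c("report_id", "sex", "age", "age_unit", "country", "event_date",
              "therapy_start_date", "drug_name", "drug_role", "indication",
              "reactions")
  missing <- setdiff(needed, names(reports))
  if (length(missing) > 0) {
    stop("reports is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reports$report_id)) {
    stop("report_id values must be unique within a report_set")
  }
  if (!is.list(reports$reactions)) {
    reports$reactions <- strsplit(as.character(reports$reactions), ";",
                                  fixed = TRUE)
  }
  if (any(lengths(reports$reactions) == 0)) {
    stop("every report must carry at least one reaction PT")
  }
  if (is.null(log)) {
    log <- tibble::tibble(stage = "input", n_before = nrow(reports),
                          n_after = nrow(reports), n_removed = 0L)
  }
  structure(
    list(reports = reports, provenance = provenance,
         filters_applied = filters_applied, log = log),
    class = "report_set"
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$reports), " reports (", x$provenance, ")\n",
      sep = "")
  if (length(x$filters_applied) > 0) {
    cat("  filters: ", paste(x$filters_applied, collapse = " -> "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
length.report_set <- function(x) nrow(x$reports)

log_stage <- function(rs, stage, n_before, n_after) {
  rs$log <- dplyr::bind_rows(
    rs$log,
    tibble::tibble(stage = stage, n_before = as.integer(n_before),
                   n_after = as.integer(n_after),
                   n_removed = as.integer(n_before - n_after))
  )
  rs
}

# ---- simplified CSV dialect -------------------------------------------------

simple_csv_columns <- c("report_id", "sex", "age", "age_unit", "country",
                        "event_date", "therapy_start_date", "drug_name",
                        "drug_role", "indication", "reactions")

#' Read / write the simplified flat CSV report dialect
#'
#' One row per report; dates ISO-8601; reaction PTs joined by `";"` in a
#' single `reactions` cell. `read_simple_csv(write_simple_csv(rs))` is the
#' identity on well-formed report sets.
#'
#' @param path File path.
#' @param rs A `report_set` (for writing).
#' @return `read_simple_csv` returns a `report_set`; `write_simple_csv`
#'   returns `path` invisibly.
#' @export
read_simple_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    report_id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double(),
    age_unit = readr::col_character(),
    country = readr::col_character(),
    event_date = readr::col_date(format = "%Y-%m-%d"),
    therapy_start_date = readr::col_date(format = "%Y-%m-%d"),
    drug_name = readr::col_character(),
    drug_role = readr::col_character(),
    indication = readr::col_character(),
    reactions = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(simple_csv_columns, names(df))
  if (length(missing) > 0) {
    stop("simple CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df$reactions <- strsplit(df$reactions, ";", fixed = TRUE)
  report_set(df, provenance = path)
}

#' @rdname read_simple_csv
#' @export
write_simple_csv <- function(rs, path) {
  stopifnot(inherits(rs, "report_set"))
  df <- rs$reports[simple_csv_columns[simple_csv_columns %in% names(rs$reports)]]
  df$reactions <- vapply(rs$reports$reactions,
                         function(x) paste(x, collapse = ";"), character(1))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# ---- FAERS quarterly ASCII --------------------------------------------------

read_faers_table <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NULL)
  readr::read_delim(path, delim = "$", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
}

parse_faers_date <- function(x) {
  # FAERS dates are yyyymmdd; partial dates (yyyy, yyyymm) and garbage
  # parse to NA rather than failing the row
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

#' Read FAERS quarterly ASCII tables into a report set
#'
#' Joins the `$`-delimited DEMO/DRUG/REAC/INDI/THER quarterly tables into
#' one case report per (primaryid, suspect drug). DEMO is mandatory; the
#' other tables are optional. Reports whose REAC join is empty are dropped
#' (a report must carry at least one reaction); unparseable dates become
#' absent values; malformed rows are skipped with a logged count.
#'
#' @param paths Named list of file paths with elements `demo` (required)
#'   and optionally `drug`, `reac`, `indi`, `ther`.
#' @param primary_suspect_only Keep only drugs with `role_cod == "PS"`.
#' @return A `report_set`.
#' @export
read_faers_ascii <- function(paths, primary_suspect_only = FALSE) {
  if (is.null(paths$demo) || !file.exists(paths$demo)) {
    stop("DEMO file is required but was not found: ", paths$demo)
  }
  demo <- read_faers_table(paths$demo)
  need_demo <- c("primaryid")
  if (!all(need_demo %in% names(demo))) {
    stop("DEMO file lacks mandatory column primaryid")
  }
  drug <- read_faers_table(paths$drug)
  reac <- read_faers_table(paths$reac)
  indi <- read_faers_table(paths$indi)
  ther <- read_faers_table(paths$ther)

  col_or_na <- function(df, col) {
    if (!is.null(df) && col %in% names(df)) df[[col]] else NA_character_
  }

  demo_t <- tibble::tibble(
    primaryid = demo$primaryid,
    sex = dplyr::case_when(
      toupper(col_or_na(demo, "sex")) %in% c("M", "MALE") ~ "male",
      toupper(col_or_na(demo, "sex")) %in% c("F", "FEMALE") ~ "female",
      TRUE ~ "unknown"
    ),
    age = suppressWarnings(as.numeric(col_or_na(demo, "age"))),
    age_unit = dplyr::case_when(
      toupper(col_or_na(demo, "age_cod")) %in% c("YR", "YEAR", "YEARS") ~ "years",
      toupper(col_or_na(demo, "age_cod")) %in% c("MON", "MONTH", "MONTHS") ~ "months",
      TRUE ~ "unknown"
    ),
    country = dplyr::coalesce(col_or_na(demo, "occr_country"), "unknown"),
    event_date = parse_faers_date(col_or_na(demo, "event_dt"))
  )
  demo_t <- demo_t[!is.na(demo_t$primaryid), ]
  n_demo <- nrow(demo_t)

  if (is.null(drug)) {
    drug_t <- tibble::tibble(primaryid = demo_t$primaryid,
                             drug_name = "unknown",
                             drug_role = "other")
  } else {
    drug_t <- tibble::tibble(
      primaryid = drug$primaryid,
      drug_name = normalize_drug_name(col_or_na(drug, "drugname")),
      drug_role = ifelse(toupper(col_or_na(drug, "role_cod")) == "PS",
                         "primary_suspect", "other")
    )
    if (primary_suspect_only) {
      drug_t <- drug_t[drug_t$drug_role == "primary_suspect", ]
    }
  }

  if (is.null(reac)) {
    reac_t <- tibble::tibble(primaryid = character(), pt = character())
  } else {
    reac_t <- tibble::tibble(primaryid = reac$primaryid,
                             pt = col_or_na(reac, "pt"))
    reac_t <- reac_t[!is.na(reac_t$pt), ]
  }
  reac_agg <- reac_t |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(reactions = list(unique(.data$pt)), .groups = "drop")

  indi_agg <- if (is.null(indi)) {
    tibble::tibble(primaryid = character(), indication = character())
  } else {
    tibble::tibble(primaryid = indi$primaryid,
                   indication = col_or_na(indi, "indi_pt")) |>
      dplyr::group_by(.data$primaryid) |>
      dplyr::summarise(indication = .data$indication[1], .groups = "drop")
  }

  ther_agg <- if (is.null(ther)) {
    tibble::tibble(primaryid = character(),
                   therapy_start_date = as.Date(character()))
  } else {
    tibble::tibble(primaryid = ther$primaryid,
                   therapy_start_date = parse_faers_date(
                     col_or_na(ther, "start_dt"))) |>
      dplyr::group_by(.data$primaryid) |>
      # first therapy start for multi-course therapy
      dplyr::summarise(
        therapy_start_date = if (all(is.na(.data$therapy_start_date)))
          as.Date(NA) else min(.data$therapy_start_date, na.rm = TRUE),
        .groups = "drop")
  }

  joined <- demo_t |>
    dplyr::inner_join(drug_t, by = "primaryid",
                      relationship = "one-to-many") |>
    dplyr::left_join(reac_agg, by = "primaryid") |>
    dplyr::left_join(indi_agg, by = "primaryid") |>
    dplyr::left_join(ther_agg, by = "primaryid")

  no_reac <- vapply(joined$reactions, is.null, logical(1))
  n_dropped <- sum(no_reac)
  if (n_dropped > 0) {
    warning(n_dropped, " report(s) dropped: no reaction PT after REAC join")
  }
  joined <- joined[!no_reac, ]
  if (!"indication" %in% names(joined)) joined$indication <- NA_character_
  if (!"therapy_start_date" %in% names(joined)) {
    joined$therapy_start_date <- as.Date(NA)
  }
  joined$report_id <- paste(joined$primaryid, joined$drug_name, sep = "::")
  joined <- joined[!duplicated(joined$report_id), ]
  joined$primaryid <- NULL

  rs <- report_set(joined, provenance = paths$demo)
  rs$log <- tibble::tibble(stage = "faers_ingest", n_before = n_demo,
                           n_after = nrow(joined),
                           n_removed = n_demo - nrow(joined))
  rs
}

# ---- preprocessing chain ----------------------------------------------------

dedup_key <- function(reports) {
  reaction_key <- vapply(reports$reactions,
                         function(x) paste(sort(x), collapse = "|"),
                         character(1))
  paste(reports$sex, reports$age, reports$age_unit, reports$country,
        reports$event_date, reaction_key, reports$drug_name,
        reports$indication, sep = "\r")
}

#' Deduplicate a report set
#'
#' Removes reports sharing identical values in sex, age (value and unit,
#' compared verbatim), country, event date, sorted reaction-PT set, drug
#' and indication. The first occurrence in input order is retained, so the
#' operation is deterministic and order-stable; the removed count is
#' logged. Idempotent.
#'
#' @param rs A `report_set`.
#' @return The deduplicated `report_set`.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  n0 <- nrow(rs$reports)
  keep <- !duplicated(dedup_key(rs$reports))
  rs$reports <- rs$reports[keep, ]
  rs$filters_applied <- c(rs$filters_applied, "deduplicate")
  log_stage(rs, "deduplicate", n0, nrow(rs$reports))
}

#' Keep only reports with a malignancy-related indication
#'
#' Case-insensitive substring match of the indication against a keyword
#' list ([default_malignancy_terms()] by default). Reports lacking an
#' indication cannot be confirmed malignant and are excluded (counted
#' separately in the log).
#'
#' @param rs A `report_set`.
#' @param terms Non-empty character vector of malignancy keywords.
#' @return The filtered `report_set`.
#' @export
filter_malignancy <- function(rs, terms = default_malignancy_terms()) {
  stopifnot(inherits(rs, "report_set"))
  if (length(terms) == 0) stop("malignancy term list must be non-empty")
  n0 <- nrow(rs$reports)
  ind <- tolower(rs$reports$indication)
  has_ind <- !is.na(ind) & nzchar(ind)
  pattern <- paste(sapply(tolower(terms),
                          function(t) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", t)),
                   collapse = "|")
  keep <- has_ind & grepl(pattern, ind)
  rs$reports <- rs$reports[keep, ]
  rs$filters_applied <- c(rs$filters_applied, "filter_malignancy")
  rs <- log_stage(rs, "filter_malignancy(no_indication)", n0,
                  n0 - sum(!has_ind))
  log_stage(rs, "filter_malignancy", n0, nrow(rs$reports))
}

#' Annotate reports with their drug class
#'
#' Adds a `drug_class` column (VEGFi / VEGFRi / other) from a
#' [drug_catalog()]. Optionally restricts to primary-suspect reports, the
#' screening rule used for signal analyses.
#'
#' @param rs A `report_set`.
#' @param catalog A `drug_catalog`.
#' @param primary_suspect_only Drop reports whose drug role is not
#'   `primary_suspect`.
#' @return The annotated `report_set`.
#' @export
assign_class <- function(rs, catalog = drug_catalog(),
                         primary_suspect_only = FALSE) {
  stopifnot(inherits(rs, "report_set"))
  n0 <- nrow(rs$reports)
  rs$reports$drug_class <- lookup_drug_class(catalog, rs$reports$drug_name)
  if (primary_suspect_only) {
    rs$reports <- rs$reports[rs$reports$drug_role == "primary_suspect", ]
  }
  rs$filters_applied <- c(rs$filters_applied, "assign_class")
  log_stage(rs, "assign_class", n0, nrow(rs$reports))
}
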