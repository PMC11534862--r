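#' Drug catalog: name -> class
#'
#' Maps normalized drug names to the two inhibitor classes under study:
#' ligand-blocking VEGF inhibitors (`VEGFi`) and receptor tyrosine-kinase
#' VEGFR inhibitors (`VEGFRi`). Names not in the catalog are `other`.
#' Matching is case-insensitive after [normalize_drug_name()].
#'
#' @param vegfi,vegfri Character vectors of drug names per class.
#' @return An object of class `drug_catalog`: a named character vector
#'   (normalized name -> class).
#' @export
#' @examples
#' cat <- drug_catalog()
#' lookup_drug_class(cat, "Bevacizumab")
drug_catalog <- function(vegfi = default_vegfi(), vegfri = default_vegfri()) {
  vegfi <- normalize_drug_name(vegfi)
  vegfri <- normalize_drug_name(vegfri)
  if (length(intersect(vegfi, vegfri)) > 0) {
    stop("a drug cannot belong to both classes: ",
         paste(intersect(vegfi, vegfri), collapse = ", "))
  }
  entries <- c(
    setNames(rep("VEGFi", length(vegfi)), vegfi),
    setNames(rep("VEGFRi", length(vegfri)), vegfri)
  )
  structure(entries, class = "drug_catalog")
}

#' @rdname drug_catalog
#' @export
default_vegfi <- function() {
  c("bevacizumab", "ranibizumab", "brolucizumab", "aflibercept",
    "conbercept", "pegaptanib")
}

#' @rdname drug_catalog
#' @export
default_vegfri <- function() {
  c("ramucirumab", "nintedanib", "apatinib", "axitinib", "sunitinib",
    "sorafenib", "regorafenib", "vandetanib", "cabozantinib", "pazopanib",
    "lenvatinib", "anlotinib", "fruquintinib", "tivozanib", "cediranib",
    "brivanib")
}

#' @param catalog A `drug_catalog`.
#' @param drug_name Character vector of (possibly unnormalized) drug names.
#' @rdname drug_catalog
#' @export
lookup_drug_class <- function(catalog, drug_name) {
  stopifnot(inherits(catalog, "drug_catalog"))
  cls <- unname(catalog[normalize_drug_name(drug_name)])
  cls[is.na(cls)] <- "other"
  cls
}

#' Normalize a drug name for catalog matching
#'
#' Lowercases, trims whitespace, and strips trade-name parentheticals,
#' e.g. `"AVASTIN (bevacizumab)"` and `"Bevacizumab"` both normalize to
#' `"bevacizumab"` provided the non-parenthetical token is the substance.
#'
#' @param x Character vector.
#' @return Character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  # prefer the parenthetical content when it names the substance, as in
  # "avastin (bevacizumab)"; otherwise drop the parenthetical
  inner <- sub("^.*\\(([^)]*)\\).*$", "\\1", x)
  has_paren <- grepl("\\(", x)
  stripped <- trimws(sub("\\s*\\([^)]*\\)", "", x))
  out <- stripped
  known <- c(default_vegfi(), default_vegfri())
  use_inner <- has_paren & trimws(inner) %in% known
  out[use_inner] <- trimws(inner[use_inner])
  out
}

#' Preferred-term catalog for blood-pressure-related adverse events
#'
#' The study design distinguishes a broad set of blood-pressure-related
#' preferred terms (PTs) from the subset directly describing hypertension.
#' The shipped default is a configurable illustrative list, not a licensed
#' MedDRA extract; supply your own PT lists for real analyses.
#'
#' @param bp_related Character vector of BP-related PTs.
#' @param hypertension_directly_related Subset of `bp_related` that
#'   directly describes hypertension.
#' @return An object of class `pt_catalog` with elements `bp_related` and
#'   `hypertension_directly_related`.
#' @export
pt_catalog <- function(bp_related = default_bp_pts(),
                       hypertension_directly_related = default_hypertension_pts()) {
  bp_related <- unique(as.character(bp_related))
  hypertension_directly_related <- unique(as.character(hypertension_directly_related))
  if (!all(hypertension_directly_related %in% bp_related)) {
    stop("hypertension_directly_related must be a subset of bp_related")
  }
  structure(
    list(bp_related = bp_related,
         hypertension_directly_related = hypertension_directly_related),
    class = "pt_catalog"
  )
}

#' @rdname pt_catalog
#' @export
default_bp_pts <- function() {
  c(default_hypertension_pts(),
    "Blood pressure increased", "Blood pressure fluctuation",
    "Blood pressure abnormal", "Blood pressure systolic increased",
    "Blood pressure diastolic increased", "Blood pressure inadequately controlled",
    "Orthostatic hypertension")
}

#' @rdname pt_catalog
#' @export
default_hypertension_pts <- function() {
  c("Hypertension", "Hypertensive crisis", "Hypertensive emergency",
    "Hypertensive urgency", "Essential hypertension", "Secondary hypertension",
    "Malignant hypertension", "Systolic hypertension", "Diastolic hypertension",
    "Labile hypertension", "Accelerated hypertension")
}

#' Default malignancy keyword list
#'
#' Used by [filter_malignancy()] for case-insensitive substring matching
#' against report indications. Editable; shipped as a pragmatic keyword
#' list because MedDRA system-organ-class mapping needs a license.
#'
#' @return Character vector of keywords.
#' @export
default_malignancy_terms <- function() {
  c("carcinoma", "cancer", "neoplasm malignant", "malignant neoplasm",
    "sarcoma", "lymphoma", "leukemia", "leukaemia", "melanoma", "myeloma",
    "glioma", "glioblastoma", "mesothelioma", "blastoma",
    "tumour malignant", "tumor malignant", "adenocarcinoma")
}

#' Read a run configuration file
#'
#' YAML file carrying the drug catalog, PT catalog, malignancy terms,
#' the primary-suspect-only flag and analysis toggles. Absent keys fall
#' back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @param x A named list of config fields (see [default_run_config()]).
#' @rdname read_run_config
#' @export
as_run_config <- function(x) {
  cfg <- default_run_config()
  for (k in names(x)) cfg[[k]] <- x[[k]]
  if (!is.null(x$drug_catalog)) {
    cfg$drug_catalog <- drug_catalog(vegfi = x$drug_catalog$vegfi,
                                     vegfri = x$drug_catalog$vegfri)
  }
  if (!is.null(x$pt_catalog)) {
    cfg$pt_catalog <- pt_catalog(
      bp_related = x$pt_catalog$bp_related,
      hypertension_directly_related = x$pt_catalog$hypertension_directly_related
    )
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    drug_catalog = drug_catalog(),
    pt_catalog = pt_catalog(),
    malignancy_terms = default_malignancy_terms(),
    primary_suspect_only = TRUE,
    literal_ic = FALSE,
    holm_adjust = FALSE,
    paired_test = "wilcoxon",
    alpha = 0.25,
    min_cases = 5,
    seed = 1L
  )
}
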