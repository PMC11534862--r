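#' Genes x samples expression matrix with cancer-type labels
#'
#' @param values Non-negative numeric matrix, genes in rows (rownames),
#'   samples in columns (colnames).
#' @param cancer_type Character vector of per-sample cancer-type labels,
#'   one per column.
#' @param scale `"FPKM"` or `"TPM"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cancer_type, scale = c("FPKM", "TPM")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(cancer_type) != ncol(values) || any(is.na(cancer_type))) {
    stop("every sample needs a cancer-type label")
  }
  structure(list(values = values,
                 cancer_type = setNames(as.character(cancer_type),
                                        colnames(values)),
                 scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", x$scale, "), ",
      length(unique(x$cancer_type)), " cancer types\n", sep = "")
  invisible(x)
}

#' Convert an FPKM matrix to TPM
#'
#' Per sample, `TPM_g = FPKM_g / sum_g FPKM_g * 1e6`, so every column
#' sums to one million. Errors on an all-zero sample column, naming it.
#'
#' @param m An `expression_matrix` on the FPKM scale.
#' @return The matrix on the TPM scale.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "FPKM") stop("input must be on the FPKM scale")
  cs <- colSums(m$values)
  if (any(cs == 0)) {
    stop("all-zero expression column(s): ",
         paste(colnames(m$values)[cs == 0], collapse = ", "))
  }
  m$values <- sweep(m$values, 2, cs, "/") * 1e6
  m$scale <- "TPM"
  m
}

#' A named gene set
#'
#' @param name Set name.
#' @param members Non-empty character vector of gene identifiers.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set must be non-empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(parts[1], parts[-(1:2)])
  })
  setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' @rdname read_gmt
#' @param sets Named list of `gene_set` objects.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

ssgsea_one_sample <- function(expr, in_set, alpha) {
  # expr: named numeric vector for one sample; in_set: logical over genes
  n <- length(expr)
  r <- rank(expr, ties.method = "average")   # high expression -> high rank
  ord <- order(expr, decreasing = TRUE)      # ties broken by gene order
  w <- r^alpha
  in_ord <- in_set[ord]
  p_in <- cumsum(ifelse(in_ord, w[ord], 0)) / sum(w[in_set])
  p_out <- cumsum(!in_ord) / (n - sum(in_set))
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based per-sample pathway activity score in the ssGSEA family:
#' genes are ranked by expression within each sample (average ranks for
#' ties), and the score is the running sum, over the list ordered by
#' decreasing expression, of the difference between the weighted ECDF of
#' in-set genes (weights `rank^alpha`, normalized) and the uniform ECDF
#' of out-of-set genes — the integrated statistic. `stat = "max_dev"`
#' returns the maximum deviation instead. The score is invariant under
#' any strictly monotone transform of a sample's expression values.
#'
#' @param m An `expression_matrix`.
#' @param gs A `gene_set` or named list of `gene_set` objects. Members
#'   are intersected with the matrix genes; the intersection must be
#'   non-empty and must not cover all genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param stat `"integrated"` (default) or `"max_dev"`.
#' @return A tibble (sample, cancer_type, gene_set, es, alpha).
#' @export
ssgsea_score <- function(m, gs, alpha = 0.25, stat = c("integrated", "max_dev")) {
  stopifnot(inherits(m, "expression_matrix"))
  stat <- match.arg(stat)
  if (inherits(gs, "gene_set")) gs <- setNames(list(gs), gs$name)
  genes <- rownames(m$values)
  out <- lapply(names(gs), function(nm) {
    members <- intersect(gs[[nm]]$members, genes)
    if (length(members) == 0) {
      stop("gene set '", nm, "' has empty intersection with the matrix genes")
    }
    if (length(members) == length(genes)) {
      stop("gene set '", nm, "' covers all genes; the complement is empty")
    }
    in_set <- genes %in% members
    es <- apply(m$values, 2, function(col) {
      if (stat == "integrated") {
        ssgsea_one_sample(col, in_set, alpha)
      } else {
        n <- length(col)
        r <- rank(col, ties.method = "average")
        ord <- order(col, decreasing = TRUE)
        in_ord <- in_set[ord]
        w <- r^alpha
        p_in <- cumsum(ifelse(in_ord, w[ord], 0)) / sum(w[in_set])
        p_out <- cumsum(!in_ord) / (n - sum(in_set))
        dev <- p_in - p_out
        dev[which.max(abs(dev))]
      }
    })
    tibble::tibble(sample = colnames(m$values),
                   cancer_type = unname(m$cancer_type),
                   gene_set = nm, es = unname(es), alpha = alpha)
  })
  dplyr::bind_rows(out)
}

#' Mean pathway score per cancer type
#'
#' @param scores Tibble from [ssgsea_score()].
#' @return A tibble (cancer_type, gene_set, mean_es, n_samples).
#' @export
per_cancer_pathway_score <- function(scores) {
  scores |>
    dplyr::group_by(.data$cancer_type, .data$gene_set) |>
    dplyr::summarise(mean_es = mean(.data$es), n_samples = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$cancer_type, .data$gene_set)
}

all_permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_permutations(v[-i]), deparse.level = 0)
  }))
}

#' Spearman correlation with tie correction and small-n exact p
#'
#' rho is the Pearson correlation of the two rank vectors (average ranks
#' for ties). The two-sided p-value uses the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for `n >= 10` and the exact
#' permutation distribution (all `n!` arrangements) below.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    return(list(rho = rho, p_value = min(1, max(p, .Machine$double.xmin)),
                n = n, method = "t_approximation"))
  }
  perms <- all_permutations(seq_len(n))
  ry_perm <- matrix(ry[perms], nrow = nrow(perms))
  rhos <- as.numeric(cor(rx, t(ry_perm)))
  p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  list(rho = rho, p_value = p, n = n, method = "exact_permutation")
}

#' Correlate per-cancer pathway activity with per-cancer ROR
#'
#' Inner-joins the two tables on cancer type and computes, per pathway,
#' the Spearman rank correlation between the mean enrichment score and
#' the reporting odds ratio across cancer types.
#'
#' @param scores Tibble from [per_cancer_pathway_score()] (columns
#'   cancer_type, gene_set, mean_es).
#' @param rors Tibble with columns cancer_type and ror (e.g. from
#'   [per_cancer_ror()]).
#' @return A tibble (gene_set, rho, p_value, n_cancers, method).
#' @export
correlate_with_ror <- function(scores, rors) {
  joined <- dplyr::inner_join(scores, rors[, c("cancer_type", "ror")],
                              by = "cancer_type")
  if (length(unique(joined$cancer_type)) < 4) {
    stop("fewer than 4 cancer types shared between scores and RORs")
  }
  joined |>
    dplyr::group_by(.data$gene_set) |>
    dplyr::group_modify(function(df, key) {
      st <- spearman_test(df$mean_es, df$ror)
      tibble::tibble(rho = st$rho, p_value = st$p_value,
                     n_cancers = st$n, method = st$method)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_set)
}
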