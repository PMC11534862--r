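# Seeded generators emulating the three study inputs: spontaneous-report
# data with planted disproportionality, a paired pre/post clinical BP
# cohort, and a pan-cancer expression matrix with planted pathway-ROR
# rank correlations. Every generator is a pure function of its config
# (seed included) and returns the generated data together with a truth
# record sufficient to compute expected downstream statistics.

#' Indication string -> cancer-type mapping used by the simulator
#'
#' @return Named character vector (indication -> cancer-type code).
#' @export
cancer_indication_map <- function() {
  c("Hepatocellular carcinoma" = "LIHC",
    "Colorectal cancer" = "CRC",
    "Non-small cell lung cancer" = "NSCLC",
    "Renal cell carcinoma" = "KIRC",
    "Breast cancer" = "BRCA",
    "Gastric cancer" = "STAD",
    "Ovarian cancer" = "OV",
    "Thyroid cancer" = "THCA",
    "Prostate cancer" = "PRAD",
    "Pancreatic carcinoma" = "PAAD",
    "Head and neck squamous cell carcinoma" = "HNSC",
    "Cholangiocarcinoma" = "CHOL",
    "Mesothelioma malignant" = "MESO",
    "Adrenal cortical carcinoma" = "ACC")
}

#' Configuration for the spontaneous-report simulator
#'
#' Defaults emulate the structure of the study's report data: a drug mix
#' dominated by the eight focal inhibitors plus background oncology and
#' non-oncology drugs, blood-pressure PT groups with planted
#' class-level reporting odds ratios (receptor inhibitors stronger, as
#' observed), a malignant-indication fraction, duplicate injection,
#' missing therapy dates, and right-skewed log-normal time-to-onset per
#' class (medians 59 d for ligand inhibitors, 21 d for receptor
#' inhibitors).
#'
#' @param n_reports Number of reports to generate (duplicates included).
#' @param seed Integer seed; the generator is a pure function of the
#'   config including this seed.
#' @param drug_probs Named numeric: marginal reporting probability per
#'   drug (normalized internally).
#' @param pt_groups Named list of PT character vectors.
#' @param baseline_pt_prob Named numeric, baseline per-report probability
#'   of each PT group for unplanted drugs.
#' @param planted_ror Tibble (drug, pt_group, ror): drug may be a drug
#'   name or a class label; ror multiplies the baseline reporting odds.
#' @param malignant_fraction Fraction of reports with a malignant
#'   indication.
#' @param cancer_type_weights Named numeric over the indications of
#'   [cancer_indication_map()] (two rare types by default, to exercise
#'   minimum-case exclusions).
#' @param duplicate_rate Fraction of reports that are injected copies of
#'   another report's full dedup key.
#' @param missing_date_rate Fraction of reports with the therapy start
#'   date removed.
#' @param tto_by_class List per class: `median` (days) and `sdlog` of the
#'   log-normal time to onset.
#' @return A list of class `faers_sim_config`.
#' @export
faers_sim_config <- function(
    n_reports = 10000L,
    seed = 1L,
    drug_probs = NULL,
    pt_groups = NULL,
    baseline_pt_prob = NULL,
    planted_ror = NULL,
    malignant_fraction = 0.6,
    cancer_type_weights = NULL,
    duplicate_rate = 0.05,
    missing_date_rate = 0.2,
    tto_by_class = list(VEGFi = list(median = 59, sdlog = 1.6),
                        VEGFRi = list(median = 21, sdlog = 1.6),
                        other = list(median = 40, sdlog = 1.6))) {
  if (n_reports <= 0) stop("n_reports must be positive")
  if (is.null(drug_probs)) {
    drug_probs <- c(
      bevacizumab = 0.06, sunitinib = 0.04, sorafenib = 0.04,
      lenvatinib = 0.03, axitinib = 0.02, pazopanib = 0.02,
      regorafenib = 0.02, cabozantinib = 0.02, ramucirumab = 0.015,
      nintedanib = 0.01, apatinib = 0.005,
      cisplatin = 0.15, paclitaxel = 0.15, pembrolizumab = 0.15,
      capecitabine = 0.1, aspirin = 0.1, metformin = 0.1
    )
  }
  drug_probs <- drug_probs / sum(drug_probs)
  if (is.null(pt_groups)) {
    pt_groups <- list(
      hypertension = c("Hypertension", "Hypertensive crisis",
                       "Systolic hypertension", "Diastolic hypertension"),
      blood_pressure_increased = c("Blood pressure increased",
                                   "Blood pressure systolic increased")
    )
  }
  if (is.null(baseline_pt_prob)) {
    baseline_pt_prob <- setNames(rep(0.03, length(pt_groups)),
                                 names(pt_groups))
  }
  if (is.null(planted_ror)) {
    planted_ror <- tibble::tibble(
      drug = c("VEGFi", "VEGFRi", "VEGFi", "VEGFRi"),
      pt_group = c("hypertension", "hypertension",
                   "blood_pressure_increased", "blood_pressure_increased"),
      ror = c(6, 9, 3, 5)
    )
  }
  if (is.null(cancer_type_weights)) {
    w <- rep(1, length(cancer_indication_map()))
    names(w) <- names(cancer_indication_map())
    # two deliberately rare tumor types
    w[c("Mesothelioma malignant", "Adrenal cortical carcinoma")] <- 0.01
    cancer_type_weights <- w
  }
  stopifnot(malignant_fraction >= 0, malignant_fraction <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_date_rate >= 0, missing_date_rate <= 1,
            all(planted_ror$ror > 0),
            all(names(baseline_pt_prob) == names(pt_groups)),
            all(baseline_pt_prob > 0 & baseline_pt_prob < 1))
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drug_probs = drug_probs, pt_groups = pt_groups,
    baseline_pt_prob = baseline_pt_prob, planted_ror = planted_ror,
    malignant_fraction = malignant_fraction,
    cancer_type_weights = cancer_type_weights,
    duplicate_rate = duplicate_rate,
    missing_date_rate = missing_date_rate,
    tto_by_class = tto_by_class
  ), class = "faers_sim_config")
}

#' Simulate a spontaneous-report set with recorded ground truth
#'
#' @param cfg A [faers_sim_config()].
#' @return A list with `reports` (a `report_set`) and `truth`, which
#'   records the injected duplicate count, the number of retained unique
#'   dedup keys, realized contingency cells per planted (drug, PT-group)
#'   pair on the deduplicated set, per-cancer exposed-case counts, the
#'   planted TTO parameters, and the missing-date count.
#' @export
simulate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "faers_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  n_dup <- round(cfg$duplicate_rate * n)
  n_orig <- n - n_dup
  if (n_orig <= 0) stop("duplicate_rate leaves no original reports")

  catalog <- drug_catalog()
  drug_name <- sample(names(cfg$drug_probs), n_orig, replace = TRUE,
                      prob = cfg$drug_probs)
  drug_class <- lookup_drug_class(catalog, drug_name)

  sex <- sample(c("male", "female", "unknown"), n_orig, replace = TRUE,
                prob = c(0.45, 0.45, 0.10))
  age <- sample(25:90, n_orig, replace = TRUE)
  country <- sample(c("US", "JP", "CN", "FR", "DE", "GB", "IT", "BR"),
                    n_orig, replace = TRUE)

  malignant <- runif(n_orig) < cfg$malignant_fraction
  benign_pool <- c("Macular degeneration", "Diabetic retinopathy",
                   "Rheumatoid arthritis", "Idiopathic pulmonary fibrosis")
  indication <- character(n_orig)
  indication[malignant] <- sample(names(cfg$cancer_type_weights),
                                  sum(malignant), replace = TRUE,
                                  prob = cfg$cancer_type_weights)
  indication[!malignant] <- sample(benign_pool, sum(!malignant),
                                   replace = TRUE)

  therapy_start <- as.Date("2013-01-01") +
    sample(0:3950, n_orig, replace = TRUE)
  tto_pars <- cfg$tto_by_class
  cls_key <- ifelse(drug_class %in% names(tto_pars), drug_class, "other")
  meanlog <- vapply(tto_pars, function(p) log(p$median), numeric(1))[cls_key]
  sdlog <- vapply(tto_pars, function(p) p$sdlog, numeric(1))[cls_key]
  tto <- round(rlnorm(n_orig, meanlog = meanlog, sdlog = sdlog))
  event_date <- therapy_start + tto

  # PT-group membership: baseline odds scaled by the planted relative rate
  background_pool <- c("Nausea", "Fatigue", "Diarrhoea", "Rash", "Headache",
                       "Vomiting", "Pyrexia", "Decreased appetite")
  reactions <- as.list(sample(background_pool, n_orig, replace = TRUE))
  group_hit <- matrix(FALSE, n_orig, length(cfg$pt_groups),
                      dimnames = list(NULL, names(cfg$pt_groups)))
  for (g in names(cfg$pt_groups)) {
    p0 <- cfg$baseline_pt_prob[[g]]
    rr <- rep(1, n_orig)
    planted_g <- cfg$planted_ror[cfg$planted_ror$pt_group == g, ]
    for (k in seq_len(nrow(planted_g))) {
      tgt <- planted_g$drug[k]
      hit <- drug_name == tgt | drug_class == tgt
      rr[hit] <- planted_g$ror[k]
    }
    p <- stats::plogis(stats::qlogis(p0) + log(rr))
    hit <- runif(n_orig) < p
    group_hit[, g] <- hit
    grp_pts <- cfg$pt_groups[[g]]
    add <- grp_pts[sample.int(length(grp_pts), sum(hit), replace = TRUE)]
    reactions[hit] <- Map(c, reactions[hit], add)
  }

  missing_date <- runif(n_orig) < cfg$missing_date_rate
  therapy_start[missing_date] <- NA

  drug_role <- sample(c("primary_suspect", "other"), n_orig, replace = TRUE,
                      prob = c(0.9, 0.1))

  orig <- tibble::tibble(
    report_id = sprintf("R%07d", seq_len(n_orig)),
    sex = sex, age = as.numeric(age), age_unit = "years", country = country,
    event_date = event_date, therapy_start_date = therapy_start,
    drug_name = drug_name, drug_role = drug_role, indication = indication,
    reactions = reactions
  )

  if (n_dup > 0) {
    src <- sample.int(n_orig, n_dup, replace = FALSE)
    dup <- orig[src, ]
    dup$report_id <- sprintf("R%07d", n_orig + seq_len(n_dup))
    all_reports <- dplyr::bind_rows(orig, dup)
  } else {
    all_reports <- orig
  }

  rs <- report_set(all_reports, provenance = "synthetic")

  # truth on the deduplicated set (originals minus accidental key clashes)
  keys <- dedup_key(all_reports)
  retained <- !duplicated(keys)
  kept <- all_reports[retained, ]
  kept_class <- lookup_drug_class(catalog, kept$drug_name)
  kept_hit <- group_hit[which(retained[seq_len(n_orig)]), , drop = FALSE]

  cells <- lapply(seq_len(nrow(cfg$planted_ror)), function(k) {
    tgt <- cfg$planted_ror$drug[k]
    g <- cfg$planted_ror$pt_group[k]
    dh <- kept$drug_name == tgt | kept_class == tgt
    ph <- kept_hit[, g]
    list(drug = tgt, pt_group = g, ror_planted = cfg$planted_ror$ror[k],
         a = sum(dh & ph), b = sum(dh & !ph), c = sum(!dh & ph),
         d = sum(!dh & !ph))
  })

  cmap <- cancer_indication_map()
  ctype <- unname(cmap[kept$indication])
  exposed <- kept_class %in% c("VEGFi", "VEGFRi")
  hyp_hit <- kept_hit[, "hypertension"]
  per_cancer_a <- tapply(exposed & hyp_hit, ctype, sum)

  truth <- list(
    n_injected_duplicates = n_dup,
    n_retained = sum(retained),
    cells = cells,
    per_cancer_a = per_cancer_a[!is.na(names(per_cancer_a))],
    n_malignant = sum(malignant),
    n_missing_dates = sum(missing_date),
    tto_by_class = cfg$tto_by_class,
    group_hit_rate = colMeans(group_hit)
  )
  list(reports = rs, truth = truth)
}

# ---- clinical cohort --------------------------------------------------------

#' Configuration for the clinical blood-pressure simulator
#'
#' Defaults emulate the study's hospital cohorts: 1087 ligand-inhibitor
#' and 529 receptor-inhibitor patients, pre-treatment medians near
#' 128/78 and 125/77 mmHg, and post-treatment upward shifts of about
#' +12/+2 and +7/+4 mmHg respectively.
#'
#' @param n_per_class Named integer vector (VEGFi, VEGFRi).
#' @param pre_mean Named list per class: c(sbp, dbp) pre-treatment means.
#' @param pre_sd c(sbp, dbp) pre-treatment standard deviations.
#' @param pre_cor Correlation between systolic and diastolic pressure.
#' @param shift Named list per class: c(sbp, dbp) additive post shift.
#' @param noise_sd c(sbp, dbp) standard deviation of the post noise.
#' @param seed Integer seed.
#' @return A list of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(
    n_per_class = c(VEGFi = 1087L, VEGFRi = 529L),
    pre_mean = list(VEGFi = c(sbp = 128, dbp = 78),
                    VEGFRi = c(sbp = 125, dbp = 77)),
    pre_sd = c(sbp = 15, dbp = 10),
    pre_cor = 0.6,
    shift = list(VEGFi = c(sbp = 12, dbp = 2),
                 VEGFRi = c(sbp = 7, dbp = 4)),
    noise_sd = c(sbp = 8, dbp = 5),
    seed = 1L) {
  stopifnot(all(pre_sd > 0), all(noise_sd > 0), abs(pre_cor) < 1,
            all(n_per_class > 0))
  structure(list(n_per_class = n_per_class, pre_mean = pre_mean,
                 pre_sd = pre_sd, pre_cor = pre_cor, shift = shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "clinical_sim_config")
}

# P(pre-category i, post-category j) under the config model, by grid
# quadrature over the pre-treatment bivariate normal (truncation to the
# plausibility window is ignored; its mass is negligible at these means)
expected_transition_probs <- function(cfg, class) {
  mu <- cfg$pre_mean[[class]]
  sd <- cfg$pre_sd
  rho <- cfg$pre_cor
  sh <- cfg$shift[[class]]
  ns <- cfg$noise_sd

  s <- seq(mu["sbp"] - 5 * sd["sbp"], mu["sbp"] + 5 * sd["sbp"], by = 0.5)
  d <- seq(mu["dbp"] - 5 * sd["dbp"], mu["dbp"] + 5 * sd["dbp"], by = 0.5)
  grid <- expand.grid(s = s, d = d)
  # bivariate normal density
  zs <- (grid$s - mu["sbp"]) / sd["sbp"]
  zd <- (grid$d - mu["dbp"]) / sd["dbp"]
  dens <- exp(-(zs^2 - 2 * rho * zs * zd + zd^2) / (2 * (1 - rho^2)))
  w <- dens / sum(dens)

  pre_cat <- as.integer(bp_categorize(pmin(pmax(grid$s, 31), 299),
                                      pmin(pmax(grid$d, 31), 299)))
  ps140 <- pnorm(140, grid$s + sh["sbp"], ns["sbp"])
  ps130 <- pnorm(130, grid$s + sh["sbp"], ns["sbp"])
  pd90 <- pnorm(90, grid$d + sh["dbp"], ns["dbp"])
  pd85 <- pnorm(85, grid$d + sh["dbp"], ns["dbp"])
  p_post <- cbind(normal = ps130 * pd85,
                  high_normal = ps140 * pd90 - ps130 * pd85,
                  hypertension = 1 - ps140 * pd90)

  out <- matrix(0, 3, 3, dimnames = list(pre = bp_category_levels,
                                         post = bp_category_levels))
  for (i in 1:3) {
    sel <- pre_cat == i
    out[i, ] <- colSums(p_post[sel, , drop = FALSE] * w[sel])
  }
  out
}

#' Simulate a paired pre/post blood-pressure cohort
#'
#' @param cfg A [clinical_sim_config()].
#' @return A list with `records` (a `bp_records` tibble for both classes)
#'   and `truth`: the planted shifts and the analytically expected 3x3
#'   category-transition probability matrix per class.
#' @export
simulate_clinical <- function(cfg) {
  stopifnot(inherits(cfg, "clinical_sim_config"))
  set.seed(cfg$seed)

  draw_class <- function(class, n) {
    mu <- cfg$pre_mean[[class]]
    sd <- cfg$pre_sd
    rho <- cfg$pre_cor
    sh <- cfg$shift[[class]]
    ns <- cfg$noise_sd
    sbp_pre <- dbp_pre <- sbp_post <- dbp_post <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      m <- length(todo)
      z1 <- rnorm(m)
      z2 <- rnorm(m)
      sp <- mu["sbp"] + sd["sbp"] * z1
      dp <- mu["dbp"] + sd["dbp"] * (rho * z1 + sqrt(1 - rho^2) * z2)
      spo <- sp + sh["sbp"] + rnorm(m, 0, ns["sbp"])
      dpo <- dp + sh["dbp"] + rnorm(m, 0, ns["dbp"])
      ok <- sp > 30 & sp < 300 & dp > 30 & dp < 300 & sp > dp &
        spo > 30 & spo < 300 & dpo > 30 & dpo < 300 & spo > dpo
      idx <- todo[ok]
      sbp_pre[idx] <- sp[ok]; dbp_pre[idx] <- dp[ok]
      sbp_post[idx] <- spo[ok]; dbp_post[idx] <- dpo[ok]
      todo <- todo[!ok]
    }
    tibble::tibble(patient_id = paste0(class, "_", seq_len(n)),
                   drug_class = class,
                   sbp_pre = sbp_pre, dbp_pre = dbp_pre,
                   sbp_post = sbp_post, dbp_post = dbp_post)
  }

  classes <- names(cfg$n_per_class)
  records <- dplyr::bind_rows(lapply(classes, function(cl) {
    draw_class(cl, cfg$n_per_class[[cl]])
  }))
  truth <- list(
    shift = cfg$shift,
    transition_probs = setNames(
      lapply(classes, function(cl) expected_transition_probs(cfg, cl)),
      classes)
  )
  list(records = bp_records(records), truth = truth)
}

# ---- pan-cancer expression --------------------------------------------------

#' Configuration for the pan-cancer expression simulator
#'
#' Defaults emulate the pan-cancer arm: 24 cancer types, a few samples
#' each, FPKM-scale values, disjoint planted gene sets whose type-level
#' activity follows a Gaussian copula with the per-cancer reporting odds
#' ratio at planted Spearman correlations matching the magnitudes of the
#' reported pathway associations (about -0.66, -0.44, +0.39, -0.38).
#'
#' @param n_genes Gene-universe size.
#' @param n_cancer_types Number of cancer types.
#' @param samples_per_type Samples per type.
#' @param set_size Genes per planted set.
#' @param pathways Tibble (name, rho): planted Spearman correlation of
#'   each pathway's type-level activity with the per-cancer ROR.
#' @param gradient_scale Log-scale expression shift per unit activity for
#'   set genes.
#' @param noise_sd Log-scale per-value noise standard deviation.
#' @param ror_log_mean,ror_log_sd Location/scale of the log per-cancer
#'   ROR (defaults span roughly 2.4 to 18, as in the reported range).
#' @param seed Integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(
    n_genes = 600L, n_cancer_types = 24L, samples_per_type = 4L,
    set_size = 25L,
    pathways = tibble::tibble(
      name = c("mapk_negative_feedback", "triglyceride_metabolism",
               "ip3_calcium_release", "enos_no_metabolism"),
      rho = c(-0.38, -0.66, 0.39, -0.44)),
    gradient_scale = 1.0, noise_sd = 0.5,
    ror_log_mean = 1.9, ror_log_sd = 0.55,
    seed = 1L) {
  stopifnot(all(abs(pathways$rho) <= 1), noise_sd >= 0,
            set_size * nrow(pathways) < n_genes, n_cancer_types >= 4)
  structure(list(n_genes = as.integer(n_genes),
                 n_cancer_types = as.integer(n_cancer_types),
                 samples_per_type = as.integer(samples_per_type),
                 set_size = as.integer(set_size), pathways = pathways,
                 gradient_scale = gradient_scale, noise_sd = noise_sd,
                 ror_log_mean = ror_log_mean, ror_log_sd = ror_log_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

# Construct ranks sigma over 1..n whose sample Spearman correlation with
# the ranks ry is within tol of rho_target: start from the perfectly
# (anti)correlated permutation and accept random pair swaps that move the
# correlation toward the target. Deterministic given the RNG state.
plant_rank_permutation <- function(ry, rho_target, tol = 0.015,
                                   max_iter = 50000) {
  n <- length(ry)
  sigma <- if (rho_target >= 0) ry else (n + 1 - ry)
  cur <- cor(sigma, ry)
  iter <- 0
  while (abs(cur - rho_target) > tol && iter < max_iter) {
    iter <- iter + 1
    i <- sample.int(n, 2)
    cand <- sigma
    cand[i] <- sigma[rev(i)]
    newc <- cor(cand, ry)
    if (abs(newc - rho_target) < abs(cur - rho_target)) {
      sigma <- cand
      cur <- newc
    }
  }
  sigma
}

#' Simulate a pan-cancer expression matrix with planted pathway gradients
#'
#' The per-cancer ROR is drawn log-normally; each pathway's type-level
#' activity is then constructed so that its sample Spearman correlation
#' with the ROR vector equals the planted `rho` (rank planting per
#' dataset, not merely in expectation); set-gene log-expression is
#' shifted by the type activity.
#'
#' @param cfg An [expression_sim_config()].
#' @return A list with `matrix` (FPKM `expression_matrix`), `gene_sets`
#'   (named list of `gene_set`), `rors` (tibble cancer_type, ror) and
#'   `truth` (planted rho per pathway, type activities, ROR vector).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  set.seed(cfg$seed)
  nt <- cfg$n_cancer_types
  types <- sprintf("CT%02d", seq_len(nt))
  y <- rnorm(nt)                       # latent driving the per-cancer ROR
  ror <- exp(cfg$ror_log_mean + cfg$ror_log_sd * y)

  npath <- nrow(cfg$pathways)
  ry <- rank(y)
  u <- matrix(0, nt, npath, dimnames = list(types, cfg$pathways$name))
  for (j in seq_len(npath)) {
    sigma <- plant_rank_permutation(ry, cfg$pathways$rho[j])
    u[, j] <- qnorm(sigma / (nt + 1))
  }

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  sets <- list()
  set_idx <- matrix(FALSE, cfg$n_genes, npath)
  for (j in seq_len(npath)) {
    members <- genes[((j - 1) * cfg$set_size + 1):(j * cfg$set_size)]
    sets[[cfg$pathways$name[j]]] <- gene_set(cfg$pathways$name[j], members)
    set_idx[, j] <- genes %in% members
  }

  ns <- cfg$samples_per_type
  samples <- paste0(rep(types, each = ns), "_s", rep(seq_len(ns), nt))
  sample_type <- rep(types, each = ns)
  mu_g <- rnorm(cfg$n_genes, mean = 2, sd = 1)

  logexpr <- matrix(rnorm(cfg$n_genes * length(samples), 0, cfg$noise_sd),
                    cfg$n_genes, length(samples)) + mu_g
  for (j in seq_len(npath)) {
    shift <- cfg$gradient_scale * u[sample_type, j]
    logexpr[set_idx[, j], ] <- logexpr[set_idx[, j], ] +
      rep(shift, each = cfg$set_size)
  }
  values <- exp(logexpr)
  dimnames(values) <- list(genes, samples)

  list(
    matrix = expression_matrix(values, sample_type, scale = "FPKM"),
    gene_sets = sets,
    rors = tibble::tibble(cancer_type = types, ror = ror),
    truth = list(planted_rho = setNames(cfg$pathways$rho,
                                        cfg$pathways$name),
                 type_activity = u, ror = setNames(ror, types))
  )
}
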