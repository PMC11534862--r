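test_that("onset extraction does date arithmetic and excludes bad records", {
  df <- make_reports(3)
  df$therapy_start_date <- as.Date(c("2020-01-01", "2020-03-01", NA))
  df$event_date <- as.Date(c("2020-01-22", "2020-02-01", "2020-05-01"))
  df$reactions <- list("Hypertension", "Hypertension", "Hypertension")
  rs <- report_set(df)
  rec <- extract_tto(rs, "Hypertension")
  expect_equal(rec$tto_days, 21)              # 2020-01-01 -> 2020-01-22
  expect_equal(attr(rec, "n_negative"), 1)    # event before start
  expect_equal(attr(rec, "n_missing_dates"), 1)
})

test_that("missing-date bookkeeping matches the generator", {
  cfg <- faers_sim_config(n_reports = 3000, seed = 17, duplicate_rate = 0,
                          missing_date_rate = 0.3)
  sim <- simulate_reports(cfg)
  rs <- assign_class(sim$reports)
  pts <- unique(unlist(cfg$pt_groups))
  rec <- extract_tto(rs, pts)
  # independent bookkeeping straight off the generated tibble
  match_pt <- vapply(rs$reports$reactions, function(x) sum(x %in% pts),
                     integer(1))
  eligible <- sum(match_pt[!is.na(rs$reports$therapy_start_date)])
  expect_equal(nrow(rec), eligible)
  expect_equal(attr(rec, "n_missing_dates"),
               sum(match_pt[is.na(rs$reports$therapy_start_date)]))
})

test_that("group summaries use the linear-interpolation quantile convention", {
  rec <- tibble::tibble(report_id = "x", drug_name = "d", drug_class = "c",
                        pt = "p", tto_days = 21)
  s <- summarize_tto(rec, "drug")
  expect_equal(c(s$median_days, s$iqr_low, s$iqr_high), c(21, 21, 21))

  # hand-computed type-7 quantiles of {3, 7, 8, 29, 34}
  rec2 <- tibble::tibble(report_id = letters[1:5], drug_name = "d",
                         drug_class = "c", pt = "p",
                         tto_days = c(3, 7, 8, 29, 34))
  s2 <- summarize_tto(rec2, "drug")
  expect_equal(s2$median_days, 8)
  expect_equal(s2$iqr_low, 7)
  expect_equal(s2$iqr_high, 29)

  # sampling recovery of a log-normal median
  set.seed(5)
  v <- rlnorm(2000, meanlog = log(21), sdlog = 1.6)
  rec3 <- tibble::tibble(report_id = as.character(seq_along(v)),
                         drug_name = "d", drug_class = "c", pt = "p",
                         tto_days = round(v))
  s3 <- summarize_tto(rec3, "class")
  expect_lt(abs(s3$median_days - 21) / 21, 0.1)
})

test_that("ECDF curves are right-continuous step functions reaching 1", {
  e <- ecdf_curve(c(5, 10), "g")
  expect_equal(e$F[e$t == 5], 0.5)
  expect_equal(e$F[e$t == 10], 1.0)

  e2 <- ecdf_curve(c(5, 5, 10), "g")
  expect_equal(e2$F[e2$t == 5], 2 / 3)

  set.seed(2)
  v <- sample(1:50, 200, replace = TRUE)
  e3 <- ecdf_curve(v, "g")
  expect_true(all(diff(e3$F) > 0))
  expect_equal(max(e3$F), 1)

  # pooled ECDF is the sample-size-weighted mixture of group ECDFs
  x <- c(1, 3, 3, 7)
  y <- c(2, 3, 9)
  pool <- ecdf_curve(c(x, y), "pool")
  fx <- stats::ecdf(x)
  fy <- stats::ecdf(y)
  mix <- (length(x) * fx(pool$t) + length(y) * fy(pool$t)) /
    (length(x) + length(y))
  expect_equal(pool$F, mix)
})

test_that("Mann-Whitney comparison matches exact and approximate oracles", {
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(compare_groups(c(2, 4, 6), c(2, 4, 6))$p_value, 1)

  # cross-check the enumeration against the exact distribution oracle
  r <- compare_groups(c(1, 2, 5), c(3, 4))
  o <- wilcox.test(c(1, 2, 5), c(3, 4), exact = TRUE)
  expect_equal(r$U, unname(o$statistic))
  expect_equal(r$p_value, o$p.value)
  expect_equal(r$method, "exact_enumeration")

  set.seed(7)
  for (i in 1:20) {
    x <- sample(1000, sample(2:5, 1))
    y <- sample(2000:3000, sample(2:5, 1))
    r <- compare_groups(x, y)
    o <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
  }

  # large samples: tie-corrected normal approximation against the oracle
  set.seed(8)
  x <- sample(1:40, 120, replace = TRUE)
  y <- sample(5:45, 150, replace = TRUE)
  r <- compare_groups(x, y)
  o <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$method, "normal_approx")
  expect_equal(r$p_value, o$p.value, tolerance = 1e-10)

  # symmetry and shift invariance
  expect_equal(compare_groups(x, y)$p_value, compare_groups(y, x)$p_value)
  expect_equal(compare_groups(x + 17, y + 17)$p_value,
               compare_groups(x, y)$p_value)
  expect_equal(compare_groups(rep(4, 10), rep(4, 12))$p_value, 1)
})

test_that("pairwise drug comparisons single out a planted fast-onset drug", {
  set.seed(9)
  drugs <- paste0("drug", 1:8)
  meds <- c(5, rep(60, 7))   # drug1 is the planted fast-onset drug
  rec <- dplyr::bind_rows(lapply(1:8, function(i) {
    tibble::tibble(report_id = paste0(i, "_", 1:80), drug_name = drugs[i],
                   drug_class = "VEGFRi", pt = "Hypertension",
                   tto_days = round(rlnorm(80, log(meds[i]), 0.8)))
  }))
  p <- pairwise_drug_comparison(rec, drugs)
  expect_equal(dim(p), c(8, 8))
  expect_true(all(diag(p) == 1))
  expect_equal(p, t(p))
  fast <- p["drug1", -1]
  others <- p[-1, -1][upper.tri(p[-1, -1])]
  expect_lt(max(fast), min(others))

  # a drug compared with itself
  expect_equal(compare_groups(rec$tto_days[rec$drug_name == "drug1"],
                              rec$tto_days[rec$drug_name == "drug1"])$p_value,
               1)
})

test_that("planted class medians and their separation are recovered", {
  cfg <- faers_sim_config(
    n_reports = 20000, seed = 23, duplicate_rate = 0,
    missing_date_rate = 0.2,
    drug_probs = c(bevacizumab = 0.3, sunitinib = 0.3, cisplatin = 0.2,
                   aspirin = 0.2),
    baseline_pt_prob = c(hypertension = 0.3,
                         blood_pressure_increased = 0.02),
    planted_ror = tibble::tibble(drug = "VEGFi", pt_group = "hypertension",
                                 ror = 1))
  sim <- simulate_reports(cfg)
  rs <- assign_class(deduplicate(sim$reports))
  rec <- extract_tto(rs, cfg$pt_groups$hypertension)
  rec <- rec[rec$drug_class %in% c("VEGFi", "VEGFRi"), ]
  s <- summarize_tto(rec, "class")
  expect_gte(min(s$n), 1000)
  expect_lt(abs(s$median_days[s$group == "VEGFi"] - 59) / 59, 0.15)
  expect_lt(abs(s$median_days[s$group == "VEGFRi"] - 21) / 21, 0.15)
  cmp <- compare_groups(rec$tto_days[rec$drug_class == "VEGFi"],
                        rec$tto_days[rec$drug_class == "VEGFRi"])
  expect_lt(cmp$p_value, 0.001)
})
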