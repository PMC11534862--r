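test_that("contingency construction enumerates the four cells exactly", {
  rs <- make_cell_reports(1, 1, 1, 1)
  t <- build_contingency(rs, "bevacizumab", "Hypertension")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  rs2 <- make_cell_reports(20, 80, 10, 890)
  t2 <- build_contingency(rs2, "bevacizumab", "Hypertension")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(20, 80, 10, 890))
  expect_equal(t2$N, length(rs2))

  # target PTs disjoint from all reactions -> empty event margin
  t3 <- build_contingency(rs, "bevacizumab", "Dizziness")
  expect_equal(c(t3$a, t3$c), c(0, 0))

  expect_error(contingency_table(0, 0, 0, 0), "all zero")
  expect_error(contingency_table(-1, 1, 1, 1), "non-negative")
})

test_that("ROR point estimate and Woolf interval match the closed form", {
  expect_equal(ror_with_ci(contingency_table(10, 10, 10, 10))$ror, 1)

  # unobserved exposed-event cell: point estimate 0, finite corrected CI
  r0 <- ror_with_ci(contingency_table(0, 100, 50, 1000))
  expect_equal(r0$ror, 0)
  expect_true(is.finite(r0$ci_low) && r0$ci_low > 0)
  expect_equal(r0$zero_cell_policy_used, "haldane_anscombe_0.5")

  # independent hand evaluation of the formulas
  r <- ror_with_ci(contingency_table(20, 80, 10, 890))
  expect_equal(r$ror, 22.25)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 890)
  expect_equal(r$ci_low, exp(log(22.25) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(22.25) + 1.96 * se), tolerance = 1e-12)
})

test_that("IC is zero at independence and matches direct arithmetic", {
  # a*N == (a+b)(a+c): observed equals expected
  expect_equal(ic_with_ic025(contingency_table(10, 90, 100, 900))$ic, 0)

  r <- ic_with_ic025(contingency_table(20, 80, 10, 890))
  expect_equal(r$ic, log2(20 * 1000 / (100 * 30)), tolerance = 1e-12)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 890)
  expect_equal(r$ic025, r$ic - 1.96 * se, tolerance = 1e-12)

  # a=0 under the +0.5 correction: finite and negative for a rare event
  r0 <- ic_with_ic025(contingency_table(0, 500, 20, 5000))
  expect_true(is.finite(r0$ic))
  expect_lt(r0$ic, 0)

  # the literal league-table variant differs from the default
  t <- contingency_table(20, 80, 10, 890)
  expect_false(isTRUE(all.equal(ic_with_ic025(t)$ic,
                                ic_with_ic025(t, literal_ic = TRUE)$ic)))
})

test_that("the three-part signal criterion uses strict bounds", {
  mk <- function(a, ci_low, ic025) {
    list(table = list(a = a), ror_ci_low = ci_low, ic025 = ic025)
  }
  expect_false(flag_signal(mk(2, 5, 2)))     # below the minimum count
  expect_false(flag_signal(mk(10, 1.0, 0.5))) # CI bound not strictly > 1
  expect_false(flag_signal(mk(10, 1.2, 0)))   # IC025 not strictly > 0
  expect_true(flag_signal(mk(10, 1.2, 0.3)))
})

test_that("signal_table is consistent with the scalar pipeline and planted signals", {
  rs <- make_cell_reports(20, 80, 10, 890)
  st <- signal_table(rs, "bevacizumab", c(Hypertension = "Hypertension"))
  expect_equal(nrow(st), 1)
  scalar <- signal_stats(build_contingency(rs, "bevacizumab", "Hypertension"))
  expect_equal(st$ror, scalar$ror)
  expect_equal(st$ic025, scalar$ic025)
  expect_equal(st$is_signal, scalar$is_signal)

  # cardinality: drugs x PT groups
  sim <- simulate_reports(faers_sim_config(n_reports = 2000, seed = 11))
  rs2 <- assign_class(deduplicate(sim$reports))
  drugs <- c("bevacizumab", "sunitinib", "sorafenib", "lenvatinib",
             "axitinib", "pazopanib", "regorafenib", "cabozantinib")
  pts <- unique(unlist(faers_sim_config()$pt_groups))[1:6]
  grid <- signal_table(rs2, drugs, pts)
  expect_equal(nrow(grid), 8 * 6)
  expect_false(is.unsorted(grid$drug))

  # planted class-level signals are recovered, unplanted pairs are not
  cfg <- faers_sim_config(
    n_reports = 10000, seed = 21, duplicate_rate = 0,
    planted_ror = tibble::tibble(
      drug = c("VEGFi", "VEGFRi"),
      pt_group = c("hypertension", "hypertension"),
      ror = c(8, 1)))
  sim2 <- simulate_reports(cfg)
  rs3 <- assign_class(deduplicate(sim2$reports))
  st2 <- signal_table(rs3, c("VEGFi", "VEGFRi"),
                      list(hypertension = cfg$pt_groups$hypertension))
  expect_true(st2$is_signal[st2$drug == "VEGFi"])
  expect_false(st2$is_signal[st2$drug == "VEGFRi"])
})

test_that("per-cancer ROR applies the strict minimum-case exclusion", {
  # two strata built by indication: one with a=4, one with a=5
  mk_stratum <- function(ind, a, b, c, d, offset) {
    df <- make_cell_reports(a, b, c, d)$reports
    df$indication <- ind
    df$report_id <- paste0(df$report_id, "_", offset)
    df
  }
  df <- dplyr::bind_rows(
    mk_stratum("Hepatocellular carcinoma", 4, 20, 10, 100, 1),
    mk_stratum("Colorectal cancer", 5, 20, 10, 100, 2))
  rs <- report_set(df)
  res <- per_cancer_ror(rs, cancer_indication_map(),
                        target_drugs = "bevacizumab",
                        target_pts = "Hypertension", min_cases = 5)
  expect_equal(res$cancer_type, "CRC")
  expect_equal(attr(res, "excluded"), "LIHC")
  expect_equal(res$a, 5)

  # parameter recovery: equal planted odds for both classes, so each
  # stratum's true reporting odds ratio is the planted value
  cfg <- faers_sim_config(
    n_reports = 20000, seed = 31, duplicate_rate = 0,
    malignant_fraction = 1,
    planted_ror = tibble::tibble(drug = c("VEGFi", "VEGFRi"),
                                 pt_group = "hypertension", ror = c(6, 6)))
  sim <- simulate_reports(cfg)
  rs2 <- assign_class(deduplicate(sim$reports))
  res2 <- per_cancer_ror(rs2, cancer_indication_map(),
                         target_pts = cfg$pt_groups$hypertension,
                         min_cases = 5)
  covered <- mean(res2$ci_low <= 6 & 6 <= res2$ci_high)
  expect_gte(covered, 0.8)
})

test_that("disproportionality invariants hold on random tables", {
  set.seed(1)
  tabs <- matrix(sample(1:50, 4 * 200, replace = TRUE), ncol = 4)
  s <- disprop_stats(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  # transposition symmetry of the ROR
  s_t <- disprop_stats(tabs[, 1], tabs[, 3], tabs[, 2], tabs[, 4])
  expect_equal(s$ror, s_t$ror, tolerance = 1e-12)

  # monotonicity: increasing a with b, c, d fixed raises the ROR always,
  # and the league-table IC variant (the default observed/expected IC also
  # grows its expected count with a, so it is monotone only while a is
  # small against the margins)
  a <- 5:50
  s_a <- disprop_stats(a, rep(20, length(a)), rep(15, length(a)),
                       rep(200, length(a)))
  expect_true(all(diff(s_a$ror) > 0))
  s_lit <- disprop_stats(a, rep(20, length(a)), rep(15, length(a)),
                         rep(200, length(a)), literal_ic = TRUE)
  expect_true(all(diff(s_lit$ic) > 0))
  small_a <- 1:10
  s_small <- disprop_stats(small_a, rep(200, 10), rep(150, 10), rep(2000, 10))
  expect_true(all(diff(s_small$ic) > 0))

  # flag monotone in each criterion threshold
  r <- signal_stats(contingency_table(10, 40, 20, 400))
  expect_true(flag_signal(r, min_a = 3) >= flag_signal(r, min_a = 11))
})
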