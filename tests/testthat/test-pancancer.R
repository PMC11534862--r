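test_that("FPKM to TPM normalizes every column to one million", {
  m <- make_expr(matrix(c(2, 2, 2, 2), ncol = 1))
  tpm <- fpkm_to_tpm(m)
  expect_equal(as.numeric(tpm$values), rep(250000, 4))

  set.seed(3)
  m2 <- make_expr(matrix(rgamma(60, 2), nrow = 10), types = rep("A", 6))
  tpm2 <- fpkm_to_tpm(m2)
  expect_equal(unname(colSums(tpm2$values)), rep(1e6, 6), tolerance = 1e-6)
  expect_equal(tpm2$scale, "TPM")

  single <- make_expr(matrix(7, 1, 1))
  expect_equal(as.numeric(fpkm_to_tpm(single)$values), 1e6)

  withzero <- make_expr(matrix(c(1, 2, 0, 0), nrow = 2), types = c("A", "B"))
  expect_error(fpkm_to_tpm(withzero), "s2")

  # idempotent up to the normalization constant
  renorm <- expression_matrix(tpm2$values, rep("A", 6), scale = "FPKM")
  expect_equal(fpkm_to_tpm(renorm)$values, tpm2$values, tolerance = 1e-12)
})

test_that("ssGSEA matches a hand-evaluated weighted running sum", {
  m <- make_expr(matrix(c(5, 4, 3, 2, 1), ncol = 1))
  gs <- gene_set("s", c("g2", "g4"))
  es <- ssgsea_score(m, gs, alpha = 0.25)$es

  # independent evaluation: ranks are 5..1, set genes sit at list
  # positions 2 and 4 with weights 4^0.25 and 2^0.25
  w2 <- 4^0.25
  w4 <- 2^0.25
  p_in <- c(0, w2, w2, w2 + w4, w2 + w4) / (w2 + w4)
  p_out <- c(1, 1, 2, 2, 3) / 3
  expect_equal(es, sum(p_in - p_out), tolerance = 1e-12)
})

test_that("ssGSEA extremal placement, label invariance and rank invariance", {
  vals <- c(9, 7, 5, 3, 1)
  placements <- combn(5, 2)
  scores <- apply(placements, 2, function(ix) {
    m <- make_expr(matrix(vals, ncol = 1))
    ssgsea_score(m, gene_set("s", paste0("g", ix)))$es
  })
  top <- which(apply(placements, 2, identical, c(1L, 2L)))
  expect_equal(which.max(scores), top)

  # permuting out-of-set gene labels leaves the score unchanged
  m1 <- make_expr(matrix(c(5, 4, 3, 2, 1), ncol = 1),
                  genes = c("a", "b", "c", "d", "e"))
  m2 <- make_expr(matrix(c(5, 4, 3, 2, 1), ncol = 1),
                  genes = c("a", "b", "e", "d", "c"))
  gs <- gene_set("s", c("a", "d"))
  expect_equal(ssgsea_score(m1, gs)$es, ssgsea_score(m2, gs)$es)

  # invariant under strictly monotone transforms of the expression values
  set.seed(4)
  v <- matrix(rgamma(40, 2), nrow = 20)
  ma <- make_expr(v, types = c("A", "B"))
  mb <- make_expr(v^3 + 1, types = c("A", "B"))
  gs2 <- gene_set("s", paste0("g", 1:6))
  expect_equal(ssgsea_score(ma, gs2)$es, ssgsea_score(mb, gs2)$es,
               tolerance = 1e-12)

  expect_error(ssgsea_score(ma, gene_set("s", "zzz")), "empty intersection")
  expect_error(ssgsea_score(ma, gene_set("s", paste0("g", 1:20))),
               "complement")
})

test_that("per-cancer aggregation is the arithmetic mean of sample scores", {
  scores <- tibble::tibble(
    sample = c("s1", "s2", "s3"), cancer_type = c("A", "A", "B"),
    gene_set = "s", es = c(1, 3, 5), alpha = 0.25)
  agg <- per_cancer_pathway_score(scores)
  expect_equal(agg$mean_es[agg$cancer_type == "A"], 2)
  expect_equal(agg$mean_es[agg$cancer_type == "B"], 5)

  # duplicating samples leaves the mean unchanged
  agg2 <- per_cancer_pathway_score(dplyr::bind_rows(scores, scores))
  expect_equal(agg2$mean_es, agg$mean_es)

  # a noise-free planted gradient is recovered in near-perfect rank order
  # (other planted sets shift the shared rank space, so exact order is
  # not guaranteed even without noise)
  cfg <- expression_sim_config(seed = 2, noise_sd = 0,
                               samples_per_type = 1)
  sim <- simulate_expression(cfg)
  sc <- ssgsea_score(fpkm_to_tpm(sim$matrix), sim$gene_sets)
  agg3 <- per_cancer_pathway_score(sc)
  for (p in names(sim$gene_sets)) {
    means <- agg3$mean_es[agg3$gene_set == p]
    expect_gt(cor(means, sim$truth$type_activity[, p],
                  method = "spearman"), 0.95)
  }
})

test_that("Spearman correlation handles monotone extremes and small-n exactness", {
  x <- c(1, 4, 9, 16, 25, 36)
  expect_equal(spearman_test(x, x^2)$rho, 1)
  expect_equal(spearman_test(x, -sqrt(x))$rho, -1)

  # exact permutation p against the classical small-sample oracle
  set.seed(6)
  for (i in 1:10) {
    a <- sample(100, 7)
    b <- sample(100, 7)
    mine <- spearman_test(a, b)
    oracle <- suppressWarnings(cor.test(a, b, method = "spearman"))
    expect_equal(mine$rho, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-9)
    expect_equal(mine$method, "exact_permutation")
  }

  # t-approximation path for n >= 10 against its closed form
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3.5, 8, 9.7)
  b <- c(2, 7, 1, 8, 2, 8.2, 1.8, 2.8, 4, 5, 6, 7)
  st <- spearman_test(a, b)
  rho <- cor(rank(a), rank(b))
  tt <- rho * sqrt(10 / (1 - rho^2))
  expect_equal(st$p_value, 2 * pt(-abs(tt), 10), tolerance = 1e-12)

  expect_error(spearman_test(1:3, 3:1), "at least 4")
})

test_that("pathway-ROR correlation joins on cancer type and is rank-invariant", {
  scores <- tibble::tibble(cancer_type = paste0("T", 1:12), gene_set = "s",
                           mean_es = c(4, 8, 1, 6, 3, 9, 2, 7, 5, 10, 11, 0),
                           n_samples = 1)
  rors <- tibble::tibble(cancer_type = paste0("T", 1:12),
                         ror = exp(scores$mean_es / 4) + runif(12, 0, 0.1))
  r1 <- correlate_with_ror(scores, rors)
  rors2 <- rors
  rors2$ror <- log(rors2$ror)      # strictly monotone transform
  r2 <- correlate_with_ror(scores, rors2)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_value, r2$p_value)

  expect_error(correlate_with_ror(scores[1:3, ], rors), "fewer than 4")
})

test_that("planted pathway-ROR rank correlations keep their sign across seeds", {
  for (rho in c(-0.66, -0.44, 0.39)) {
    hits <- 0
    for (seed in 1:100) {
      cfg <- expression_sim_config(
        seed = seed, n_genes = 200, samples_per_type = 4, set_size = 20,
        pathways = tibble::tibble(name = "p", rho = rho))
      sim <- simulate_expression(cfg)
      sc <- ssgsea_score(fpkm_to_tpm(sim$matrix), sim$gene_sets)
      corr <- correlate_with_ror(per_cancer_pathway_score(sc), sim$rors)
      hits <- hits + (sign(corr$rho) == sign(rho))
    }
    expect_gte(hits, 95)
  }
})
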