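test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_genes = 200L, seed = 42L)
  s1 <- simulate_expression(p)
  s2 <- simulate_expression(p)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_expression(s1$matrix, f1); write_expression(s2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))

  ph1 <- simulate_phenotypes(seed = 5L); ph2 <- simulate_phenotypes(seed = 5L)
  expect_identical(ph1, ph2)
  ct1 <- simulate_ct_table("g", 1, seed = 9L)
  ct2 <- simulate_ct_table("g", 1, seed = 9L)
  expect_identical(ct1, ct2)
})

test_that("with zero planted effects the generator behaves as a null model", {
  p <- sim_params(n_genes = 5000L, seed = 11L,
                  planted = data.frame(trait = "growth_habit",
                                       n_concordant = 0L, n_discordant = 0L,
                                       effect = 0))
  sim <- simulate_expression(p)
  expect_equal(nrow(sim$truth), 0L)
  cr <- two_group_contrast(sim$matrix, "SILe", "LILe")
  # t-test p-values are ~Uniform(0,1) under the null
  ks <- suppressWarnings(stats::ks.test(cr$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # joint rule can only call fewer genes than the t-test alone
  expect_lte(mean(cr$is_deg), mean(cr$p_value < 0.05))
})

test_that("within-group replicate correlation rises as replicate noise falls", {
  med_r <- vapply(c(1.0, 0.5, 0.2), function(sd) {
    sim <- simulate_expression(sim_params(n_genes = 300L, replicate_sd = sd,
                                          seed = 21L))
    qc <- replicate_correlation(sim$matrix)
    stats::median(qc$r)
  }, numeric(1L))
  expect_true(all(diff(med_r) > 0))
})

test_that("planted concordant genes are recoverable; the noise-free limit is (1 - alpha)", {
  planted <- data.frame(trait = "internode_length", n_concordant = 50L,
                        n_discordant = 0L, effect = 1.5)
  run <- function(sd, seed) {
    sim <- simulate_expression(sim_params(n_genes = 2000L, replicate_sd = sd,
                                          planted = planted, seed = seed))
    prim <- two_group_contrast(sim$matrix, "SILe", "LILe")
    conc <- two_group_contrast(sim$matrix, "Chiquitita", "SILe")
    sel <- three_way_select(prim, conc, trait = "internode_length")
    c(recall = mean(sim$truth$gene_id %in% sel$gene_id),
      primary = mean(sim$truth$gene_id %in% prim$gene_id[prim$is_deg]))
  }
  # pooled over 4 datasets so the Monte-Carlo error on recall is ~1.5%
  res <- vapply(33:36, function(s) run(0.2, s), numeric(2L))
  expect_gte(mean(res["recall", ]), 0.9)
  # noise-free limit: the primary stage recovers every planted gene; the
  # concordance filter still falsely rejects ~alpha of them, since its
  # p-value stays Uniform(0,1) under its exact null however small the
  # noise -- so overall recall converges to 1 - alpha, not 1
  res0 <- vapply(33:36, function(s) run(1e-4, s), numeric(2L))
  expect_equal(mean(res0["primary", ]), 1.0)
  expect_equal(mean(res0["recall", ]), 0.95, tolerance = 0.05)
})

test_that("simulated phenotype tables honour size, degeneracy and positivity", {
  ph <- simulate_phenotypes(n_seedlings = 120L, seed = 2L)
  expect_equal(nrow(ph), 120L)
  expect_true(all(ph$diameter_mm > 0))
  expect_true(all(as.matrix(ph[paste0("branch", 1:5, "_mm")]) > 0))

  ph0 <- simulate_phenotypes(n_seedlings = 10L,
                             trait_sds = list(diameter = 0, internode = 0),
                             seed = 2L)
  expect_equal(length(unique(ph0$diameter_mm)), 1L)  # all identical
  sel <- select_extreme_pools(ph0, "diameter", k_low = 3L, k_high = 3L)
  expect_equal(sel$low, 1:3)        # tie rule: input row order
  expect_equal(sort(sel$high), c(8L, 9L, 10L))

  expect_error(simulate_phenotypes(trait_sds = list(diameter = -1, internode = 0.5)),
               "non-negative")
})

test_that("noiseless Ct tables invert the delta-Ct transform exactly", {
  ct <- simulate_ct_table(c("g1", "g2", "g3"), c(0, -1, 2), ct_sd = 0, seed = 1L)
  r <- qpcr_log2_ratios(ct, "Chiquitita", "Arbosana")
  expect_equal(unname(r), c(0, -1, 2))
  # true ratio 0.5 recovered exactly
  ct2 <- simulate_ct_table("g", log2(0.5), ct_sd = 0, seed = 1L)
  expect_equal(unname(2^qpcr_log2_ratios(ct2, "Chiquitita", "Arbosana")), 0.5)
})

test_that("noisy Ct recovery is unbiased within Monte-Carlo error", {
  # 3 tech x 3 bio wells per sample, ct_sd = 0.2: each recovered log2 ratio
  # is a difference of two means of 3 bio-level averages, each bio average
  # over 3 target + 3 reference wells -> SEM = 0.2 * sqrt(2 * 2/9) = 0.133
  reps <- vapply(1:200, function(i) {
    ct <- simulate_ct_table("g", 1, ct_sd = 0.2, seed = i)
    unname(qpcr_log2_ratios(ct, "Chiquitita", "Arbosana"))
  }, numeric(1L))
  sem <- 0.2 * sqrt(2 * 2 / 9)
  expect_lt(abs(mean(reps) - 1), 3 * sem / sqrt(200))
  expect_true(all(abs(reps - 1) < 5 * sem))
})

test_that("simulation parameter validation rejects impossible requests", {
  expect_error(sim_params(replicate_sd = 0), "positive")
  expect_error(sim_params(n_genes = 10L,
                          planted = data.frame(trait = "growth_habit",
                                               n_concordant = 20L,
                                               n_discordant = 0L, effect = 1)),
               "planted")
  expect_error(sim_params(planted = data.frame(trait = "nope",
                                               n_concordant = 1L,
                                               n_discordant = 0L, effect = 1)),
               "trait")
})
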