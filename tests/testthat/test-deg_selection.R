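test_that("replicate correlation: identical and affine replicates give r = 1", {
  base <- 2^runif(50, 4, 12)
  m <- make_mat(list(A = list(base, base, base),
                     B = list(base, 2 * base^1.3, base^0.7)))
  qc <- replicate_correlation(m)
  # identical replicates
  expect_equal(qc$r[qc$group == "A"], rep(1, 3), tolerance = 1e-12)
  # log2 of a power/scale transform is affine in log2(base) -> r = 1
  expect_equal(qc$r[qc$group == "B"], rep(1, 3), tolerance = 1e-12)

  flat <- rep(8, 50)
  m2 <- make_mat(list(A = list(base, flat), B = list(base, base)))
  qc2 <- replicate_correlation(m2)
  expect_true(any(qc2$undefined))            # zero-variance column flagged
  expect_true(is.na(qc2$r[qc2$undefined][1]))
})

test_that("two-group contrast matches the closed-form pooled-variance t-test", {
  m <- make_mat(list(A = list(1, 2, 3), B = list(4, 5, 6)), gene_ids = "g")
  cr <- two_group_contrast(m, "A", "B", test_scale = "linear")
  expect_equal(cr$t, -3.674235, tolerance = 1e-6)
  expect_equal(cr$df, 4L)
  expect_equal(cr$p_value, 0.02131164, tolerance = 1e-6)
  # independent implementation agrees
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(cr$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(cr$fold_change, 2 / 5)

  # identical groups: t = 0, p = 1, no call
  m2 <- make_mat(list(A = list(1, 2, 3), B = list(1, 2, 3)), gene_ids = "g")
  cr2 <- two_group_contrast(m2, "A", "B", test_scale = "linear")
  expect_equal(cr2$t, 0)
  expect_equal(cr2$p_value, 1)
  expect_false(cr2$is_deg)
})

test_that("fold change uses linear means and the DEG window is strict", {
  # means 4 vs 2 (ratio exactly 2), tiny within-group spread -> p << alpha
  m <- make_mat(list(A = list(c(3.999), c(4.000), c(4.001)),
                     B = list(c(1.999), c(2.000), c(2.001))),
                gene_ids = "g")
  cr <- two_group_contrast(m, "A", "B")
  expect_equal(cr$fold_change, 2)
  expect_lt(cr$p_value, 0.05)
  expect_false(cr$is_deg)                    # "more than" 2-fold required
  # nudge above the threshold and the call flips
  m2 <- make_mat(list(A = list(c(4.01), c(4.011), c(4.012)),
                      B = list(c(1.999), c(2.000), c(2.001))),
                 gene_ids = "g")
  expect_true(two_group_contrast(m2, "A", "B")$is_deg)
})

test_that("DEG calls are symmetric under group swap and FC reciprocates", {
  sim <- simulate_expression(sim_params(n_genes = 400L, seed = 13L))
  ab <- two_group_contrast(sim$matrix, "SmaD", "LarD")
  ba <- two_group_contrast(sim$matrix, "LarD", "SmaD")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_identical(ab$is_deg, ba$is_deg)
})

test_that("degenerate zero-variance genes get the documented p conventions", {
  m <- make_mat(list(A = list(c(4, 8), c(4, 8), c(4, 8)),
                     B = list(c(4, 2), c(4, 2), c(4, 2))))
  expect_warning(cr <- two_group_contrast(m, "A", "B"), "zero pooled variance")
  expect_equal(cr$p_value, c(1, 0))          # equal means vs unequal means
  expect_error(two_group_contrast(
    make_mat(list(A = list(c(0), c(1), c(1)), B = list(c(1), c(1), c(1))),
             gene_ids = "g"), "A", "B"), "positive")
})

test_that("three-way selection applies the concordance rule gene by gene", {
  set.seed(8)
  base <- 2^stats::rnorm(60, 8, 2)
  a <- base; a[1:10] <- a[1:10] * 8   # genes 1-10 DEG in the primary contrast
  chi <- base; chi[6:10] <- chi[6:10] * 8  # reference tracks A only for 6-10
  mk <- function(v, eps) make_group(v, c(1, 1 + eps, 1 - eps))
  m <- make_mat(list(A = mk(a, 0.01), B = mk(base, 0.012),
                     Chi = mk(chi, 0.01)))
  prim <- two_group_contrast(m, "A", "B")
  conc <- two_group_contrast(m, "Chi", "A")
  sel <- three_way_select(prim, conc, trait = "t")
  got <- sel$gene_id
  expect_setequal(got, paste0("Contig_", 6:10))  # concordant genes only
  expect_true(all(sel$direction == "over"))
  expect_true(all(got %in% prim$gene_id[prim$is_deg]))  # subset of primary DEGs

  # excluded gene: DEG in primary but significantly different from reference
  expect_false("Contig_1" %in% got)
  # universe mismatch is fatal
  expect_error(three_way_select(prim, conc[-1, ]), "universe")
})

test_that("three-way selection separates planted concordant from discordant genes", {
  planted <- data.frame(trait = "trunk_diameter", n_concordant = 50L,
                        n_discordant = 50L, effect = 1.5)
  sim <- simulate_expression(sim_params(n_genes = 2000L, planted = planted,
                                        replicate_sd = 0.2, seed = 77L))
  prim <- two_group_contrast(sim$matrix, "SmaD", "LarD")
  conc <- two_group_contrast(sim$matrix, "Chiquitita", "SmaD")
  sel <- three_way_select(prim, conc, trait = "trunk_diameter")
  truth <- sim$truth
  conc_ids <- truth$gene_id[truth$concordant]
  disc_ids <- truth$gene_id[!truth$concordant]
  n_conc_in <- length(intersect(sel$gene_id, conc_ids))
  n_disc_in <- length(intersect(sel$gene_id, disc_ids))
  expect_gte(n_conc_in / max(1, n_disc_in), 9)   # >= 9:1 enrichment
  # direction agrees with the planted effect sign for recovered genes
  rec <- truth[truth$gene_id %in% sel$gene_id & truth$concordant, ]
  dirs <- sel$direction[match(rec$gene_id, sel$gene_id)]
  expect_identical(dirs, ifelse(rec$log2_effect > 0, "over", "under"))
})

test_that("brute-force per-gene oracle reproduces the whole pipeline at small n", {
  sim <- simulate_expression(sim_params(
    n_genes = 40L, seed = 3L,
    planted = data.frame(trait = "growth_habit", n_concordant = 8L,
                         n_discordant = 4L, effect = 1.5)))
  m <- sim$matrix
  prim <- two_group_contrast(m, "Chiquitita", "Arbosana")
  conc <- two_group_contrast(m, "Chiquitita", "ChiCa")
  sel <- three_way_select(prim, conc, trait = "growth_habit")
  alpha <- 0.05
  for (i in seq_along(m$gene_ids)) {
    va <- m$values[i, group_columns(m, "Chiquitita")]
    vb <- m$values[i, group_columns(m, "Arbosana")]
    vc <- m$values[i, group_columns(m, "ChiCa")]
    o_prim <- oracle_t(log2(va), log2(vb))
    o_conc <- oracle_t(log2(va), log2(vc))
    fc <- mean(va) / mean(vb)
    expect_equal(prim$p_value[i], o_prim$p, tolerance = 1e-12)
    expect_equal(prim$fold_change[i], fc, tolerance = 1e-12)
    is_deg <- o_prim$p < alpha && (fc > 2 || fc < 0.5)
    expect_equal(prim$is_deg[i], is_deg)
    expect_equal(m$gene_ids[i] %in% sel$gene_id,
                 is_deg && o_conc$p >= alpha)
  }
})

test_that("venn summary performs exact inclusion-exclusion set algebra", {
  sets <- make_venn_sets(10, 12, 15, 3, 2, 4, 1)
  v <- venn_summary(sets)
  expect_equal(unname(v$sizes), c(10L, 12L, 15L))
  expect_equal(unname(v$pairwise), c(3L, 2L, 4L))
  expect_equal(v$triple, 1L)
  expect_equal(v$union_size, 10 + 12 + 15 - 3 - 2 - 4 + 1)

  disjoint <- list(A = paste0("x", 1:5), B = paste0("y", 1:6), C = paste0("z", 1:7))
  expect_equal(venn_summary(disjoint)$union_size, 18L)
  same <- list(A = paste0("x", 1:5), B = paste0("x", 1:5), C = paste0("x", 1:5))
  expect_equal(venn_summary(same)$union_size, 5L)
})
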