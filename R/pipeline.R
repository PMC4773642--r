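# Orchestration: one-shot simulate + analyse runs driven by a single
# config, with every output written under a run directory and a manifest
# recording inputs, parameters and the seed, so a run is reproducible from
# the manifest alone.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Top-level seed; every stage derives its randomness from it.
#' @param n_genes Simulated gene count (default 5000).
#' @param alpha,fc_threshold,test_scale DEG-calling parameters.
#' @param n_random Random sets for the Kruskal-Wallis validation.
#' @param universe_n Universe size for overlap statistics; defaults to the
#'   number of genes in the matrix.
#' @param enrichment_cutoff FDR cutoff for GO enrichment.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(out_dir = tempfile("poolDEG_run_"), seed = 1L,
                            n_genes = 5000L, alpha = 0.05, fc_threshold = 2,
                            test_scale = "log2", n_random = 200L,
                            universe_n = NULL, enrichment_cutoff = 0.05) {
  list(out_dir = out_dir, seed = as.integer(seed), n_genes = as.integer(n_genes),
       alpha = alpha, fc_threshold = fc_threshold, test_scale = test_scale,
       n_random = as.integer(n_random), universe_n = universe_n,
       enrichment_cutoff = enrichment_cutoff)
}

stage_seed <- function(seed, stage) {
  # documented derivation: offset the top-level seed by a fixed per-stage
  # increment, kept well below 2^31
  offsets <- c(simulate = 0L, phenotypes = 101L, ct = 202L, validation = 303L)
  seed + unname(offsets[stage])
}

#' Simulate a complete fixture bundle
#'
#' Writes the expression matrix, planted truth, phenotype table and a Ct
#' table to \code{out_dir} using the default 9-group x 3-replicate design.
#'
#' @param config List from \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_bundle <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- sim_params(n_genes = config$n_genes,
                       design = default_design(config$alpha, config$fc_threshold),
                       seed = stage_seed(config$seed, "simulate"))
  sim <- simulate_expression(params)
  expr_path <- file.path(config$out_dir, "expression.tsv")
  write_expression(sim$matrix, expr_path)
  truth_path <- file.path(config$out_dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pheno <- simulate_phenotypes(seed = stage_seed(config$seed, "phenotypes"))
  pheno_path <- file.path(config$out_dir, "phenotypes.tsv")
  utils::write.table(pheno, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ct_genes <- utils::head(sim$truth$gene_id[sim$truth$trait == "growth_habit" &
                                              sim$truth$concordant], 12L)
  ct_ratios <- sim$truth$log2_effect[match(ct_genes, sim$truth$gene_id)]
  ct <- simulate_ct_table(ct_genes, ct_ratios, ct_sd = 0.2,
                          seed = stage_seed(config$seed, "ct"))
  ct_path <- file.path(config$out_dir, "ct.tsv")
  utils::write.table(ct, ct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(matrix = sim$matrix, truth = sim$truth, phenotypes = pheno,
                 ct = ct, params = params,
                 paths = list(expression = expr_path, truth = truth_path,
                              phenotypes = pheno_path, ct = ct_path)))
}

#' Run the full candidate-gene discovery pipeline
#'
#' Stages: replicate QC, per-trait primary and concordance contrasts,
#' three-way selection, Venn/union assembly, Kruskal-Wallis random-set
#' validation, Poisson overlap statistics, optional GO enrichment and
#' qPCR concordance, and (when planted truth is available) recovery
#' metrics. All reports are written under \code{config$out_dir}; a
#' \code{manifest.json} records parameters, the seed and package version.
#'
#' @param matrix An \code{ExpressionMatrix} (e.g. from
#'   \code{\link{simulate_bundle}} or \code{\link{load_expression}}).
#' @param design A \code{StudyDesign} (default \code{default_design()}).
#' @param config List from \code{\link{pipeline_config}}.
#' @param truth Optional planted-truth data frame for recovery metrics.
#' @param annotations Optional GO annotation list for enrichment.
#' @param ct_table Optional Ct table for qPCR concordance.
#' @return List of stage results (also written to disk).
#' @export
run_pipeline <- function(matrix, design = NULL, config = pipeline_config(),
                         truth = NULL, annotations = NULL, ct_table = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.null(design))
    design <- default_design(config$alpha, config$fc_threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  results <- list()

  qc <- replicate_correlation(matrix)
  utils::write.table(qc, out("qc_replicate_correlation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$qc <- qc

  sets <- list()
  for (i in seq_len(nrow(design$three_way))) {
    tw <- design$three_way[i, ]
    prim <- two_group_contrast(matrix, tw$primary_a, tw$primary_b,
                               alpha = design$alpha,
                               fc_threshold = design$fc_threshold,
                               test_scale = config$test_scale)
    conc <- two_group_contrast(matrix, tw$concordance_a, tw$concordance_b,
                               alpha = design$alpha,
                               fc_threshold = design$fc_threshold,
                               test_scale = config$test_scale)
    utils::write.table(prim, out(paste0("contrast_", tw$trait, "_primary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conc, out(paste0("contrast_", tw$trait, "_concordance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sets[[tw$trait]] <- three_way_select(prim, conc, trait = tw$trait)
  }
  write_candidate_table(sets, out("candidates.tsv"))
  results$candidates <- sets

  if (length(sets) == 3L) {
    venn <- venn_summary(sets)
    jsonlite::write_json(venn[c("sizes", "pairwise", "triple", "union_size")],
                         out("venn.json"), auto_unbox = TRUE)
    results$venn <- venn
    N <- if (is.null(config$universe_n)) nrow(matrix$values) else config$universe_n
    nm <- names(sets)
    overlaps <- list()
    combos <- utils::combn(3L, 2L)
    for (j in seq_len(ncol(combos))) {
      a <- combos[1L, j]; b <- combos[2L, j]
      k <- length(intersect(sets[[a]]$gene_id, sets[[b]]$gene_id))
      overlaps[[paste(nm[a], nm[b], sep = "&")]] <-
        poisson_overlap_p(nrow(sets[[a]]), nrow(sets[[b]]), N, k,
                          label = paste(nm[a], nm[b], sep = "&"))
    }
    jsonlite::write_json(lapply(overlaps, unclass), out("overlap.json"),
                         auto_unbox = TRUE)
    results$overlaps <- overlaps
  }

  kw <- lapply(sets, function(s) {
    if (nrow(s) >= 2L)
      kw_set_validation(matrix, s$gene_id, n_random = config$n_random,
                        seed = stage_seed(config$seed, "validation"),
                        alpha = design$alpha)
  })
  kw_out <- lapply(kw, function(r) if (!is.null(r))
    r[c("set_size", "candidate", "median_random_p",
        "frac_random_significant", "n_random")])
  jsonlite::write_json(kw_out, out("kw_validation.json"), auto_unbox = TRUE)
  results$kw <- kw

  if (!is.null(annotations)) {
    enr <- lapply(sets, function(s) enrich(s, annotations, matrix$gene_ids,
                                           cutoff = config$enrichment_cutoff))
    for (tr in names(enr))
      utils::write.table(enr[[tr]]$table, out(paste0("enrichment_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    results$enrichment <- enr
  }

  if (!is.null(ct_table)) {
    smp <- unique(ct_table$sample)
    ratios <- qpcr_log2_ratios(ct_table, smp[[1L]], smp[[2L]])
    prim_habit <- two_group_contrast(matrix, smp[[1L]], smp[[2L]],
                                     alpha = design$alpha,
                                     fc_threshold = design$fc_threshold,
                                     test_scale = config$test_scale)
    arr <- prim_habit$log2_fc[match(names(ratios), prim_habit$gene_id)]
    conc <- concordance(unname(ratios), arr)
    qdf <- data.frame(gene = names(ratios), log2_qpcr = unname(ratios),
                      log2_array = arr, stringsAsFactors = FALSE)
    utils::write.table(qdf, out("qpcr_ratios.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(conc, out("qpcr_concordance.json"), auto_unbox = TRUE)
    results$qpcr <- list(ratios = qdf, concordance = conc)
  }

  if (!is.null(truth) && nrow(truth)) {
    rec <- recovery_metrics(sets, truth)
    utils::write.table(rec, out("recovery.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$recovery <- rec
  }

  manifest <- list(package = "poolDEG",
                   version = as.character(utils::packageVersion("poolDEG")),
                   seed = config$seed, parameters = config[
                     c("n_genes", "alpha", "fc_threshold", "test_scale",
                       "n_random", "enrichment_cutoff")],
                   groups = design$groups$name,
                   three_way = design$three_way,
                   n_genes_analyzed = nrow(matrix$values))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Recovery metrics of candidate sets against planted truth
#'
#' Per trait: how many concordant planted genes were recovered
#' (sensitivity), how many discordant planted genes leaked through the
#' concordance filter, and the precision of the candidate set against the
#' concordant truth.
#'
#' @param sets Named list of \code{CandidateSet}s (names = traits).
#' @param truth Planted-truth data frame (\code{gene_id}, \code{trait},
#'   \code{log2_effect}, \code{concordant}).
#' @return Data frame with one row per trait.
#' @export
recovery_metrics <- function(sets, truth) {
  do.call(rbind, lapply(names(sets), function(tr) {
    sel <- sets[[tr]]$gene_id
    tt <- truth[truth$trait == tr, , drop = FALSE]
    conc <- tt$gene_id[tt$concordant]
    disc <- tt$gene_id[!tt$concordant]
    data.frame(trait = tr, n_selected = length(sel),
               n_planted_concordant = length(conc),
               n_planted_discordant = length(disc),
               recovered = length(intersect(sel, conc)),
               recall = if (length(conc)) length(intersect(sel, conc)) / length(conc) else NA_real_,
               discordant_excluded = if (length(disc))
                 1 - length(intersect(sel, disc)) / length(disc) else NA_real_,
               precision = if (length(sel)) length(intersect(sel, conc)) / length(sel) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
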