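# Synthetic data with known planted truth. The generator reproduces the
# structure the analysis assumes: 9 sample groups x 3 biological replicates
# on a common gene universe, log-normal intensities with i.i.d. Gaussian
# replicate noise on the log2 scale, and trait-linked effects shared between
# the reference variety and its like-phenotype pool (the concordance rule
# that the three-way filter exploits).

#' The default olive architecture study design
#'
#' Nine sample groups: four varieties (Chiquitita, Picual, Arbequina,
#' Arbosana) and five seedling pools (SILe/LILe: short/long internode
#' length; SmaD/LarD: small/large trunk diameter; ChiCa: Chiquitita-like
#' canopy), with the three three-way designs used in the analysis --
#' internode length (SILe vs LILe, concordance Chiquitita vs SILe), trunk
#' diameter (SmaD vs LarD, concordance Chiquitita vs SmaD) and growth
#' habit (Chiquitita vs Arbosana, concordance Chiquitita vs ChiCa).
#'
#' @param alpha Gene-level significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2).
#' @return A \code{StudyDesign}.
#' @export
default_design <- function(alpha = 0.05, fc_threshold = 2) {
  groups <- data.frame(
    name = c("Chiquitita", "Picual", "Arbequina", "Arbosana",
             "SILe", "LILe", "SmaD", "LarD", "ChiCa"),
    role = c(rep("variety", 4L), rep("pool", 5L)),
    stringsAsFactors = FALSE)
  three_way <- data.frame(
    trait = c("internode_length", "trunk_diameter", "growth_habit"),
    primary_a = c("SILe", "SmaD", "Chiquitita"),
    primary_b = c("LILe", "LarD", "Arbosana"),
    concordance_a = c("Chiquitita", "Chiquitita", "Chiquitita"),
    concordance_b = c("SILe", "SmaD", "ChiCa"),
    stringsAsFactors = FALSE)
  study_design(groups, three_way, alpha = alpha, fc_threshold = fc_threshold)
}

#' Simulation parameters
#'
#' @param n_genes Number of genes (default 5000; the full-scale array has
#'   37449).
#' @param design A \code{StudyDesign}; defaults to \code{default_design()}.
#' @param replicates Biological replicates per group (default 3).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 intensity, drawn once per gene and shared across groups
#'   (defaults 8 and 2, typical of normalized array intensities).
#' @param replicate_sd Within-group replicate noise sd on the log2 scale
#'   (default 0.2, consistent with the high between-replicate correlations
#'   the analysis requires).
#' @param planted Data frame with one row per trait: \code{trait},
#'   \code{n_concordant}, \code{n_discordant}, \code{effect} (absolute
#'   log2 effect size). Defaults to 50 concordant, 0 discordant genes per
#'   design trait at |log2 effect| = 1.5. Planted sets are disjoint across
#'   traits.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A \code{SimulationParams} list.
#' @export
sim_params <- function(n_genes = 5000L, design = default_design(),
                       replicates = 3L,
                       baseline_log2_mean = 8, baseline_log2_sd = 2,
                       replicate_sd = 0.2, planted = NULL, seed = 1L) {
  stopifnot(inherits(design, "StudyDesign"))
  if (replicate_sd <= 0) stop("replicate_sd must be positive")
  if (is.null(planted)) {
    planted <- data.frame(trait = design$three_way$trait,
                          n_concordant = 50L, n_discordant = 0L,
                          effect = 1.5, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("trait", "n_concordant", "n_discordant", "effect")
                %in% names(planted)))
  if (!all(planted$trait %in% design$three_way$trait))
    stop("planted trait not present in design three_way")
  if (sum(planted$n_concordant + planted$n_discordant) > n_genes)
    stop("more planted genes requested than genes simulated")
  structure(list(n_genes = as.integer(n_genes), design = design,
                 replicates = as.integer(replicates),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 replicate_sd = replicate_sd, planted = planted,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Simulate an expression matrix with planted trait effects
#'
#' Linear-scale values are \code{2^(baseline + group effect + noise)}.
#' For each trait, concordant planted genes carry the signed log2 effect
#' identically in the reference variety and the like-phenotype pool (both
#' members of the concordance contrast), leaving the opposite-phenotype
#' group at baseline, so the three-way rule should recover them.
#' Discordant planted genes carry the effect in the like-phenotype pool
#' but the opposite effect in the reference variety, so the concordance
#' filter should reject them. Effect signs alternate so both over- and
#' under-expressed candidates occur.
#'
#' @param params A \code{SimulationParams}.
#' @return List with \code{matrix} (an \code{ExpressionMatrix}) and
#'   \code{truth}, a data frame (\code{gene_id}, \code{trait},
#'   \code{log2_effect}, \code{concordant}).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  des <- params$design
  gnames <- des$groups$name
  n_genes <- params$n_genes
  reps <- params$replicates
  gene_ids <- paste0("Contig_", seq_len(n_genes))

  baseline <- stats::rnorm(n_genes, params$baseline_log2_mean,
                           params$baseline_log2_sd)
  effect <- matrix(0, n_genes, length(gnames),
                   dimnames = list(gene_ids, gnames))

  # disjoint planted gene indices, allocated in gene order
  total <- sum(params$planted$n_concordant + params$planted$n_discordant)
  pool <- sample.int(n_genes, total)
  truth <- NULL
  cursor <- 0L
  for (i in seq_len(nrow(params$planted))) {
    p <- params$planted[i, ]
    tw <- des$three_way[des$three_way$trait == p$trait, ]
    like <- intersect(c(tw$primary_a, tw$primary_b),
                      c(tw$concordance_a, tw$concordance_b))
    if (length(like) != 1L)
      stop("three-way design for trait '", p$trait,
           "' must share exactly one group between its contrasts")
    partner <- setdiff(c(tw$concordance_a, tw$concordance_b), like)
    n_tot <- p$n_concordant + p$n_discordant
    if (!n_tot) next
    idx <- pool[cursor + seq_len(n_tot)]
    cursor <- cursor + n_tot
    signs <- rep_len(c(1, -1), n_tot)
    eff <- signs * p$effect
    conc <- rep(c(TRUE, FALSE), c(p$n_concordant, p$n_discordant))
    # like-phenotype pool always carries the effect
    effect[idx, like] <- effect[idx, like] + eff
    # reference partner: same effect if concordant, opposite if discordant
    effect[cbind(idx, match(partner, gnames))] <-
      effect[cbind(idx, match(partner, gnames))] + ifelse(conc, eff, -eff)
    truth <- rbind(truth, data.frame(
      gene_id = gene_ids[idx], trait = p$trait, log2_effect = eff,
      concordant = conc, stringsAsFactors = FALSE))
  }
  if (is.null(truth))
    truth <- data.frame(gene_id = character(), trait = character(),
                        log2_effect = numeric(), concordant = logical())

  log2_vals <- matrix(NA_real_, n_genes, length(gnames) * reps)
  cn <- character(ncol(log2_vals))
  for (g in seq_along(gnames)) {
    for (r in seq_len(reps)) {
      j <- (g - 1L) * reps + r
      log2_vals[, j] <- baseline + effect[, g] +
        stats::rnorm(n_genes, 0, params$replicate_sd)
      cn[j] <- paste0(gnames[g], "_r", r)
    }
  }
  dimnames(log2_vals) <- list(gene_ids, cn)
  list(matrix = expression_matrix(2^log2_vals), truth = truth)
}

#' Simulate a seedling phenotype table
#'
#' Per-seedling trunk diameter and five branch-mean internode lengths are
#' drawn from independent normals, emulating a segregating cross progeny
#' measured for architecture traits.
#'
#' @param n_seedlings Number of seedlings (the source cross had 120).
#' @param trait_means Named list: \code{diameter} (mm) and
#'   \code{internode} (mm, shared by the five branches). Defaults 75 and
#'   1.8, matching the range observed in the selected-seedling table.
#' @param trait_sds Matching sds (defaults 20 and 0.5); zero gives the
#'   degenerate all-identical table, negative values are an error.
#' @param seed Integer seed.
#' @param mother,pollen_donor Parent labels recorded per seedling.
#' @return A phenotype data frame (see \code{\link{load_phenotypes}} for
#'   the column layout).
#' @export
simulate_phenotypes <- function(n_seedlings = 120L,
                                trait_means = list(diameter = 75, internode = 1.8),
                                trait_sds = list(diameter = 20, internode = 0.5),
                                seed = 1L, mother = "Picual",
                                pollen_donor = "Arbequina") {
  if (trait_sds$diameter < 0 || trait_sds$internode < 0)
    stop("trait sds must be non-negative")
  set.seed(seed)
  rpos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), mean * 1e-3)
  branches <- matrix(rpos(n_seedlings * 5L, trait_means$internode,
                          trait_sds$internode), n_seedlings, 5L)
  colnames(branches) <- paste0("branch", 1:5, "_mm")
  data.frame(seedling_id = as.character(seq_len(n_seedlings)),
             mother = mother, pollen_donor = pollen_donor,
             diameter_mm = rpos(n_seedlings, trait_means$diameter,
                                trait_sds$diameter),
             branches, stringsAsFactors = FALSE)
}

#' Simulate a qPCR Ct table with known log2 expression ratios
#'
#' Emulates a two-sample comparison (e.g. reference variety vs comparator)
#' measured for a set of genes against a constitutive reference gene
#' (actin): the target Ct is the reference-gene Ct minus the log2 relative
#' expression, plus well noise, so \code{2^-(Ct_target - Ct_reference)}
#' recovers the planted ratio exactly when \code{ct_sd = 0}.
#'
#' @param genes Character vector of gene ids.
#' @param true_log2_ratios Planted log2 expression ratio of
#'   \code{sample_a} over \code{sample_b}, one per gene.
#' @param ct_sd Per-well Ct noise sd (cycles).
#' @param seed Integer seed.
#' @param samples Length-2 character vector of sample names; the ratio is
#'   sample 1 over sample 2.
#' @param n_bio,n_tech Biological and technical replicates (default 3 and 3).
#' @param reference_ct Mean Ct of the reference gene (default 20 cycles).
#' @return Data frame with columns \code{sample}, \code{biological_rep},
#'   \code{gene}, \code{tech_rep}, \code{ct_target}, \code{ct_reference}.
#' @export
simulate_ct_table <- function(genes, true_log2_ratios, ct_sd = 0.2, seed = 1L,
                              samples = c("Chiquitita", "Arbosana"),
                              n_bio = 3L, n_tech = 3L, reference_ct = 20) {
  stopifnot(length(genes) == length(true_log2_ratios), length(samples) == 2L)
  if (ct_sd < 0) stop("ct_sd must be non-negative")
  set.seed(seed)
  grid <- expand.grid(tech_rep = seq_len(n_tech), gene = genes,
                      biological_rep = seq_len(n_bio), sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ratio <- true_log2_ratios[match(grid$gene, genes)]
  base_ct <- ifelse(grid$sample == samples[[1L]],
                    reference_ct - ratio, reference_ct)
  grid$ct_target <- base_ct + stats::rnorm(nrow(grid), 0, ct_sd)
  grid$ct_reference <- reference_ct + stats::rnorm(nrow(grid), 0, ct_sd)
  grid[c("sample", "biological_rep", "gene", "tech_rep",
         "ct_target", "ct_reference")]
}
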