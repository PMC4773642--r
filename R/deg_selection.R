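# Core DEG analysis: replicate QC, per-gene two-group contrasts under the
# joint fold-change / t-test rule, three-way reference-concordance
# filtering, and Venn/union assembly of trait candidate sets.
#
# The selection rule is deliberately the classic microarray one: a gene is
# differentially expressed between groups A and B iff its two-tailed
# equal-variance Student t-test gives p < alpha AND the ratio of linear
# group means falls strictly outside [1/fc_threshold, fc_threshold]
# ("more than" a 2-fold change, so FC exactly 2 does not qualify). No
# gene-level multiple-testing correction is applied by default; FDR control
# belongs to the GO enrichment stage.

#' Pairwise Pearson correlation between biological replicates
#'
#' Replicate quality control: for every group, the Pearson correlation of
#' each pair of replicate columns computed on log2 intensities. Columns
#' with zero variance yield an undefined correlation, reported as NA with
#' a flag rather than an error.
#'
#' @param x An \code{ExpressionMatrix}.
#' @return Data frame: \code{group}, \code{rep_i}, \code{rep_j}, \code{r},
#'   \code{undefined}; plus a per-group minimum in attribute
#'   \code{"min_r"}.
#' @export
replicate_correlation <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lv <- log2(pmax(x$values, .Machine$double.xmin))
  out <- NULL
  for (g in unique(x$groups)) {
    idx <- which(x$groups == g)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      ca <- lv[, idx[a]]; cb <- lv[, idx[b]]
      und <- stats::sd(ca) == 0 || stats::sd(cb) == 0
      r <- if (und) NA_real_ else stats::cor(ca, cb)
      out <- rbind(out, data.frame(
        group = g, rep_i = x$replicates[idx[a]], rep_j = x$replicates[idx[b]],
        r = r, undefined = und, stringsAsFactors = FALSE))
    }
  }
  min_r <- tapply(out$r, out$group, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  attr(out, "min_r") <- min_r
  out
}

#' Per-gene two-group contrast (fold change + Student t-test)
#'
#' For every gene: linear-scale group means, fold change
#' \code{mean_a / mean_b}, a two-tailed equal-variance two-sample t-test
#' with \code{df = n_a + n_b - 2} (run on log2-transformed replicate
#' values by default, or on the linear values with
#' \code{test_scale = "linear"}), and the joint DEG call.
#'
#' Degenerate genes (zero pooled variance) get p = 1 when the group means
#' are equal and p = 0 (with a warning) when they differ.
#'
#' @param x An \code{ExpressionMatrix} of positive linear intensities.
#' @param group_a,group_b Group names; fold change is A over B.
#' @param alpha Significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2); the DEG window
#'   is strict: FC > threshold or FC < 1/threshold.
#' @param test_scale \code{"log2"} (default) or \code{"linear"} scale for
#'   the t-test; fold change always uses linear means.
#' @param bh If \code{TRUE}, additionally apply Benjamini-Hochberg
#'   adjustment and call DEGs on the adjusted values (off by default).
#' @return A \code{ContrastResult}: data frame with \code{gene_id},
#'   \code{mean_a}, \code{mean_b}, \code{fold_change}, \code{log2_fc},
#'   \code{t}, \code{df}, \code{p_value}, \code{is_deg} and contrast
#'   metadata in attributes.
#' @export
two_group_contrast <- function(x, group_a, group_b, alpha = 0.05,
                               fc_threshold = 2, test_scale = c("log2", "linear"),
                               bh = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  test_scale <- match.arg(test_scale)
  ia <- group_columns(x, group_a); ib <- group_columns(x, group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need >=2 replicates")
  va <- x$values[, ia, drop = FALSE]; vb <- x$values[, ib, drop = FALSE]
  if (any(va <= 0) || any(vb <= 0))
    stop("expression values must be strictly positive for contrast analysis")
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  fc <- mean_a / mean_b

  ta <- if (test_scale == "log2") log2(va) else va
  tb <- if (test_scale == "log2") log2(vb) else vb
  na <- ncol(ta); nb <- ncol(tb); df <- na + nb - 2L
  ma <- rowMeans(ta); mb <- rowMeans(tb)
  ssa <- rowSums((ta - ma)^2); ssb <- rowSums((tb - mb)^2)
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & (ma == mb)
    tt[eq] <- 0; p[eq] <- 1
    ne <- degenerate & (ma != mb)
    if (any(ne)) {
      warning(sum(ne), " gene(s) with zero pooled variance but unequal means; p set to 0")
      tt[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0
    }
  }
  p_used <- if (bh) stats::p.adjust(p, method = "BH") else p
  is_deg <- (p_used < alpha) & (fc > fc_threshold | fc < 1 / fc_threshold)
  res <- data.frame(gene_id = x$gene_ids, mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, log2_fc = log2(fc), t = tt, df = df,
                    p_value = p, is_deg = is_deg,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (bh) res$q_value <- p_used
  attr(res, "group_a") <- group_a; attr(res, "group_b") <- group_b
  attr(res, "alpha") <- alpha; attr(res, "fc_threshold") <- fc_threshold
  attr(res, "test_scale") <- test_scale
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Three-way concordance selection of candidate genes
#'
#' The selection rule of the pooled-phenotype design: keep genes that are
#' differentially expressed between the opposite-phenotype groups
#' (primary contrast) AND whose expression is not significantly different
#' in the concordance contrast between the reference variety and the
#' like-phenotype group (concordance p >= alpha, significance only -- the
#' fold change plays no role in the filter). Direction is taken from the
#' sign of the primary log2 fold change (\code{"over"} means higher in
#' the first primary group).
#'
#' @param primary,concordance \code{ContrastResult}s over the same gene
#'   universe (same ids, same order).
#' @param alpha Threshold for the concordance non-significance test;
#'   defaults to the primary contrast's alpha.
#' @param trait Trait label attached to the resulting set.
#' @return A \code{CandidateSet}: data frame with \code{gene_id},
#'   \code{trait}, \code{direction}, \code{fold_change}, \code{p_value}
#'   (all from the primary contrast) plus provenance attributes.
#' @export
three_way_select <- function(primary, concordance, alpha = NULL,
                             trait = "trait") {
  stopifnot(inherits(primary, "ContrastResult"),
            inherits(concordance, "ContrastResult"))
  if (!identical(primary$gene_id, concordance$gene_id))
    stop("primary and concordance contrasts cover different gene universes")
  if (is.null(alpha)) alpha <- attr(primary, "alpha")
  sel <- primary$is_deg & concordance$p_value >= alpha
  res <- data.frame(
    gene_id = primary$gene_id[sel], trait = trait,
    direction = ifelse(primary$log2_fc[sel] > 0, "over", "under"),
    fold_change = primary$fold_change[sel],
    p_value = primary$p_value[sel],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "trait") <- trait
  attr(res, "primary") <- paste(attr(primary, "group_a"), "vs",
                                attr(primary, "group_b"))
  attr(res, "concordance") <- paste(attr(concordance, "group_a"), "vs",
                                    attr(concordance, "group_b"))
  attr(res, "alpha") <- alpha
  class(res) <- c("CandidateSet", "data.frame")
  res
}

#' Build a candidate set directly from gene ids
#'
#' Convenience constructor used when sets come from an external source
#' (e.g. published counts) rather than from contrasts.
#'
#' @param gene_ids Character vector of member gene ids.
#' @param trait Trait label.
#' @param direction Per-gene direction (recycled; default "over").
#' @param fold_change,p_value Optional per-gene statistics (recycled).
#' @return A \code{CandidateSet}.
#' @export
candidate_set <- function(gene_ids, trait, direction = "over",
                          fold_change = NA_real_, p_value = NA_real_) {
  if (anyDuplicated(gene_ids)) stop("candidate set has duplicate gene ids")
  res <- data.frame(gene_id = gene_ids, trait = trait,
                    direction = rep_len(direction, length(gene_ids)),
                    fold_change = rep_len(fold_change, length(gene_ids)),
                    p_value = rep_len(p_value, length(gene_ids)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "trait") <- trait
  class(res) <- c("CandidateSet", "data.frame")
  res
}

#' Venn summary of three candidate sets
#'
#' Exact set algebra over three gene sets: individual sizes, all pairwise
#' intersection sizes, the triple intersection, and the union, with the
#' inclusion-exclusion identity holding exactly. The explicit union
#' membership is returned alongside the counts.
#'
#' @param sets Named list of exactly three \code{CandidateSet}s or
#'   character vectors of gene ids.
#' @return List with \code{sizes}, \code{pairwise} (named
#'   \code{"A&B"} etc.), \code{triple}, \code{union_size} and
#'   \code{union} (character vector).
#' @export
venn_summary <- function(sets) {
  if (length(sets) != 3L) stop("venn_summary expects exactly three sets")
  ids <- lapply(sets, function(s)
    unique(if (inherits(s, "CandidateSet") || is.data.frame(s)) s$gene_id else s))
  nm <- names(ids)
  if (is.null(nm) || any(!nzchar(nm))) nm <- c("A", "B", "C")
  sizes <- vapply(ids, length, 1L); names(sizes) <- nm
  pair <- c(length(intersect(ids[[1]], ids[[2]])),
            length(intersect(ids[[1]], ids[[3]])),
            length(intersect(ids[[2]], ids[[3]])))
  names(pair) <- c(paste(nm[1], nm[2], sep = "&"),
                   paste(nm[1], nm[3], sep = "&"),
                   paste(nm[2], nm[3], sep = "&"))
  triple <- length(Reduce(intersect, ids))
  u <- unique(unlist(ids, use.names = FALSE))
  stopifnot(length(u) == sum(sizes) - sum(pair) + triple)
  list(sizes = sizes, pairwise = pair, triple = triple,
       union_size = length(u), union = u)
}
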