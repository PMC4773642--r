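# qPCR validation: delta-Ct relative expression, microarray/qPCR log-ratio
# concordance with the analytic Pearson critical value, and per-sample
# comparison by one-way ANOVA with 95% LSD multiple-range letter grouping.

#' Relative expression by the delta-Ct method
#'
#' \code{2^-(Ct_target - Ct_reference)}, with technical replicates
#' averaged at the Ct level first. Assumes an amplification efficiency of
#' 2 per cycle (pure delta-Ct, no efficiency correction).
#'
#' @param ct_target Ct value(s) of the target gene (technical replicates
#'   averaged if a vector).
#' @param ct_reference Ct value(s) of the constitutive reference gene
#'   (e.g. actin).
#' @return Dimensionless relative expression ratio.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!length(ct_reference) || anyNA(ct_reference))
    stop("reference-gene Ct values are required")
  if (anyNA(ct_target) || any(!is.finite(c(ct_target, ct_reference))) ||
      any(c(ct_target, ct_reference) <= 0))
    stop("Ct values must be positive and finite")
  2^(-(mean(ct_target) - mean(ct_reference)))
}

#' Per-gene log2 expression ratios from a Ct table
#'
#' For each gene and biological replicate, technical replicates are
#' averaged at the Ct level and converted to relative expression by
#' delta-Ct; biological replicates are then summarized as the mean of the
#' log2 values (preserving the geometric structure of ratios). The
#' returned log2 ratio is sample_a over sample_b.
#'
#' @param ct_table Data frame as produced by
#'   \code{\link{simulate_ct_table}} (columns \code{sample},
#'   \code{biological_rep}, \code{gene}, \code{tech_rep},
#'   \code{ct_target}, \code{ct_reference}).
#' @param sample_a,sample_b Sample names; ratio is A over B.
#' @return Named numeric vector of log2 ratios, one per gene.
#' @export
qpcr_log2_ratios <- function(ct_table, sample_a, sample_b) {
  needed <- c("sample", "biological_rep", "gene", "tech_rep",
              "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(ct_table)))
  per_bio <- function(sub) {
    if (nrow(sub) < 3L)
      warning("fewer than 3 technical replicates for gene ", sub$gene[[1L]])
    log2(relative_expression(sub$ct_target, sub$ct_reference))
  }
  mean_log2 <- function(smp, gene) {
    sub <- ct_table[ct_table$sample == smp & ct_table$gene == gene, ]
    if (!nrow(sub)) stop("no Ct rows for sample ", smp, ", gene ", gene)
    mean(vapply(split(sub, sub$biological_rep), per_bio, numeric(1L)))
  }
  genes <- unique(ct_table$gene)
  out <- vapply(genes, function(g)
    mean_log2(sample_a, g) - mean_log2(sample_b, g), numeric(1L))
  names(out) <- genes
  out
}

#' Analytic Pearson critical value
#'
#' \code{r_crit = t / sqrt(t^2 + df)} with \code{df = n - 2} and \code{t}
#' the Student quantile at the chosen alpha; single-tailed by default.
#'
#' @param n Number of pairs.
#' @param alpha Significance level (default 0.005).
#' @param tails 1 (default) or 2.
#' @return Critical absolute correlation.
#' @export
pearson_critical <- function(n, alpha = 0.005, tails = 1L) {
  if (n < 3L) stop("need at least 3 pairs")
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2")
  df <- n - 2L
  tq <- stats::qt(1 - alpha / tails, df)
  tq / sqrt(tq^2 + df)
}

#' Concordance between microarray and qPCR log ratios
#'
#' Pearson correlation of paired log2 expression ratios measured by the
#' two methods, compared against the analytic critical value
#' \code{t / sqrt(t^2 + df)}; the correlation is significant when
#' \code{|r|} exceeds it.
#'
#' @param log2_qpcr,log2_array Paired numeric vectors (n >= 3).
#' @param alpha Significance level (default 0.005).
#' @param tails 1 (default) or 2 tails for the critical value.
#' @return List: \code{r}, \code{n}, \code{r_critical},
#'   \code{significant}, \code{undefined} (TRUE when either vector has
#'   zero variance, in which case r is NA).
#' @export
concordance <- function(log2_qpcr, log2_array, alpha = 0.005, tails = 1L) {
  if (length(log2_qpcr) != length(log2_array))
    stop("paired vectors must have equal length")
  n <- length(log2_qpcr)
  if (n < 3L) stop("need at least 3 pairs")
  undefined <- stats::sd(log2_qpcr) == 0 || stats::sd(log2_array) == 0
  r <- if (undefined) NA_real_ else stats::cor(log2_qpcr, log2_array)
  rc <- pearson_critical(n, alpha, tails)
  list(r = r, n = n, r_critical = rc,
       significant = !undefined && abs(r) > rc, undefined = undefined)
}

#' One-way ANOVA with 95% LSD multiple-range letter grouping
#'
#' Fits a one-way ANOVA across sample groups; if the ANOVA is significant
#' at \code{alpha}, performs all pairwise comparisons with Fisher's least
#' significant difference
#' \code{LSD = t(alpha/2, df_error) * sqrt(MSE * (1/ni + 1/nj))} and
#' summarizes them as letter groups (groups sharing a letter are not
#' significantly different). If the ANOVA is not significant, all groups
#' share one letter.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 replicates).
#' @param alpha Significance level (default 0.05, i.e. 95\% LSD).
#' @return An \code{LsdGrouping} list: \code{summary} data frame
#'   (\code{group}, \code{n}, \code{mean}, \code{letters}, ordered by
#'   descending mean), \code{F}, \code{p}, \code{df_error}, \code{MSE},
#'   \code{alpha}.
#' @export
anova_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 replicates")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df_error <- length(y) - length(groups)
  if (df_error <= 0) stop("zero error degrees of freedom")
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1L]]
  Fv <- an[["F value"]][[1L]]; p <- an[["Pr(>F)"]][[1L]]
  mse <- an[["Mean Sq"]][[2L]]

  means <- vapply(groups, mean, numeric(1L))
  ns <- lengths(groups)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ns <- ns[ord]; gnames <- names(groups)[ord]
  kk <- length(gnames)

  if (!is.na(p) && p < alpha) {
    tq <- stats::qt(1 - alpha / 2, df_error)
    differ <- matrix(FALSE, kk, kk)
    for (i in seq_len(kk)) for (j in seq_len(kk)) if (i != j) {
      lsd <- tq * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      differ[i, j] <- abs(means[i] - means[j]) > lsd
    }
  } else {
    differ <- matrix(FALSE, kk, kk)
  }
  letters_vec <- lsd_letters(differ)
  structure(list(summary = data.frame(group = gnames, n = as.integer(ns),
                                      mean = unname(means),
                                      letters = letters_vec,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 F = Fv, p = p, df_error = df_error, MSE = mse,
                 alpha = alpha),
            class = "LsdGrouping")
}

# Letter assignment over groups ordered by descending mean: every maximal
# clique of the "not significantly different" graph gets one letter, so
# two groups share a letter iff they are pairwise non-different. With
# unequal group sizes the per-pair LSD varies, so the relation need not be
# interval-like along the mean ordering; a clique cover is exact. Group
# counts here are small (a handful of samples), so plain Bron-Kerbosch
# enumeration is adequate.
lsd_letters <- function(differ) {
  k <- nrow(differ)
  nonsig <- !differ; diag(nonsig) <- TRUE
  cliques <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1L]] <<- r
      return()
    }
    for (v in p) {
      nb <- setdiff(which(nonsig[v, ]), v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v); x <- c(x, v)
    }
  }
  bk(integer(), seq_len(k), integer())
  cliques <- cliques[order(vapply(cliques, min, 1L))]
  out <- character(k)
  for (s in seq_along(cliques)) {
    idx <- cliques[[s]]
    out[idx] <- paste0(out[idx], letters[(s - 1L) %% 26L + 1L])
  }
  out
}

#' @export
print.LsdGrouping <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (df error %d); 95%% LSD letters:\n",
              x$F, x$p, x$df_error))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
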