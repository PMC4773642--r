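# Candidate-set validation statistics: the random same-size gene-set
# Kruskal-Wallis null and the Poisson model for Venn-overlap significance.

#' Kruskal-Wallis validation of a candidate set against random sets
#'
#' Tests whether expression of a candidate gene set differs across the
#' sample groups of the whole study, and calibrates that test against
#' random gene sets of the same size drawn uniformly (without
#' replacement) from the full gene universe. The observation unit is the
#' per-gene, per-group mean of log2 expression over replicates, with the
#' study groups as the Kruskal-Wallis factor; a trait-linked candidate
#' set concentrates group-specific shifts and turns significant, while
#' same-size random sets behave like the null.
#'
#' @param x An \code{ExpressionMatrix}.
#' @param gene_set Character vector of candidate gene ids (>= 2, subset of
#'   the matrix genes).
#' @param n_random Number of random same-size sets (default 1000).
#' @param seed Integer seed for the random draws.
#' @param alpha Significance threshold used in the summary (default 0.05).
#' @return A \code{KWValidationReport} list: \code{set_size},
#'   \code{candidate} (H, p), \code{random} data frame of (H, p),
#'   \code{median_random_p}, \code{frac_random_significant},
#'   \code{n_random}, \code{seed}.
#' @export
kw_set_validation <- function(x, gene_set, n_random = 1000L, seed = 1L,
                              alpha = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (length(gene_set) < 2L) stop("candidate set must contain >= 2 genes")
  if (!all(gene_set %in% x$gene_ids))
    stop("candidate set contains genes absent from the matrix")
  if (n_random < 1L) stop("n_random must be >= 1")

  lv <- log2(x$values)
  gnames <- unique(x$groups)
  # genes x groups matrix of replicate-mean log2 expression
  gm <- vapply(gnames, function(g)
    rowMeans(lv[, x$groups == g, drop = FALSE]), numeric(nrow(lv)))
  grp_factor <- factor(rep(gnames, each = length(gene_set)), levels = gnames)

  kw <- function(idx) {
    obs <- as.vector(gm[idx, , drop = FALSE])
    k <- stats::kruskal.test(obs, grp_factor)
    c(H = unname(k$statistic), p = k$p.value)
  }
  cand_idx <- match(gene_set, x$gene_ids)
  cand <- kw(cand_idx)

  set.seed(seed)
  rnd <- t(vapply(seq_len(n_random), function(i)
    kw(sample.int(nrow(lv), length(gene_set))), numeric(2L)))
  rnd <- as.data.frame(rnd)
  structure(list(set_size = length(gene_set),
                 candidate = list(H = cand[["H"]], p = cand[["p"]]),
                 random = rnd,
                 median_random_p = stats::median(rnd$p),
                 frac_random_significant = mean(rnd$p < alpha),
                 n_random = n_random, seed = seed, alpha = alpha),
            class = "KWValidationReport")
}

#' @export
print.KWValidationReport <- function(x, ...) {
  cat(sprintf(paste0("KW set validation: size %d, candidate p = %.3g; ",
                     "%d random sets: median p = %.3g, %.1f%% significant at %g\n"),
              x$set_size, x$candidate$p, x$n_random, x$median_random_p,
              100 * x$frac_random_significant, x$alpha))
  invisible(x)
}

# exact upper Poisson tail P(X >= k) = sum_{j>=k} e^-lambda lambda^j / j!
# by direct series summation with a multiplicative term recurrence; no
# normal approximation and no 1-minus-lower-tail cancellation.
poisson_upper_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  if (lambda == 0) return(0)
  term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  total <- term
  j <- k
  repeat {
    j <- j + 1L
    term <- term * lambda / j
    total <- total + term
    if (term < total * 1e-18 || j > k + 100000L) break
  }
  min(1, total)
}

#' Poisson overlap significance for two gene sets
#'
#' Models the observed overlap of two candidate sets of sizes nA and nB in
#' a universe of N genes as Poisson with rate \code{lambda = nA * nB / N}
#' (the expected overlap under independent uniform draws) and reports the
#' exact upper tail \code{P(X >= k)} by direct series summation.
#'
#' @param nA,nB Set sizes (each <= N).
#' @param N Universe size (the number of genes on the array; > 0).
#' @param k_observed Observed overlap (<= min(nA, nB)).
#' @param label Optional pair label for reporting.
#' @return An \code{OverlapReport} list: \code{label}, \code{nA},
#'   \code{nB}, \code{N}, \code{k}, \code{lambda}, \code{p}.
#' @export
poisson_overlap_p <- function(nA, nB, N, k_observed, label = "") {
  if (N <= 0) stop("universe size N must be positive")
  if (nA > N || nB > N) stop("set sizes cannot exceed the universe size")
  if (k_observed > min(nA, nB)) stop("overlap cannot exceed the smaller set")
  if (k_observed < 0) stop("overlap must be non-negative")
  lambda <- nA * nB / N
  structure(list(label = label, nA = nA, nB = nB, N = N, k = k_observed,
                 lambda = lambda, p = poisson_upper_tail(k_observed, lambda)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("Overlap %s: k = %d of nA=%d, nB=%d in N=%d; lambda = %.4g, P(X>=k) = %.4g\n",
              x$label, x$k, x$nA, x$nB, x$N, x$lambda, x$p))
  invisible(x)
}

#' Hypergeometric overlap tail (reference model)
#'
#' Exact \code{P(X >= k)} for the overlap of a uniform random nA-subset
#' with a fixed nB-subset of an N-gene universe. Serves as the reference
#' model the Poisson approximation is checked against; the two agree when
#' nA and nB are small relative to N.
#'
#' @param nA,nB,N,k As in \code{\link{poisson_overlap_p}}.
#' @return Upper-tail probability.
#' @export
hypergeometric_overlap_p <- function(nA, nB, N, k) {
  if (N <= 0) stop("universe size N must be positive")
  if (nA > N || nB > N) stop("set sizes cannot exceed the universe size")
  if (k > min(nA, nB)) stop("overlap cannot exceed the smaller set")
  if (k <= 0) return(1)
  stats::phyper(k - 1, nB, N - nB, nA, lower.tail = FALSE)
}
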