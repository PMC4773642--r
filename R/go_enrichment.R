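# Generic GO over/under-representation engine: per-term 2x2 Fisher's exact
# test of a candidate set against the array background, Benjamini-Hochberg
# FDR over all tested terms, optional true-path propagation along an
# ontology edge list.

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the standard point-probability rule: with
#' margins fixed, sum the hypergeometric probabilities of every table
#' whose point probability does not exceed that of the observed table
#' (comparison made with a 1e-7 relative tolerance, the usual convention).
#' All-zero margins give p = 1.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise) of non-negative
#'   integer counts.
#' @return Two-sided p-value.
#' @export
fisher_two_tailed <- function(table) {
  x <- as.vector(t(table))
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    stop("fisher_two_tailed needs a 2x2 table of non-negative integers")
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  kcol <- a + c_      # column 1 margin
  if (m + n == 0L || kcol + b + d == 0L) return(1)
  support <- max(0L, kcol - n):min(kcol, m)
  dens <- stats::dhyper(support, m, n, kcol)
  obs <- stats::dhyper(a, m, n, kcol)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust}); each q-value follows its p-value under
#' permutation of the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

propagate_annotations <- function(annotations, edges) {
  # true-path rule: a gene annotated to a term is annotated to all its
  # ancestors; edges is data.frame(child, parent)
  parents <- split(edges$parent, edges$child)
  lapply(annotations, function(terms) {
    seen <- character(); frontier <- terms
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), seen)
    }
    sort(seen)
  })
}

#' GO term enrichment of a candidate set
#'
#' For every term annotated in the background, builds the 2x2 table
#' (candidate genes with/without the term vs background-only genes
#' with/without it), applies the two-tailed Fisher test, and adjusts over
#' all tested terms with Benjamini-Hochberg. Direction is
#' \code{"over"} when the in-set term frequency exceeds the background
#' frequency.
#'
#' @param candidate Character vector of candidate gene ids or a
#'   \code{CandidateSet}; must be a subset of \code{background}.
#' @param annotations Named list gene id -> character vector of term ids
#'   (see \code{\link{load_annotations}}).
#' @param background Character vector: the gene universe (e.g. all genes
#'   on the array, or all annotated genes).
#' @param cutoff FDR cutoff for the significant subset (default 0.05).
#' @param ontology Optional data frame (\code{child}, \code{parent}) of
#'   ontology edges; when supplied, annotations are propagated to
#'   ancestors before testing.
#' @return List with \code{table} (all tested terms: \code{term},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{q},
#'   \code{direction}, \code{significant}) and \code{significant} (rows
#'   with q < cutoff).
#' @export
enrich <- function(candidate, annotations, background, cutoff = 0.05,
                   ontology = NULL) {
  if (inherits(candidate, "CandidateSet") || is.data.frame(candidate))
    candidate <- candidate$gene_id
  candidate <- unique(candidate); background <- unique(background)
  if (!all(candidate %in% background))
    stop("candidate set must be a subset of the background universe")
  if (!is.null(ontology))
    annotations <- propagate_annotations(annotations, ontology)
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  annotations <- annotations[intersect(names(annotations), background)]
  kept_terms <- unique(unlist(annotations, use.names = FALSE))
  skipped <- length(setdiff(all_terms, kept_terms))
  if (skipped)
    message(skipped, " term(s) absent from the background skipped")
  if (!length(annotations))
    return(list(table = data.frame(), significant = data.frame(),
                skipped = skipped))

  gene2term <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE), stringsAsFactors = FALSE)
  terms <- sort(unique(gene2term$term))
  K <- length(candidate); N <- length(background)
  in_set <- gene2term$gene %in% candidate
  k_by_term <- table(factor(gene2term$term[in_set], levels = terms))
  n_by_term <- table(factor(gene2term$term, levels = terms))

  p <- vapply(seq_along(terms), function(i) {
    k <- as.integer(k_by_term[[i]]); n <- as.integer(n_by_term[[i]])
    fisher_two_tailed(matrix(c(k, K - k, n - k, N - K - (n - k)), 2L,
                             byrow = TRUE))
  }, numeric(1L))
  q <- bh_fdr(p)
  tab <- data.frame(
    term = terms, k = as.integer(k_by_term), K = K,
    n = as.integer(n_by_term), N = N, p = p, q = q,
    direction = ifelse(as.integer(k_by_term) / K > as.integer(n_by_term) / N,
                       "over", "under"),
    significant = q < cutoff, row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$q, tab$p, tab$term), , drop = FALSE]
  list(table = tab, significant = tab[tab$significant, , drop = FALSE],
       skipped = skipped)
}
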