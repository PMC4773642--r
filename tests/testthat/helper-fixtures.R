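# Shared fixture builders. Everything is generated in code at test time.

# Build an ExpressionMatrix from a named list of per-group replicate value
# lists: make_mat(list(A = list(c(...), c(...)), B = ...)) where each inner
# vector is one replicate column (one value per gene).
make_mat <- function(groups, gene_ids = NULL) {
  cols <- list(); cn <- character()
  for (g in names(groups)) {
    for (r in seq_along(groups[[g]])) {
      cols[[length(cols) + 1L]] <- groups[[g]][[r]]
      cn <- c(cn, paste0(g, "_r", r))
    }
  }
  m <- do.call(cbind, cols)
  if (is.null(gene_ids)) gene_ids <- paste0("Contig_", seq_len(nrow(m)))
  dimnames(m) <- list(gene_ids, cn)
  expression_matrix(m)
}

# Replicate the same per-gene vector with additive offsets per replicate.
make_group <- function(base, offsets = c(0, 0, 0)) {
  lapply(offsets, function(o) base + o)
}

# Independent pooled-variance t-test oracle for one gene (brute force).
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b); df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Construct three gene-id sets realizing given sizes and overlaps
# (pairwise AB, AC, BC and triple), over a synthetic id universe.
make_venn_sets <- function(nA, nB, nC, nAB, nAC, nBC, nABC) {
  id <- function(n, prefix) if (n > 0) paste0(prefix, seq_len(n)) else character()
  triple <- id(nABC, "t")
  ab <- id(nAB - nABC, "ab"); ac <- id(nAC - nABC, "ac"); bc <- id(nBC - nABC, "bc")
  onlyA <- id(nA - nAB - nAC + nABC, "a")
  onlyB <- id(nB - nAB - nBC + nABC, "b")
  onlyC <- id(nC - nAC - nBC + nABC, "c")
  list(A = c(onlyA, ab, ac, triple),
       B = c(onlyB, ab, bc, triple),
       C = c(onlyC, ac, bc, triple))
}

pheno_fixture_path <- function() {
  system.file("extdata", "seedling_phenotypes.tsv", package = "poolDEG")
}
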