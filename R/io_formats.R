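# On-disk artifacts. One dialect only: tab-separated, UTF-8, header row.
# Expression sample columns are named "<group>_r<k>" (k is 1-based), so the
# file header carries the whole design.

#' Construct an expression matrix object
#'
#' Wraps a numeric matrix of normalized, linear-scale intensities
#' (genes x sample-replicates) whose column names follow the
#' \code{"<group>_r<k>"} convention, and validates the invariants every
#' downstream stage relies on: unique non-empty gene identifiers, at least
#' two replicate columns per group, strictly finite non-negative values.
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns named \code{"<group>_r<k>"}.
#' @return An object of class \code{ExpressionMatrix}: a list with
#'   \code{values}, \code{gene_ids}, \code{groups} (character, per column)
#'   and \code{replicates} (integer, per column).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  gene_ids <- rownames(values)
  if (is.null(gene_ids) || any(!nzchar(gene_ids)))
    stop("gene ids (rownames) must be present and non-empty")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id: ", dup[[1L]])
  cols <- colnames(values)
  if (is.null(cols))
    stop("sample columns must be named '<group>_r<k>'")
  parsed <- parse_sample_names(cols)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene '%s', column '%s'",
                 gene_ids[bad[[1L]]], cols[bad[[2L]]]))
  }
  tab <- table(parsed$group)
  if (any(tab < 2L))
    stop("every group needs >=2 replicate columns; offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(list(values = values,
                 gene_ids = gene_ids,
                 groups = parsed$group,
                 replicates = parsed$replicate),
            class = "ExpressionMatrix")
}

parse_sample_names <- function(cols) {
  m <- regmatches(cols, regexec("^(.+)_r([0-9]+)$", cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("sample column not of the form '<group>_r<k>': ", cols[bad][[1L]])
  list(group = vapply(m, `[[`, "", 2L),
       replicate = as.integer(vapply(m, `[[`, "", 3L)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d groups)\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Columns of an expression matrix belonging to one group
#' @param x An \code{ExpressionMatrix}.
#' @param group Group name.
#' @return Integer column indices.
#' @export
group_columns <- function(x, group) {
  idx <- which(x$groups == group)
  if (!length(idx)) stop("group not present in matrix: ", group)
  idx
}

#' Read a normalized expression matrix from TSV
#'
#' The file must have a \code{gene_id} first column and sample columns named
#' \code{"<group>_r<k>"}. Loading is strict: duplicate ids, missing values,
#' negative or non-numeric cells, or a group with a single replicate are
#' hard errors -- rows are never silently dropped.
#'
#' @param path Path to a tab-separated file.
#' @return An \code{ExpressionMatrix}; column order is preserved.
#' @export
load_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || names(df)[[1L]] != "gene_id")
    stop("expression TSV must start with a 'gene_id' header column")
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gene_ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at row %d ('%s'), column '%s'",
                 bad[[1L]], gene_ids[bad[[1L]]], colnames(num)[bad[[2L]]]))
  }
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#' @param x An \code{ExpressionMatrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a study design
#'
#' @param groups Data frame with columns \code{name} and \code{role}
#'   (\code{"variety"} or \code{"pool"}).
#' @param three_way Data frame with columns \code{trait},
#'   \code{primary_a}, \code{primary_b}, \code{concordance_a},
#'   \code{concordance_b}; may have zero rows.
#' @param alpha Gene-level significance threshold, in (0, 1).
#' @param fc_threshold Fold-change ratio threshold, > 1; a gene must fall
#'   outside \code{[1/fc_threshold, fc_threshold]} to qualify.
#' @return A \code{StudyDesign} object.
#' @export
study_design <- function(groups, three_way = NULL, alpha = 0.05,
                         fc_threshold = 2) {
  stopifnot(is.data.frame(groups), all(c("name", "role") %in% names(groups)))
  if (anyDuplicated(groups$name)) stop("duplicate group name in design")
  if (!all(groups$role %in% c("variety", "pool")))
    stop("group role must be 'variety' or 'pool'")
  if (is.null(three_way))
    three_way <- data.frame(trait = character(), primary_a = character(),
                            primary_b = character(), concordance_a = character(),
                            concordance_b = character())
  needed <- c("trait", "primary_a", "primary_b", "concordance_a", "concordance_b")
  stopifnot(is.data.frame(three_way), all(needed %in% names(three_way)))
  used <- unlist(three_way[c("primary_a", "primary_b",
                             "concordance_a", "concordance_b")],
                 use.names = FALSE)
  unknown <- setdiff(used, groups$name)
  if (length(unknown))
    stop("contrast names group(s) absent from design: ",
         paste(unique(unknown), collapse = ", "))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop("fc_threshold must exceed 1")
  structure(list(groups = groups, three_way = three_way,
                 alpha = alpha, fc_threshold = fc_threshold),
            class = "StudyDesign")
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat(sprintf("StudyDesign: %d groups, %d three-way designs, alpha=%g, FC>%g\n",
              nrow(x$groups), nrow(x$three_way), x$alpha, x$fc_threshold))
  invisible(x)
}

#' Read a study design from a YAML config
#'
#' Schema: top-level keys \code{groups} (list of \code{name}/\code{role}
#' maps), \code{three_way} (list of maps with \code{trait},
#' \code{primary} = [A, B], \code{concordance} = [C, D]), and optional
#' \code{alpha} (default 0.05) and \code{fc_threshold} (default 2).
#'
#' @param path Path to the YAML file.
#' @return A validated \code{StudyDesign}.
#' @export
load_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("design config lacks a 'groups' section")
  groups <- data.frame(
    name = vapply(cfg$groups, function(g) as.character(g$name), ""),
    role = vapply(cfg$groups, function(g) as.character(g$role), ""),
    stringsAsFactors = FALSE)
  tw <- cfg$three_way
  three_way <- if (is.null(tw) || !length(tw)) NULL else data.frame(
    trait = vapply(tw, function(d) as.character(d$trait), ""),
    primary_a = vapply(tw, function(d) as.character(d$primary[[1L]]), ""),
    primary_b = vapply(tw, function(d) as.character(d$primary[[2L]]), ""),
    concordance_a = vapply(tw, function(d) as.character(d$concordance[[1L]]), ""),
    concordance_b = vapply(tw, function(d) as.character(d$concordance[[2L]]), ""),
    stringsAsFactors = FALSE)
  study_design(groups, three_way,
               alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
               fc_threshold = if (is.null(cfg$fc_threshold)) 2 else cfg$fc_threshold)
}

#' Read gene-to-GO annotations from a two-column TSV
#'
#' Column 1 is the gene id, column 2 a comma-separated list of GO term ids.
#' Duplicate (gene, term) pairs are collapsed; a gene on several lines gets
#' the union of its terms.
#'
#' @param path Path to the annotation TSV (no header).
#' @return Named list mapping gene id to a character vector of terms.
#' @export
load_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 2L))
    stop("malformed annotation line ", which(nf != 2L)[[1L]],
         ": expected 2 tab-separated fields")
  genes <- vapply(parts, `[[`, "", 1L)
  terms <- strsplit(vapply(parts, `[[`, "", 2L), ",", fixed = TRUE)
  terms <- lapply(terms, function(t) unique(trimws(t)))
  if (any(vapply(terms, function(t) any(!nzchar(t)), TRUE)))
    stop("empty GO term identifier in annotation file")
  out <- tapply(terms, genes, function(ts) sort(unique(unlist(ts))),
                simplify = FALSE)
  out[unique(genes)]  # preserve first-seen gene order
}

#' Write candidate gene sets to TSV
#'
#' One row per (trait, gene): \code{gene_id}, \code{trait},
#' \code{direction}, \code{fold_change}, \code{p_value}, ordered by trait
#' then gene id so output is deterministic.
#'
#' @param sets A list of \code{CandidateSet} objects (see
#'   \code{\link{three_way_select}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidate_table <- function(sets, path) {
  cols <- c("gene_id", "trait", "direction", "fold_change", "p_value")
  if (!length(sets)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(sets, function(s) {
    stopifnot(inherits(s, "CandidateSet"))
    as.data.frame(unclass(s), stringsAsFactors = FALSE)[cols]
  }))
  df <- df[order(df$trait, df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by \code{write_candidate_table}
#' @param path Path to the TSV.
#' @return Data frame with the candidate-table columns.
#' @export
read_candidate_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
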