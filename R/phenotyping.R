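# Seedling architecture phenotyping: trait derivation and extreme-phenotype
# pool construction. Display rounding is half-up to 2 decimals (matching the
# published presentation of such tables); full precision is what propagates.

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean internode length of a seedling
#'
#' The seedling-level trait is the arithmetic mean of the five branch-level
#' mean internode lengths (each branch value itself summarizes four
#' measured internodes; branches are treated as atomic inputs here).
#'
#' @param branch_means Numeric vector of exactly 5 positive values (mm).
#' @param rounded If \code{TRUE} (default \code{FALSE}), return the value
#'   rounded half-up to 2 decimals as displayed in phenotype tables.
#' @return Mean internode length in mm.
#' @export
mean_internode_length <- function(branch_means, rounded = FALSE) {
  if (length(branch_means) != 5L)
    stop("exactly 5 branch means are required, got ", length(branch_means))
  if (any(!is.finite(branch_means)) || any(branch_means <= 0))
    stop("branch means must be positive finite values")
  m <- mean(branch_means)
  if (rounded) round_half_up(m, 2L) else m
}

#' Read a seedling phenotype table from TSV
#'
#' Expected columns: \code{seedling_id}, \code{mother},
#' \code{pollen_donor}, \code{diameter_mm}, \code{branch1_mm} ..
#' \code{branch5_mm}, optional \code{pool}. The derived
#' \code{mean_internode_mm} column is (re)computed from the branch means.
#'
#' @param path Path to the TSV.
#' @return Data frame with a computed \code{mean_internode_mm} column.
#' @export
load_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(seedling_id = "character"))
  needed <- c("seedling_id", "mother", "pollen_donor", "diameter_mm",
              paste0("branch", 1:5, "_mm"))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("phenotype TSV lacks column(s): ", paste(missing, collapse = ", "))
  meas <- as.matrix(df[c("diameter_mm", paste0("branch", 1:5, "_mm"))])
  if (anyNA(meas) || any(meas <= 0))
    stop("all phenotype measurements must be positive and present")
  key <- paste(df$mother, df$pollen_donor, df$seedling_id,
               if ("pool" %in% names(df)) df$pool else "")
  if (anyDuplicated(key))
    warning("seedling id reused within a cross/pool: ",
            key[duplicated(key)][[1L]],
            " (rows are kept; published tables reuse bare ids)")
  if ("mean_internode_mm" %in% names(df))
    df$mean_internode_mm_reported <- df$mean_internode_mm
  df$mean_internode_mm <- rowMeans(df[paste0("branch", 1:5, "_mm")])
  df
}

#' Select extreme-phenotype seedling pools
#'
#' Returns the \code{k_low} seedlings with the smallest and the
#' \code{k_high} with the largest values of the chosen trait, the
#' selection rule used to build opposite-phenotype RNA pools from a
#' segregating progeny. Ties are broken by input row order, so selection
#' is deterministic.
#'
#' @param table Phenotype data frame (see \code{\link{load_phenotypes}}).
#' @param trait \code{"mean_internode"} or \code{"diameter"}.
#' @param k_low,k_high Pool sizes.
#' @return List with integer row indices \code{low} and \code{high}
#'   (disjoint) and the trait values selected.
#' @export
select_extreme_pools <- function(table, trait = c("mean_internode", "diameter"),
                                 k_low, k_high) {
  trait <- match.arg(trait)
  vals <- switch(trait, mean_internode = {
    if (!"mean_internode_mm" %in% names(table))
      table$mean_internode_mm <- rowMeans(table[paste0("branch", 1:5, "_mm")])
    table$mean_internode_mm
  }, diameter = table$diameter_mm)
  n <- length(vals)
  if (k_low + k_high > n)
    stop("k_low + k_high exceeds the number of seedlings (", n, ")")
  ord <- order(vals)                       # stable: ties keep row order
  low <- ord[seq_len(k_low)]
  high <- ord[n + 1L - seq_len(k_high)]
  if (length(intersect(low, high)))
    stop("low and high pools overlap; reduce pool sizes")
  list(low = low, high = high,
       low_values = vals[low], high_values = vals[high])
}

#' Summarize phenotype pools
#'
#' Per-pool mean and sd of trunk diameter and mean internode length.
#' Single-member pools report \code{sd = 0} and are flagged; empty pool
#' labels are dropped with a warning.
#'
#' @param table Phenotype data frame with a \code{pool} column.
#' @return Data frame: \code{pool}, \code{n}, \code{diameter_mean},
#'   \code{diameter_sd}, \code{internode_mean}, \code{internode_sd},
#'   \code{degenerate} (TRUE when n < 2).
#' @export
summarize_pools <- function(table) {
  if (!"pool" %in% names(table)) stop("phenotype table lacks a 'pool' column")
  if (!"mean_internode_mm" %in% names(table))
    table$mean_internode_mm <- rowMeans(table[paste0("branch", 1:5, "_mm")])
  keep <- !is.na(table$pool) & nzchar(table$pool)
  if (any(!keep)) warning(sum(!keep), " seedling(s) without a pool label omitted")
  table <- table[keep, , drop = FALSE]
  pools <- unique(table$pool)
  out <- do.call(rbind, lapply(pools, function(p) {
    sub <- table[table$pool == p, , drop = FALSE]
    n <- nrow(sub)
    data.frame(pool = p, n = n,
               diameter_mean = mean(sub$diameter_mm),
               diameter_sd = if (n > 1L) stats::sd(sub$diameter_mm) else 0,
               internode_mean = mean(sub$mean_internode_mm),
               internode_sd = if (n > 1L) stats::sd(sub$mean_internode_mm) else 0,
               degenerate = n < 2L, stringsAsFactors = FALSE)
  }))
  out
}
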