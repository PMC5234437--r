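# Depth normalization.
#
# The default strategy avoids random subsampling: each count is divided by
# its library size and multiplied by the smallest library size, so within-
# sample proportions are preserved exactly and no reads are discarded.
# Classical rarefaction (subsampling without replacement) is available as an
# alternative.

#' Normalize counts to the minimum library depth
#'
#' Computes \eqn{n_{ij} = c_{ij} \cdot \min_k S_k / S_j}, where \eqn{S_j} is
#' the total read count of sample \eqn{j}. Deterministic and lossless:
#' within-sample proportions are unchanged, and every sample's normalized
#' counts sum to the smallest original depth. Values are kept as reals (not
#' rounded) because the alpha-diversity step applies its own 0.5-count floor.
#'
#' @param table an \code{otu_table} (or \code{norm_table}, in which case the
#'   operation is idempotent).
#' @return a \code{norm_table}; the scaling depth is in attribute
#'   \code{min_depth}.
#' @export
normalize_counts <- function(table) {
  v <- table$values
  totals <- colSums(v)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(v)[totals == 0], collapse = ", "))
  min_depth <- min(totals)
  out <- sweep(v, 2, min_depth / totals, `*`)
  res <- new_abundance_table(out, table$taxonomy, "norm_table")
  attr(res, "min_depth") <- min_depth
  res
}

#' Rarefy counts by subsampling without replacement
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric) to exactly \code{depth}.
#'
#' @param table an \code{otu_table} of integer counts.
#' @param depth target depth; must not exceed any sample's total.
#' @param seed integer seed making the draw reproducible.
#' @return an \code{otu_table} whose samples all sum to \code{depth}.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  v <- table$values
  totals <- colSums(v)
  if (depth <= 0 || depth != round(depth)) stop("depth must be a positive integer")
  low <- totals < depth
  if (any(low))
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(colnames(v)[low], collapse = ", "))
  set.seed(seed)
  out <- v
  for (j in seq_len(ncol(v))) {
    reads <- rep.int(seq_len(nrow(v)), v[, j])
    keep <- sample(reads, depth, replace = FALSE)
    out[, j] <- tabulate(keep, nbins = nrow(v))
  }
  new_abundance_table(out, table$taxonomy, "otu_table")
}

#' Convert counts to relative abundances (percent)
#'
#' @param table an \code{otu_table} or \code{norm_table}.
#' @return a \code{rel_table}; each sample column sums to 100.
#' @export
to_relative <- function(table) {
  v <- table$values
  totals <- colSums(v)
  if (any(totals == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(v)[totals == 0], collapse = ", "))
  new_abundance_table(sweep(v, 2, 100 / totals, `*`), table$taxonomy,
                      "rel_table")
}

#' Per-sample sequencing depth report
#'
#' Flags samples whose depth falls below \code{fraction} of the median depth
#' (default 1/10, after the rule of thumb that a 2,000-read library among
#' ~20,000-read libraries indicates experimental failure). Flagged samples
#' are reported, never removed: pruning the input is the user's decision.
#'
#' @param table an \code{otu_table}.
#' @param fraction flagging threshold as a fraction of the median depth;
#'   0 disables flagging.
#' @return data.frame with columns \code{sample}, \code{depth},
#'   \code{flagged}.
#' @export
depth_report <- function(table, fraction = 0.1) {
  totals <- colSums(table$values)
  # boundary inclusive: a 2,000-read library among ~20,000-read ones is
  # exactly at the default 1/10 fraction and should be flagged
  flagged <- fraction > 0 & totals <= fraction * median(totals)
  if (any(flagged))
    warning("shallow sample(s) flagged (depth < ", fraction,
            " x median): ", paste(names(totals)[flagged], collapse = ", "))
  data.frame(sample = names(totals), depth = as.numeric(totals),
             flagged = as.logical(flagged), row.names = NULL)
}
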