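# Taxonomic binning: aggregate OTU relative abundances at each rank.
#
# Ranks are positional in the split lineage (kingdom, phylum, class, order,
# family, genus); shorter or partially classified lineages are padded with
# "Unknown". An OTU unknown at the requested rank keeps its deepest known
# prefix, so "Bacteria;Firmicutes;;..." bins at class level as
# "Bacteria;Firmicutes;Unknown" and never merges with unknowns from a
# different root.

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

# lineage prefix label of one OTU at rank index `depth`
bin_label <- function(lineage, depth) {
  v <- rep("", depth)
  take <- seq_len(min(depth, length(lineage)))
  v[take] <- lineage[take]
  v[v == ""] <- "Unknown"
  paste(v, collapse = ";")
}

#' Aggregate relative abundances at a taxonomic rank
#'
#' Sums, per sample, the relative abundances of all OTUs sharing the same
#' lineage prefix up to \code{rank}. The binning is a partition: per-sample
#' bin totals equal the per-sample input totals exactly.
#'
#' @param rel a \code{rel_table} (or any abundance table).
#' @param rank one of \code{"kingdom"}, \code{"phylum"}, \code{"class"},
#'   \code{"order"}, \code{"family"}, \code{"genus"}, or \code{"otu"} for
#'   the identity binning.
#' @return matrix bins x samples of summed values, row names the
#'   semicolon-joined lineage prefixes, with attribute \code{rank}.
#' @export
bin_at_rank <- function(rel, rank = "genus") {
  v <- rel$values
  if (identical(rank, "otu")) {
    out <- v
    attr(out, "rank") <- "otu"
    return(out)
  }
  depth <- match(rank, TAX_RANKS)
  if (is.na(depth))
    stop("rank must be one of: otu, ", paste(TAX_RANKS, collapse = ", "))
  labels <- vapply(rel$taxonomy, bin_label, character(1), depth = depth)
  out <- rowsum(v, group = labels, reorder = TRUE)
  attr(out, "rank") <- rank
  out
}

#' Re-wrap a bin matrix as a relative-abundance table
#'
#' The row names (semicolon-joined lineage prefixes) become the taxonomy,
#' so a binned table can itself be binned at a coarser rank or fed to the
#' comparison machinery.
#'
#' @param bins matrix from [bin_at_rank()].
#' @return a \code{rel_table}.
#' @export
bins_as_table <- function(bins) {
  tax <- split_lineage(rownames(bins))
  names(tax) <- rownames(bins)
  m <- bins
  attr(m, "rank") <- NULL
  new_abundance_table(m, tax, "rel_table")
}

#' Binned tables for a set of ranks
#' @inheritParams bin_at_rank
#' @param ranks character vector of ranks.
#' @return named list of bin matrices.
#' @export
bin_all_ranks <- function(rel, ranks = TAX_RANKS) {
  stats::setNames(lapply(ranks, function(r) bin_at_rank(rel, r)), ranks)
}

#' Stacked composition bar plot
#'
#' One stacked bar per sample. Bins are sorted by grand-mean abundance
#' (descending); bins whose grand mean falls below \code{display_cutoff}
#' percent are merged into an "Other" segment for display only — data tables
#' are never collapsed.
#'
#' @param bins a bin matrix from [bin_at_rank()].
#' @param display_cutoff percent grand-mean threshold for the "Other"
#'   segment; 0 keeps every bin.
#' @param order_by optional group labels used to order the bars.
#' @param legend draw the bin legend.
#' @return invisibly, the displayed (possibly collapsed) matrix.
#' @export
composition_plot <- function(bins, display_cutoff = 0.5, order_by = NULL,
                             legend = TRUE) {
  means <- rowMeans(bins)
  ord <- order(means, decreasing = TRUE)
  m <- bins[ord, , drop = FALSE]
  small <- rowMeans(m) < display_cutoff
  if (any(small) && display_cutoff > 0) {
    other <- colSums(m[small, , drop = FALSE])
    m <- rbind(m[!small, , drop = FALSE], Other = other)
  }
  if (!is.null(order_by)) m <- m[, order(as.character(order_by)), drop = FALSE]
  cols <- grDevices::hcl.colors(max(nrow(m), 2), "Spectral")[seq_len(nrow(m))]
  graphics::barplot(m, col = cols, las = 2, ylab = "Relative abundance (%)",
                    border = NA)
  if (legend)
    graphics::legend("topright", legend = rownames(m), fill = cols,
                     cex = 0.6, bty = "n")
  invisible(m)
}
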