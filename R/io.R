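#' @importFrom stats median sd cor dist hclust cutree cmdscale as.dist
#'   kruskal.test wilcox.test fisher.test p.adjust pt qt rmultinom rgamma
#'   rnbinom runif rnorm quantile complete.cases lm predict coef
#' @importFrom utils read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Domain containers
#
# An OTU table is stored as a numeric matrix (rows = OTUs, columns = samples)
# plus a parallel list of split taxonomic lineages. Three classes share the
# layout and differ only in what the values mean:
#   otu_table  - raw integer read counts
#   norm_table - depth-normalized real counts (attr "min_depth" holds the
#                scaling depth, i.e. the smallest original library size)
#   rel_table  - relative abundances in percent (columns sum to 100)
# ---------------------------------------------------------------------------

new_abundance_table <- function(values, taxonomy, class) {
  stopifnot(is.matrix(values), length(taxonomy) == nrow(values))
  structure(list(values = values, taxonomy = taxonomy),
            class = c(class, "abundance_table"))
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<%s> %d OTUs x %d samples\n", class(x)[1],
              nrow(x$values), ncol(x$values)))
  if (inherits(x, "norm_table"))
    cat(sprintf("  normalized to minimum depth %s\n",
                format(attr(x, "min_depth"))))
  invisible(x)
}

otu_ids    <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Split a semicolon-delimited lineage string into rank labels
#'
#' Empty ranks (consecutive semicolons, trailing semicolons, or tokens such
#' as whitespace) are kept as empty strings so that positional rank indexing
#' stays intact.
#'
#' @param x character vector of lineage strings.
#' @return list of character vectors, one per input string.
#' @export
split_lineage <- function(x) {
  n_ranks <- nchar(x) - nchar(gsub(";", "", x, fixed = TRUE)) + 1L
  parts <- strsplit(x, ";", fixed = TRUE)
  # strsplit drops trailing empty fields; pad them back so positional rank
  # indexing survives lineages like "Bacteria;Firmicutes;;;"
  mapply(function(v, n) trimws(c(v, rep("", n - length(v)))),
         parts, n_ranks, SIMPLIFY = FALSE)
}

#' Read an OTU count table
#'
#' Expects the tab-separated layout produced by common amplicon pipelines:
#' first column OTU identifiers, one numeric column per sample, and a final
#' column named \code{taxonomy} holding semicolon-delimited lineages.
#'
#' @param path path to the tab-separated file.
#' @return an object of class \code{otu_table} with integer counts and a
#'   per-OTU split lineage.
#' @export
read_otu_table <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 3)
    stop("OTU table needs at least one sample column and a taxonomy column")
  header <- colnames(raw)
  if (tolower(header[ncol(raw)]) != "taxonomy")
    stop("last column must be named 'taxonomy'; found '",
         header[ncol(raw)], "'")
  otus <- raw[[1]]
  if (anyDuplicated(otus))
    stop("duplicated OTU identifier(s): ",
         paste(unique(otus[duplicated(otus)]), collapse = ", "))
  samples <- header[2:(ncol(raw) - 1)]
  if (anyDuplicated(samples))
    stop("duplicated sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  counts <- matrix(NA_real_, nrow(raw), length(samples),
                   dimnames = list(otus, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop(sprintf(
        "non-count value '%s' at OTU '%s', sample '%s'",
        raw[[j + 1]][bad[1]], otus[bad[1]], samples[j]))
    counts[, j] <- col
  }
  taxonomy <- split_lineage(raw[[ncol(raw)]])
  names(taxonomy) <- otus
  new_abundance_table(counts, taxonomy, "otu_table")
}

#' Read a sample mapping file
#'
#' @param path tab-separated file, first column sample identifiers.
#' @param group_cols names of categorical group columns.
#' @param meta_cols names of numeric meta-variable columns; missing cells
#'   ("NA" or empty) are kept as \code{NA}.
#' @return a \code{mapping_table}: a data.frame with sample IDs as row names
#'   and attributes \code{group_cols} / \code{meta_cols}.
#' @export
read_mapping <- function(path, group_cols = character(), meta_cols = character()) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample identifier(s) in mapping: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  absent <- setdiff(c(group_cols, meta_cols), colnames(raw))
  if (length(absent))
    stop("declared column(s) absent from mapping: ",
         paste(absent, collapse = ", "))
  out <- raw[, -1, drop = FALSE]
  rownames(out) <- ids
  for (g in group_cols) out[[g]] <- as.character(out[[g]])
  for (m in meta_cols) {
    val <- out[[m]]
    num <- suppressWarnings(as.numeric(val))
    bad <- which(!is.na(val) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in meta column '%s', sample '%s'",
                   val[bad[1]], m, ids[bad[1]]))
    out[[m]] <- num
  }
  structure(out, group_cols = group_cols, meta_cols = meta_cols,
            class = c("mapping_table", "data.frame"))
}

#' Intersect an OTU table and a mapping table on their sample sets
#'
#' All joint analyses run on the intersection of the two sample sets; any
#' asymmetry is reported as a warning listing the dropped samples.
#'
#' @param table an abundance table.
#' @param mapping a \code{mapping_table}.
#' @return list with the subsetted \code{table} and \code{mapping}, sample
#'   order taken from the OTU table.
#' @export
align_samples <- function(table, mapping) {
  st <- sample_ids(table)
  sm <- rownames(mapping)
  common <- intersect(st, sm)
  only_t <- setdiff(st, sm)
  only_m <- setdiff(sm, st)
  if (length(only_t) || length(only_m))
    warning("samples dropped from joint analyses - only in OTU table: {",
            paste(only_t, collapse = ", "), "}; only in mapping: {",
            paste(only_m, collapse = ", "), "}")
  if (!length(common)) stop("no samples shared between OTU table and mapping")
  tab <- table
  tab$values <- tab$values[, common, drop = FALSE]
  map <- mapping[common, , drop = FALSE]
  attributes(map)[c("group_cols", "meta_cols", "class")] <-
    attributes(mapping)[c("group_cols", "meta_cols", "class")]
  list(table = tab, mapping = map)
}

#' Read a phylogenetic tree in Newick format
#'
#' Unrooted input is rooted deterministically at the midpoint of the longest
#' leaf-to-leaf path. By default every OTU in \code{otus} must be a leaf and
#' every leaf may be checked against the table; leaves not in \code{otus} are
#' pruned only when \code{prune_extra = TRUE}.
#'
#' @param path Newick file with branch lengths.
#' @param otus optional character vector of OTU identifiers the tree must
#'   cover.
#' @param prune_extra drop leaves that are not in \code{otus} (default keeps
#'   them and errors if \code{otus} is given and leaves mismatch).
#' @return an \code{ape} \code{phylo} object, rooted.
#' @export
read_tree <- function(path, otus = NULL, prune_extra = FALSE) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: no tree parsed from ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
    message("unrooted input tree rooted at midpoint")
  }
  if (!is.null(otus)) {
    missing_leaves <- setdiff(otus, tree$tip.label)
    if (length(missing_leaves))
      stop("missing leaves (OTUs absent from tree): ",
           paste(missing_leaves, collapse = ", "))
    extra <- setdiff(tree$tip.label, otus)
    if (length(extra)) {
      if (!prune_extra)
        stop("tree has leaves absent from the OTU table: ",
             paste(extra, collapse = ", "),
             " (use prune_extra = TRUE to drop them)")
      tree <- ape::drop.tip(tree, extra)
      message("pruned ", length(extra), " leaf/leaves not in the OTU table")
    }
  }
  tree
}

#' Write a numeric matrix or distance matrix as tab-separated text
#'
#' Values are written at full precision (15 significant digits); missing
#' values are emitted as \code{NA}.
#'
#' @param x matrix, \code{dist}, abundance table or data.frame.
#' @param path output path.
#' @param rowname_header header of the first (row-name) column.
#' @export
write_tab <- function(x, path, rowname_header = "#ID") {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (inherits(x, "abundance_table")) {
    tax <- vapply(x$taxonomy, paste, character(1), collapse = ";")
    x <- data.frame(x$values, taxonomy = tax, check.names = FALSE)
  }
  df <- as.data.frame(x, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    out[is.na(v)] <- "NA"
    out
  })
  header <- paste(c(rowname_header, colnames(df)), collapse = "\t")
  lines <- c(header, do.call(paste,
                             c(list(rownames(df)), as.list(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a square tab-separated matrix written by [write_tab()]
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_tab_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  as.matrix(df)
}

#' Append a run log entry
#'
#' Every pipeline invocation records a timestamp, the input files, and every
#' threshold, seed and parameter used, so that an analysis can be repeated.
#'
#' @param step name of the pipeline step.
#' @param params named list of parameter values.
#' @param inputs character vector of input file names.
#' @param path log file (appended); \code{NULL} returns the lines invisibly.
#' @return the log lines, invisibly.
#' @export
write_run_log <- function(step, params = list(), inputs = character(),
                          path = NULL) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  lines <- c(sprintf("[%s] step=%s", stamp, step),
             if (length(inputs)) paste0("  input: ", inputs),
             if (length(params))
               sprintf("  %s = %s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = ","), character(1))))
  if (!is.null(path)) cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(lines)
}
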