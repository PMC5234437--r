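# Shared fixture builders and independent oracles.

# abundance table straight from a matrix; taxonomy defaults to one kingdom
make_table <- function(m, taxonomy = NULL, class = "otu_table") {
  if (is.null(rownames(m))) rownames(m) <- paste0("OTU_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  if (is.null(taxonomy)) {
    taxonomy <- rep(list("Bacteria"), nrow(m))
    names(taxonomy) <- rownames(m)
  }
  otuflow:::new_abundance_table(m, taxonomy, class)
}

# write a small OTU table file in the expected on-disk dialect
write_otu_fixture <- function(path, counts, lineages) {
  header <- paste(c("#OTUId", colnames(counts), "taxonomy"), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i)
    paste(rownames(counts)[i], paste(counts[i, ], collapse = "\t"),
          lineages[i], sep = "\t"), character(1))
  writeLines(c(header, rows), path)
  path
}

write_mapping_fixture <- function(path, ids, ...) {
  cols <- list(...)
  header <- paste(c("#SampleID", names(cols)), collapse = "\t")
  rows <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], vapply(cols, function(cl) as.character(cl[i]),
                           character(1))), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  path
}

# Independent brute-force generalized UniFrac: explicit loop over every
# branch, descendant tips found by naive recursion on the edge table.
brute_gunifrac <- function(table, tree, alpha) {
  v <- table$values
  prop <- sweep(v, 2, colSums(v), `/`)
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  leaf_prop <- function(sample, tips) {
    present <- intersect(tips, rownames(prop))
    if (!length(present)) 0 else sum(prop[present, sample])
  }
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tips_below(tree$edge[e, 2])
      pa <- leaf_prop(i, tips); pb <- leaf_prop(j, tips)
      if (pa + pb > 0) {
        w <- tree$edge.length[e] * (pa + pb)^alpha
        num <- num + w * abs(pa - pb) / (pa + pb)
        den <- den + w
      }
    }
    d[i, j] <- d[j, i] <- num / den
  }
  as.dist(d)
}

# random tree + matched count table for cross-checks
random_unifrac_fixture <- function(n_tips, n_samples = 4) {
  tree <- ape::rtree(n_tips)
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  m <- matrix(rpois(n_tips * n_samples, 20), n_tips, n_samples,
              dimnames = list(tree$tip.label,
                              paste0("S", seq_len(n_samples))))
  m[sample(length(m), length(m) %/% 3)] <- 0
  empty <- colSums(m) == 0
  m[1, empty] <- 5
  list(tree = tree, table = make_table(m, class = "norm_table"))
}

# exact PERMANOVA p for two groups by enumeration of all group assignments
enumerate_permanova_p <- function(dm, groups) {
  d2 <- as.matrix(dm)^2
  groups <- factor(as.character(groups))
  n <- nrow(d2)
  k <- nlevels(groups)
  f_of <- function(g) {
    ss <- otuflow:::permanova_ss(d2, g)
    ((ss[["ss_t"]] - ss[["ss_w"]]) / (k - 1)) / (ss[["ss_w"]] / (n - k))
  }
  f_obs <- f_of(groups)
  idx_a <- utils::combn(n, sum(groups == levels(groups)[1]))
  fs <- apply(idx_a, 2, function(a) {
    g <- factor(ifelse(seq_len(n) %in% a, levels(groups)[1],
                       levels(groups)[2]), levels = levels(groups))
    f_of(g)
  })
  mean(fs >= f_obs - 1e-12)
}
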