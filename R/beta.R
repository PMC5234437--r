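# Beta-diversity: generalized UniFrac distances, ordination (PCoA / NMDS),
# PERMANOVA and Ward clustering.
#
# The generalized UniFrac family compares two samples branch by branch:
#   d^(a)(A,B) = sum_i b_i (pAi+pBi)^a |pAi-pBi|/(pAi+pBi)
#              / sum_i b_i (pAi+pBi)^a
# where b_i is the length of branch i and pAi the summed proportion, in
# sample A, of all leaves descending from branch i. a = 1 recovers the
# abundance-weighted (normalized) form, a -> 0 down-weights abundant
# lineages; a = 0.5 is the balanced default. Branches with pAi + pBi = 0 are
# skipped in both sums (the limit convention).

# edges x tips incidence: entry (e, t) is TRUE when tip t descends from
# edge e's child node.
branch_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  inc <- matrix(FALSE, nrow(tree$edge), ntip,
                dimnames = list(NULL, tree$tip.label))
  for (e in seq_len(nrow(tree$edge))) inc[e, desc[[e]]] <- TRUE
  inc
}

#' Generalized UniFrac distance matrix
#'
#' @param table a \code{norm_table} or \code{otu_table}; row names must all
#'   be leaves of \code{tree}. Tree leaves absent from the table are treated
#'   as zero-abundance everywhere.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param alpha abundance weighting exponent in [0, 1]; 0.5 balances rare
#'   and dominant lineages, 1 is the abundance-weighted normalized UniFrac.
#' @return a \code{dist} object over samples, values in [0, 1].
#' @export
generalized_unifrac <- function(table, tree, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  v <- table$values
  totals <- colSums(v)
  if (any(totals == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(v)[totals == 0], collapse = ", "))
  missing_tips <- setdiff(rownames(v), tree$tip.label)
  if (length(missing_tips))
    stop("OTU(s) absent from tree: ", paste(missing_tips, collapse = ", "))
  prop <- matrix(0, length(tree$tip.label), ncol(v),
                 dimnames = list(tree$tip.label, colnames(v)))
  prop[rownames(v), ] <- sweep(v, 2, totals, `/`)
  inc <- branch_incidence(tree)
  bp <- inc %*% prop                      # branch proportions, edges x samples
  b <- tree$edge.length
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- bp[, i]; pb <- bp[, j]
      s <- pa + pb
      keep <- s > 0
      w <- b[keep] * s[keep]^alpha
      den <- sum(w)
      d[i, j] <- d[j, i] <-
        if (den == 0) 0 else sum(w * abs(pa[keep] - pb[keep]) / s[keep]) / den
    }
  }
  as.dist(d)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres \eqn{-\tfrac12 D^2} and eigendecomposes it; coordinates
#' are eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' generalized UniFrac) are reported but their axes are dropped; no
#' Cailliez/Lingoes correction is applied.
#'
#' @param dm a \code{dist} object.
#' @param k number of dimensions to keep (default 2).
#' @return an \code{ordination} object: \code{coordinates} (samples x k),
#'   \code{eigenvalues} (all, descending), \code{method = "PCoA"}.
#' @export
pcoa <- function(dm, k = 2) {
  n <- attr(dm, "Size")
  if (is.null(n) || n < 3) stop("PCoA needs at least 3 samples")
  fit <- cmdscale(dm, k = min(k, n - 1), eig = TRUE)
  pts <- as.matrix(fit$points)
  if (ncol(pts) > k) pts <- pts[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(coordinates = pts,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 method = "PCoA", k = k),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (vegan's \code{monoMDS}, global model, weak
#' ties) over \code{n_starts} starts: the first from the PCoA configuration,
#' the rest from random configurations. The best (lowest-stress) solution is
#' returned; reproducible under \code{seed}.
#'
#' @param dm a \code{dist} object.
#' @param k dimensions (default 2); needs \code{n > k + 1} samples.
#' @param seed integer seed.
#' @param n_starts number of starts (>= 1).
#' @return an \code{ordination} object with \code{stress} in [0, 1] and a
#'   \code{converged} flag; a warning is issued when no start converged.
#' @export
nmds <- function(dm, k = 2, seed = 1L, n_starts = 20L) {
  n <- attr(dm, "Size")
  if (is.null(n) || n <= k + 1) stop("NMDS needs more than k + 1 samples")
  set.seed(seed)
  init <- pcoa(dm, k)$coordinates
  if (ncol(init) < k)
    init <- cbind(init, matrix(rnorm(n * (k - ncol(init)), sd = 1e-4), n))
  best <- NULL
  for (s in seq_len(n_starts)) {
    y <- if (s == 1) init else matrix(runif(n * k, -1, 1), n, k)
    fit <- vegan::monoMDS(dm, y = y, k = k, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  converged <- isTRUE(best$maxits > best$iters) || best$stress < 1e-4
  if (!converged)
    warning("NMDS did not converge in any start (best stress ",
            format(best$stress, digits = 4), ")")
  pts <- best$points
  rownames(pts) <- attr(dm, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = pts, stress = best$stress,
                 method = "NMDS", k = k, converged = converged),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, %d samples, k = %d\n", x$method,
              nrow(x$coordinates), x$k))
  if (x$method == "NMDS")
    cat(sprintf("  stress = %.4f (converged: %s)\n", x$stress, x$converged))
  else
    cat("  eigenvalues:", format(utils::head(x$eigenvalues, 5), digits = 4),
        "...\n")
  invisible(x)
}

# sums of squares decomposition for a labelled distance matrix
# (Anderson 2001 pseudo-F via within-group squared distances)
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(ss_t = ss_t, ss_w = ss_w)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by uniform
#' random permutation of the sample labels. The reported p-value is
#' \eqn{(1 + \#\{F^* \ge F\}) / (n_{perm} + 1)} and can never fall below
#' \eqn{1/(n_{perm}+1)}.
#'
#' @param dm a \code{dist} object.
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a \code{permanova} object: \code{pseudo_F}, \code{R2}, \code{p},
#'   \code{n_permutations}.
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  d2 <- as.matrix(dm)^2
  groups <- factor(as.character(groups))
  n <- nrow(d2)
  if (length(groups) != n) stop("groups must match the distance matrix")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- nlevels(groups)
  ss <- permanova_ss(d2, groups)
  ss_a <- ss[["ss_t"]] - ss[["ss_w"]]
  f_obs <- (ss_a / (k - 1)) / (ss[["ss_w"]] / (n - k))
  set.seed(seed)
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    perm <- groups[sample.int(n)]
    ssp <- permanova_ss(d2, perm)
    f_p <- ((ssp[["ss_t"]] - ssp[["ss_w"]]) / (k - 1)) /
      (ssp[["ss_w"]] / (n - k))
    if (f_p >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs, R2 = ss_a / ss[["ss_t"]],
                 p = (1 + exceed) / (n_perm + 1),
                 n_permutations = as.integer(n_perm)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on every group-pair sub-matrix and adjusts the
#' p-values across pairs with Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @return data.frame with one row per pair: \code{group1}, \code{group2},
#'   \code{pseudo_F}, \code{R2}, \code{p}, \code{p_adj}.
#' @export
pairwise_permanova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  groups <- factor(as.character(groups))
  m <- as.matrix(dm)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    pseudo_F = NA_real_, R2 = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    idx <- which(groups %in% pairs[, i])
    fit <- permanova(as.dist(m[idx, idx]), droplevels(groups[idx]),
                     n_perm = n_perm, seed = seed + i)
    out$pseudo_F[i] <- fit$pseudo_F
    out$R2[i] <- fit$R2
    out$p[i] <- fit$p
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Ward dendrogram of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion on squared
#' dissimilarities (\code{hclust} method \code{"ward.D2"}), the
#' criterion-faithful variant.
#'
#' @param dm a \code{dist} object with >= 2 samples.
#' @return the \code{hclust} object; convert with [dendrogram_newick()].
#' @export
ward_dendrogram <- function(dm) {
  if (attr(dm, "Size") < 2) stop("need at least 2 samples to cluster")
  hclust(dm, method = "ward.D2")
}

#' Newick serialization of a dendrogram
#' @param h an \code{hclust} object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}

#' Ordination scatter plot with group hulls
#'
#' @param x an \code{ordination} object.
#' @param groups optional group labels for colours and convex hulls.
#' @param ... passed to \code{plot}.
#' @return invisibly, the coordinates plotted.
#' @export
plot.ordination <- function(x, groups = NULL, ...) {
  pts <- x$coordinates
  main <- if (x$method == "NMDS")
    sprintf("NMDS (stress = %.3f)", x$stress) else "PCoA"
  col <- "black"
  if (!is.null(groups)) {
    groups <- factor(as.character(groups))
    col <- as.integer(groups) + 1L
  }
  plot(pts[, 1], pts[, 2], col = col, pch = 19, xlab = colnames(pts)[1],
       ylab = colnames(pts)[2], main = main, ...)
  if (!is.null(groups)) {
    for (g in levels(groups)) {
      idx <- which(groups == g)
      if (length(idx) >= 3) {
        hull <- idx[grDevices::chull(pts[idx, 1], pts[idx, 2])]
        graphics::polygon(pts[hull, 1], pts[hull, 2],
                          border = as.integer(factor(g, levels(groups))) + 1L)
      }
    }
    graphics::legend("topright", legend = levels(groups), col =
                       seq_len(nlevels(groups)) + 1L, pch = 19, bty = "n")
  }
  invisible(pts)
}
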