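# Synthetic amplicon datasets.
#
# Stand-in for the two template studies the pipeline was designed around:
# a grouped mouse-faecal study (~20,000 reads per library, two to four
# sample groups) and a set of 10 technical-replicate libraries of a single
# human faecal sample. Counts follow a Dirichlet-multinomial: a sample's
# composition is drawn from a Dirichlet around a geometric rank-abundance
# base, group effects multiply selected OTUs' expected proportions, and
# reads are multinomial at a negative-binomial library depth. The tree is a
# Yule (pure-birth) tree rescaled to unit height, and the 6-rank taxonomy
# is obtained by cutting that tree at fixed heights, so tree and taxonomy
# always agree.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulation configuration
#'
#' @param n_per_group samples per group (default 10).
#' @param n_groups number of groups (default 2).
#' @param n_otus number of OTUs (default 100).
#' @param depth_mean mean library size (default 20000 reads).
#' @param depth_dispersion negative-binomial size parameter of the library
#'   depth (default 10; larger = tighter).
#' @param base_alpha Dirichlet concentration vector; the default is a
#'   geometric rank-abundance profile (ratio 0.93) with total concentration
#'   50, giving a realistically uneven community with sampling noise.
#' @param effects data.frame with columns \code{otu} (index), \code{group}
#'   (index) and \code{fold} (> 0): multiplicative change of that OTU's
#'   expected proportion in that group.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_per_group = 10, n_groups = 2, n_otus = 100,
                       depth_mean = 20000, depth_dispersion = 10,
                       base_alpha = NULL, effects = NULL, seed = 1L) {
  stopifnot(n_per_group >= 1, n_groups >= 1, n_otus >= 2,
            depth_mean > 0, depth_dispersion > 0)
  if (is.null(base_alpha)) {
    p <- 0.93^seq_len(n_otus)
    base_alpha <- 50 * p / sum(p)
  }
  stopifnot(length(base_alpha) == n_otus, all(base_alpha > 0))
  if (!is.null(effects))
    stopifnot(all(c("otu", "group", "fold") %in% names(effects)),
              all(effects$fold > 0),
              all(effects$otu %in% seq_len(n_otus)),
              all(effects$group %in% seq_len(n_groups)))
  structure(list(n_per_group = n_per_group, n_groups = n_groups,
                 n_otus = n_otus, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 base_alpha = base_alpha, effects = effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Yule tree with unit height and a rank taxonomy cut at fixed heights
simulate_tree_taxonomy <- function(n_otus) {
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_otus)])
  tree$edge.length <- tree$edge.length / height
  hc <- ape::as.hclust.phylo(tree)
  cut_h <- c(phylum = 0.8, class = 0.65, order = 0.5, family = 0.35,
             genus = 0.2)
  taxonomy <- vector("list", n_otus)
  names(taxonomy) <- tree$tip.label
  ranks <- sapply(cut_h, function(h) cutree(hc, h = h))
  for (i in seq_len(n_otus)) {
    lab <- c("Bacteria",
             sprintf("%s_%02d", c("Phy", "Cls", "Ord", "Fam", "Gen"),
                     ranks[hc$labels[i] == rownames(ranks), ]))
    taxonomy[[hc$labels[i]]] <- lab
  }
  list(tree = tree, taxonomy = taxonomy[tree$tip.label])
}

#' Simulate a grouped OTU dataset
#'
#' @param config a [sim_config()].
#' @return list: \code{table} (an \code{otu_table}), \code{mapping}
#'   (a \code{mapping_table} with group column \code{Group}), \code{tree}
#'   (\code{phylo}, leaves = OTU ids), \code{truth} (the effects actually
#'   planted). Bit-reproducible for a fixed config.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_per_group * config$n_groups
  tt <- simulate_tree_taxonomy(config$n_otus)
  group <- rep(paste0("G", seq_len(config$n_groups)),
               each = config$n_per_group)
  samples <- sprintf("S%03d", seq_len(n))
  counts <- matrix(0L, config$n_otus, n,
                   dimnames = list(tt$tree$tip.label, samples))
  for (j in seq_len(n)) {
    comp <- rdirichlet1(config$base_alpha)
    g <- (j - 1) %/% config$n_per_group + 1
    if (!is.null(config$effects)) {
      eff <- config$effects[config$effects$group == g, , drop = FALSE]
      if (nrow(eff)) {
        comp[eff$otu] <- comp[eff$otu] * eff$fold
        comp <- comp / sum(comp)
      }
    }
    depth <- max(rnbinom(1, size = config$depth_dispersion,
                         mu = config$depth_mean), 500)
    counts[, j] <- as.integer(rmultinom(1, depth, comp))
  }
  table <- new_abundance_table(counts, tt$taxonomy, "otu_table")
  mapping <- data.frame(Group = group, row.names = samples,
                        stringsAsFactors = FALSE)
  attr(mapping, "group_cols") <- "Group"
  attr(mapping, "meta_cols") <- character()
  class(mapping) <- c("mapping_table", "data.frame")
  truth <- if (is.null(config$effects))
    data.frame(otu = character(), group = character(), fold = numeric())
  else data.frame(otu = tt$tree$tip.label[config$effects$otu],
                  group = paste0("G", config$effects$group),
                  fold = config$effects$fold)
  list(table = table, mapping = mapping, tree = tt$tree, truth = truth)
}

#' Simulate technical-replicate libraries of one sample
#'
#' All replicates share one true composition; each library re-draws its
#' composition from a Dirichlet centred on the truth with overdispersion
#' \code{noise} (the Dirichlet concentration is \code{1/noise};
#' \code{noise = 0} gives pure multinomial resampling) and then multinomial
#' read counts at a negative-binomial depth.
#'
#' @param n_replicates number of libraries (default 10, as in a
#'   repeat-sequencing experiment of a single faecal sample).
#' @param n_otus,depth_mean,depth_dispersion,seed as in [sim_config()].
#' @param noise overdispersion of the between-library composition
#'   (default 0.002, mild technical variability).
#' @return an \code{otu_table} of replicate libraries with attribute
#'   \code{true_composition}.
#' @export
simulate_replicates <- function(n_replicates = 10, n_otus = 100,
                                depth_mean = 20000, depth_dispersion = 10,
                                noise = 0.002, seed = 1L) {
  stopifnot(n_replicates >= 2, noise >= 0)
  set.seed(seed)
  p <- 0.93^seq_len(n_otus)
  truth <- rdirichlet1(50 * p / sum(p))
  samples <- sprintf("R%02d", seq_len(n_replicates))
  counts <- matrix(0L, n_otus, n_replicates,
                   dimnames = list(paste0("OTU_", seq_len(n_otus)), samples))
  for (j in seq_len(n_replicates)) {
    comp <- if (noise > 0) rdirichlet1(truth / noise) else truth
    depth <- max(rnbinom(1, size = depth_dispersion, mu = depth_mean), 500)
    counts[, j] <- as.integer(rmultinom(1, depth, comp))
  }
  taxonomy <- rep(list(c("Bacteria")), n_otus)
  names(taxonomy) <- rownames(counts)
  out <- new_abundance_table(counts, taxonomy, "otu_table")
  attr(out, "true_composition") <- truth
  out
}

#' Coefficient of variation of OTU abundances across replicates
#'
#' Per OTU: mean and CV (sd/mean, percent) of the relative abundance across
#' replicate libraries, plus the abundance band at the conventional 0.1%
#' and 0.5% breakpoints.
#'
#' @param table an \code{otu_table} of technical replicates (>= 2 samples).
#' @return data.frame \code{otu}, \code{mean_abundance} (percent),
#'   \code{cv} (percent, \code{NA} when the mean is 0), \code{band}.
#' @export
replicate_cv <- function(table) {
  if (ncol(table$values) < 2) stop("need at least 2 replicate samples")
  rel <- to_relative(table)$values
  m <- rowMeans(rel)
  s <- apply(rel, 1, sd)
  cv <- ifelse(m > 0, 100 * s / m, NA_real_)
  band <- cut(m, breaks = c(-Inf, 0.1, 0.5, Inf),
              labels = c("<0.1%", "0.1-0.5%", ">=0.5%"), right = FALSE)
  data.frame(otu = rownames(rel), mean_abundance = m, cv = cv,
             band = band, row.names = NULL)
}

#' Band summary of a replicate-CV table
#'
#' @param records output of [replicate_cv()].
#' @return data.frame per band: \code{band}, \code{n} (OTUs with defined
#'   CV), \code{mean_cv}.
#' @export
cv_band_summary <- function(records) {
  ok <- records[!is.na(records$cv), , drop = FALSE]
  agg <- stats::aggregate(ok$cv, by = list(band = ok$band), FUN = mean)
  cnt <- stats::aggregate(ok$cv, by = list(band = ok$band), FUN = length)
  data.frame(band = agg$band, n = cnt$x, mean_cv = agg$x)
}
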