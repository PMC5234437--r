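# Serial group comparisons.
#
# The testing cascade for relative-abundance variables:
#   1. near-zero zeroing: values below an abundance cutoff (default 0.5%)
#      are considered absent and set to 0;
#   2. zeros become missing (NA) — a zero says "not detected", not
#      "abundance exactly zero", and retaining it as a value masks shifts
#      among the samples where the taxon actually occurs;
#   3. prevalence gate: a variable is tested only if at least one group has
#      it present in MORE than 30% of its samples (strict >, matching the
#      4-of-10 convention);
#   4. median gate: at least one group median (over detected samples) must
#      exceed 1% relative abundance;
#   5. Kruskal-Wallis overall, pairwise Mann-Whitney for > 2 groups, and
#      Fisher's exact test on prevalence, each family BH-corrected across
#      variables.
# Gates apply only to relative-abundance variables; diversity values and
# numeric meta-variables go through the same tests ungated.

#' Default filter configuration for serial comparisons
#'
#' @param abundance_cutoff percent below which a value is set to absent
#'   (default 0.5; boundary values equal to the cutoff are kept).
#' @param prevalence_min fraction of samples in which a variable must be
#'   present, in at least one group, strict inequality (default 0.30).
#' @param median_min percent that at least one group median (over detected
#'   samples) must exceed, strict inequality (default 1.0).
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(abundance_cutoff = 0.5, prevalence_min = 0.30,
                          median_min = 1.0) {
  stopifnot(abundance_cutoff >= 0, prevalence_min >= 0, prevalence_min <= 1,
            median_min >= 0)
  structure(list(abundance_cutoff = abundance_cutoff,
                 prevalence_min = prevalence_min,
                 median_min = median_min),
            class = "filter_config")
}

#' Zero out near-zero relative abundances
#'
#' Values strictly below \code{cutoff} are set to 0 ("considered as
#' absent"); values at or above it are unchanged.
#'
#' @param x numeric matrix of relative abundances (variables x samples).
#' @param cutoff percent threshold, default 0.5.
#' @return matrix of the same shape.
#' @export
apply_abundance_cutoff <- function(x, cutoff = 0.5) {
  x[x < cutoff] <- 0
  x
}

#' Replace exact zeros by missing values
#'
#' @param x numeric matrix.
#' @return matrix with zeros replaced by \code{NA}; all downstream
#'   statistics use only the non-missing (detected) values.
#' @export
zeros_to_missing <- function(x) {
  x[x == 0] <- NA_real_
  x
}

#' Prevalence gate
#'
#' @param x matrix (variables x samples) after [zeros_to_missing()];
#'   presence = non-missing.
#' @param groups group label per sample.
#' @param prevalence_min minimum fraction, strict inequality.
#' @return list: \code{tested} logical per variable, \code{prevalence}
#'   matrix (variables x groups) of "positives/total" counts as fractions.
#' @export
prevalence_gate <- function(x, groups, prevalence_min = 0.30) {
  groups <- factor(as.character(groups))
  prev <- sapply(levels(groups), function(g) {
    idx <- which(groups == g)
    rowSums(!is.na(x[, idx, drop = FALSE])) / length(idx)
  })
  prev <- matrix(prev, nrow = nrow(x),
                 dimnames = list(rownames(x), levels(groups)))
  list(tested = apply(prev, 1, max) > prevalence_min, prevalence = prev)
}

#' Median gate
#'
#' @inheritParams prevalence_gate
#' @param median_min percent threshold, strict inequality.
#' @return list: \code{tested} logical per variable, \code{medians} matrix
#'   (variables x groups) of medians over non-missing values.
#' @export
median_gate <- function(x, groups, median_min = 1.0) {
  groups <- factor(as.character(groups))
  med <- sapply(levels(groups), function(g) {
    idx <- which(groups == g)
    apply(x[, idx, drop = FALSE], 1, median, na.rm = TRUE)
  })
  med <- matrix(med, nrow = nrow(x),
                dimnames = list(rownames(x), levels(groups)))
  top <- apply(med, 1, function(v) if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  list(tested = top > median_min, medians = med)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom; missing values are excluded.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return list \code{(H, p, df)}; \code{NULL} when fewer than two groups
#'   have non-missing values.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values)
  g <- factor(as.character(groups[ok]))
  if (nlevels(droplevels(g)) < 2) return(NULL)
  fit <- kruskal.test(values[ok], droplevels(g))
  list(H = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p-value when the smaller side has at most 8 observations
#' and there are no ties; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param a,b numeric vectors (missing values removed).
#' @return list \code{(U, p, exact)}; \code{NULL} if either side is empty
#'   after removing missing values.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NULL)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  fit <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  list(U = unname(fit$statistic), p = fit$p.value, exact = exact)
}

#' Fisher's exact test on prevalence
#'
#' Tests the groups x {present, absent} contingency table. Exact for 2x2
#' and for 2xk tables with total n <= 40; larger tables fall back to a
#' Monte-Carlo estimate with at least 1e5 draws (its simulation standard
#' error is reported).
#'
#' @param present logical (or NA) per sample; NA counts as absent.
#' @param groups group label per sample.
#' @param b Monte-Carlo replicates for large tables.
#' @return list \code{(p, method, mc_se)}.
#' @export
fisher_prevalence <- function(present, groups, b = 1e5) {
  groups <- factor(as.character(groups))
  present <- !is.na(present) & present
  tab <- table(groups, factor(present, levels = c(TRUE, FALSE)))
  n <- sum(tab)
  if (nlevels(groups) <= 2 || n <= 40) {
    fit <- fisher.test(tab)
    list(p = fit$p.value, method = "exact", mc_se = 0)
  } else {
    fit <- fisher.test(tab, simulate.p.value = TRUE, B = as.integer(b))
    p <- fit$p.value
    list(p = p, method = "monte-carlo", mc_se = sqrt(p * (1 - p) / b))
  }
}

#' Benjamini-Hochberg adjustment with missing pass-through
#'
#' Step-up FDR adjustment where the number of tests m is the count of
#' non-missing p-values; missing entries are passed through untouched.
#'
#' @param p numeric vector of p-values in [0, 1], NA allowed.
#' @return adjusted vector, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Serial group comparison of all variables
#'
#' Runs the full cascade (cutoff, zeros to missing, prevalence gate, median
#' gate, Kruskal-Wallis, pairwise Mann-Whitney when more than two groups,
#' Fisher prevalence test) over every row of \code{x} and applies BH
#' correction within each test family: Kruskal-Wallis across variables,
#' Mann-Whitney across all variable-pair tests pooled, Fisher across
#' variables.
#'
#' @param x numeric matrix, variables x samples (relative abundances in
#'   percent, or with \code{gated = FALSE} any numeric variables such as
#'   alpha-diversity or meta-variables).
#' @param groups group label per sample (column).
#' @param config a [filter_config()].
#' @param gated apply abundance/prevalence/median gates (TRUE for
#'   relative-abundance variables, FALSE for meta or diversity variables,
#'   for which only missing-value handling applies).
#' @return list of class \code{comparison_result}: \code{results}
#'   data.frame (one row per tested variable), \code{pairwise} data.frame
#'   (one row per variable x group pair), \code{skipped} data.frame with a
#'   single reason per skipped variable, \code{prevalence} and
#'   \code{medians} matrices.
#' @export
serial_comparison <- function(x, groups, config = filter_config(),
                              gated = TRUE) {
  stopifnot(is.matrix(x))
  groups <- factor(as.character(groups))
  if (ncol(x) != length(groups)) stop("groups must match columns of x")
  if (gated) {
    x <- apply_abundance_cutoff(x, config$abundance_cutoff)
    x <- zeros_to_missing(x)
  }
  pg <- prevalence_gate(x, groups,
                        if (gated) config$prevalence_min else 0)
  mg <- median_gate(x, groups, if (gated) config$median_min else 0)
  tested <- if (gated) pg$tested & mg$tested else
    rowSums(!is.na(x)) > 0
  reason <- ifelse(!pg$tested, "prevalence",
                   ifelse(!mg$tested, "median", NA_character_))
  vars <- rownames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(nrow(x)))
  res <- data.frame(variable = vars[tested], KW_H = NA_real_,
                    KW_p = NA_real_, fisher_p = NA_real_,
                    stringsAsFactors = FALSE)
  lev <- levels(groups)
  pair_idx <- if (length(lev) >= 2) utils::combn(lev, 2) else NULL
  pw <- NULL
  for (r in seq_len(nrow(res))) {
    i <- which(vars == res$variable[r])
    kw <- kruskal_wallis(x[i, ], groups)
    if (!is.null(kw)) { res$KW_H[r] <- kw$H; res$KW_p[r] <- kw$p }
    else reason[i] <- "prevalence"   # fewer than 2 non-empty groups
    fp <- fisher_prevalence(!is.na(x[i, ]), groups)
    res$fisher_p[r] <- fp$p
    if (!is.null(pair_idx))
      for (q in seq_len(ncol(pair_idx))) {
        a <- x[i, groups == pair_idx[1, q]]
        b <- x[i, groups == pair_idx[2, q]]
        mw <- mann_whitney(a, b)
        pw <- rbind(pw, data.frame(
          variable = vars[i], group1 = pair_idx[1, q],
          group2 = pair_idx[2, q],
          U = if (is.null(mw)) NA_real_ else mw$U,
          MW_p = if (is.null(mw)) NA_real_ else mw$p,
          stringsAsFactors = FALSE))
      }
  }
  dropped <- is.na(res$KW_p) & is.na(res$fisher_p)
  res <- res[!dropped, , drop = FALSE]
  res$KW_p_adj <- bh_adjust(res$KW_p)
  res$fisher_p_adj <- bh_adjust(res$fisher_p)
  if (!is.null(pw)) {
    pw <- pw[pw$variable %in% res$variable, , drop = FALSE]
    pw$MW_p_adj <- bh_adjust(pw$MW_p)
  }
  skipped <- data.frame(variable = vars[!tested],
                        reason = reason[!tested],
                        stringsAsFactors = FALSE)
  structure(list(results = res, pairwise = pw, skipped = skipped,
                 prevalence = pg$prevalence, medians = mg$medians,
                 filtered = x, groups = groups, config = config),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d tested, %d skipped variables\n",
              nrow(x$results), nrow(x$skipped)))
  if (nrow(x$results)) {
    top <- x$results[order(x$results$KW_p), , drop = FALSE]
    print(utils::head(top, 10), row.names = FALSE)
  }
  invisible(x)
}

# minimal violin: mirrored density polygon
draw_violin <- function(v, at, col) {
  v <- v[!is.na(v)]
  if (length(v) < 2 || sd(v) == 0) {
    graphics::segments(at - 0.3, median(v), at + 0.3, median(v), col = col)
    return(invisible())
  }
  d <- stats::density(v)
  w <- 0.4 * d$y / max(d$y)
  graphics::polygon(c(at - w, rev(at + w)), c(d$x, rev(d$x)),
                    col = grDevices::adjustcolor(col, 0.4), border = col)
}

#' Per-variable comparison plots
#'
#' One panel per requested variable in box, violin or dot style, with
#' per-group non-missing counts and the raw and adjusted p-values in the
#' title.
#'
#' @param result a \code{comparison_result}.
#' @param variables variables to plot (default: all tested).
#' @param style one of \code{"box"}, \code{"violin"}, \code{"dot"}.
#' @return invisibly, the variables plotted.
#' @export
comparison_plots <- function(result, variables = result$results$variable,
                             style = c("box", "violin", "dot")) {
  style <- match.arg(style)
  groups <- result$groups
  lev <- levels(groups)
  for (v in variables) {
    vals <- result$filtered[v, ]
    by_g <- split(vals, groups)
    n_g <- vapply(by_g, function(z) sum(!is.na(z)), integer(1))
    row <- result$results[result$results$variable == v, ]
    main <- sprintf("%s  (KW p = %.3g, adj = %.3g)", v,
                    row$KW_p[1], row$KW_p_adj[1])
    sub <- paste(sprintf("%s: n=%d", lev, n_g), collapse = "  ")
    if (style == "box") {
      graphics::boxplot(by_g, main = main, sub = sub, col = "grey85")
    } else {
      rng <- range(vals, na.rm = TRUE)
      if (!all(is.finite(rng))) rng <- c(0, 1)
      plot(NA, xlim = c(0.5, length(lev) + 0.5), ylim = rng,
           xaxt = "n", xlab = "", ylab = v, main = main, sub = sub)
      graphics::axis(1, at = seq_along(lev), labels = lev)
      for (gi in seq_along(lev)) {
        z <- by_g[[gi]]
        if (style == "violin") draw_violin(z, gi, gi + 1L)
        graphics::points(jitter(rep(gi, length(z)), amount = 0.1), z,
                         pch = 19, col = gi + 1L)
      }
    }
  }
  invisible(variables)
}
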