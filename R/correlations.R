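# Correlation analysis between meta-variables and taxonomic variables.
#
# Relative abundances are compositional: an independent change in one taxon
# moves every other proportion, which induces spurious (mostly negative)
# correlations. Taxonomic variables are therefore centred-log-ratio (CLR)
# transformed before Pearson correlation. Zeros are treated as missing
# (consistent with the comparison module), so the CLR geometric mean is
# taken over each sample's detected taxa only, after re-closing them to
# sum 1; no pseudocount is imputed unless requested.

#' Centred log-ratio transform with missing values
#'
#' Per sample (column), over detected (non-missing) taxa only:
#' \eqn{clr_i = \ln(p_i / g)} where the \eqn{p_i} are the detected
#' proportions re-closed to sum 1 and \eqn{g} is their geometric mean.
#' Detected CLR values of each sample sum to zero.
#'
#' @param x matrix taxa x samples of relative abundances with \code{NA} for
#'   non-detections (see [zeros_to_missing()]).
#' @param pseudocount optional value added to every cell before the
#'   transform (conventional alternative; keeps zeros as values instead of
#'   missing). Default \code{NULL} uses the missing-value treatment.
#' @return matrix of CLR values, \code{NA} where the input was missing;
#'   samples with no detected taxon are dropped with a warning.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  if (!is.null(pseudocount)) {
    x[is.na(x)] <- 0
    x <- x + pseudocount
  }
  detected <- colSums(!is.na(x) & x > 0)
  if (any(detected == 0)) {
    warning("sample(s) with no detected taxon dropped: ",
            paste(colnames(x)[detected == 0], collapse = ", "))
    x <- x[, detected > 0, drop = FALSE]
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v) & v > 0
    p <- v[ok] / sum(v[ok])
    out[ok, j] <- log(p) - mean(log(p))
    out[!ok, j] <- NA_real_
  }
  out
}

#' Centre and scale variables with missing values
#'
#' Per variable (row): subtract the mean and divide by the standard
#' deviation (denominator n - 1), both over non-missing values.
#' Zero-variance variables are dropped with a warning.
#'
#' @param x matrix variables x samples, \code{NA} allowed.
#' @return standardized matrix, possibly with fewer rows.
#' @export
center_scale <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, sd, na.rm = TRUE)
  bad <- is.na(sdv) | sdv == 0
  if (any(bad)) {
    warning("zero-variance variable(s) dropped: ",
            paste(rownames(x)[bad], collapse = ", "))
    x <- x[!bad, , drop = FALSE]
    mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  (x - mu) / sdv
}

#' Pearson correlation with p-value on pairwise-complete observations
#'
#' Two-sided p from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 degrees of
#' freedom; \eqn{|r| = 1} gives p = 0. Needs at least 2 complete pairs for
#' r and 3 for a p-value.
#'
#' @param x,y numeric vectors of equal length, \code{NA} allowed.
#' @return list \code{(r, p, n_obs)} with \code{NA} where undefined.
#' @export
pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) return(list(r = NA_real_, p = NA_real_, n_obs = n))
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n_obs = n))
  r <- cor(x[ok], y[ok])
  if (n < 3) return(list(r = r, p = NA_real_, n_obs = n))
  if (abs(r) >= 1 - 1e-14) return(list(r = sign(r), p = 0, n_obs = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2), n_obs = n)
}

#' Correlation analysis between meta-variables and taxa
#'
#' Taxonomic variables pass through the comparison module's near-zero
#' removal (cutoff then zeros to missing), a total-prevalence filter
#' (detected in at least \code{prevalence_min} of all samples — boundary
#' inclusive), CLR transform and standardization. Meta-variables are only
#' standardized. Pearson correlations are computed for every pair in
#' \code{mode} and BH-corrected across all pairs computed in the run.
#'
#' @param meta matrix meta-variables x samples (\code{NA} allowed), or
#'   \code{NULL} for taxa-only modes.
#' @param taxa matrix taxa x samples of relative abundances in percent, or
#'   \code{NULL} for \code{within_meta}.
#' @param mode which pairs: \code{"meta_vs_taxa"} (default),
#'   \code{"within_meta"}, \code{"within_taxa"}, \code{"all"}.
#' @param abundance_cutoff percent below which a taxon value is absent.
#' @param prevalence_min minimum overall detection fraction for a taxon to
#'   be tested (default 0.30, boundary inclusive).
#' @param pseudocount passed to [clr_transform()].
#' @return data.frame of class \code{correlation_result}: \code{var_x},
#'   \code{class_x}, \code{var_y}, \code{class_y}, \code{r}, \code{p},
#'   \code{p_adj}, \code{n_obs}. Attribute \code{transformed} carries the
#'   standardized data used.
#' @export
correlation_analysis <- function(meta = NULL, taxa = NULL,
                                 mode = c("meta_vs_taxa", "within_meta",
                                          "within_taxa", "all"),
                                 abundance_cutoff = 0.5,
                                 prevalence_min = 0.30,
                                 pseudocount = NULL) {
  mode <- match.arg(mode)
  tx <- NULL
  if (!is.null(taxa) && mode != "within_meta") {
    t1 <- zeros_to_missing(apply_abundance_cutoff(taxa, abundance_cutoff))
    keep <- rowMeans(!is.na(t1)) >= prevalence_min
    t1 <- t1[keep, , drop = FALSE]
    if (nrow(t1)) tx <- center_scale(clr_transform(t1, pseudocount))
  }
  mt <- if (!is.null(meta) && mode != "within_taxa")
    center_scale(meta) else NULL
  if (!is.null(tx) && !is.null(mt)) {
    common <- intersect(colnames(tx), colnames(mt))
    tx <- tx[, common, drop = FALSE]
    mt <- mt[, common, drop = FALSE]
  }
  pairs <- list()
  add_pairs <- function(a, cls_a, b, cls_b, within) {
    if (is.null(a) || (!within && is.null(b))) return()
    if (within) {
      if (nrow(a) < 2) return()
      cmb <- utils::combn(rownames(a), 2)
      for (q in seq_len(ncol(cmb)))
        pairs[[length(pairs) + 1]] <<-
          list(x = cmb[1, q], cx = cls_a, y = cmb[2, q], cy = cls_a)
    } else {
      for (i in rownames(a)) for (j in rownames(b))
        pairs[[length(pairs) + 1]] <<- list(x = i, cx = cls_a, y = j, cy = cls_b)
    }
  }
  if (mode %in% c("meta_vs_taxa", "all")) add_pairs(mt, "meta", tx, "taxonomic", FALSE)
  if (mode %in% c("within_meta", "all")) add_pairs(mt, "meta", NULL, NULL, TRUE)
  if (mode %in% c("within_taxa", "all")) add_pairs(tx, "taxonomic", NULL, NULL, TRUE)
  get_row <- function(id, cls) if (cls == "meta") mt[id, ] else tx[id, ]
  out <- data.frame(var_x = character(), class_x = character(),
                    var_y = character(), class_y = character(),
                    r = numeric(), p = numeric(), n_obs = integer(),
                    stringsAsFactors = FALSE)
  for (pr in pairs) {
    est <- pearson_with_p(get_row(pr$x, pr$cx), get_row(pr$y, pr$cy))
    out[nrow(out) + 1, ] <- list(pr$x, pr$cx, pr$y, pr$cy,
                                 est$r, est$p, est$n_obs)
  }
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("var_x", "class_x", "var_y", "class_y",
                 "r", "p", "p_adj", "n_obs")]
  attr(out, "transformed") <- list(meta = mt, taxa = tx)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Correlation circle-matrix and scatter plots
#'
#' (A) A circle matrix where circle area shrinks with the raw p-value and
#' colour encodes the sign of r; (B) for each pair below
#' \code{scatter_alpha} (adjusted p), a scatter of the transformed values
#' with the least-squares line, its 95% pointwise confidence band, and
#' r / p / adjusted p and n_obs annotated.
#'
#' @param records a \code{correlation_result}.
#' @param scatter_alpha adjusted-p threshold selecting pairs for scatter
#'   panels (default 0.05; \code{NULL} skips scatters).
#' @return invisibly, the records.
#' @export
correlation_plots <- function(records, scatter_alpha = 0.05) {
  xs <- unique(records$var_x); ys <- unique(records$var_y)
  plot(NA, xlim = c(0.5, length(ys) + 0.5), ylim = c(0.5, length(xs) + 0.5),
       xaxt = "n", yaxt = "n", xlab = "", ylab = "", main = "Correlations")
  graphics::axis(1, seq_along(ys), ys, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(xs), xs, las = 2, cex.axis = 0.7)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (is.na(rec$r)) next
    size <- 2 * (1 - min(rec$p, 1, na.rm = TRUE))
    graphics::points(match(rec$var_y, ys), match(rec$var_x, xs),
                     cex = max(size, 0.1), pch = 19,
                     col = if (rec$r >= 0) "firebrick" else "navy")
  }
  if (!is.null(scatter_alpha)) {
    tr <- attr(records, "transformed")
    sig <- records[!is.na(records$p_adj) & records$p_adj < scatter_alpha, ]
    for (i in seq_len(nrow(sig))) {
      rec <- sig[i, ]
      x <- if (rec$class_x == "meta") tr$meta[rec$var_x, ] else tr$taxa[rec$var_x, ]
      y <- if (rec$class_y == "meta") tr$meta[rec$var_y, ] else tr$taxa[rec$var_y, ]
      ok <- !is.na(x) & !is.na(y)
      plot(x[ok], y[ok], pch = 19, xlab = rec$var_x, ylab = rec$var_y,
           main = sprintf("r = %.2f, p = %.3g, adj = %.3g", rec$r, rec$p,
                          rec$p_adj),
           sub = sprintf("n_obs = %d", rec$n_obs))
      fit <- lm(y[ok] ~ x[ok])
      ord <- order(x[ok])
      pred <- predict(fit, interval = "confidence")
      graphics::lines(x[ok][ord], pred[ord, "fit"], col = "firebrick")
      graphics::lines(x[ok][ord], pred[ord, "lwr"], col = "firebrick", lty = 2)
      graphics::lines(x[ok][ord], pred[ord, "upr"], col = "firebrick", lty = 2)
    }
  }
  invisible(records)
}
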