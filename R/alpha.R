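# Alpha-diversity: richness, Shannon and Simpson indices and their
# effective numbers (Hill numbers of order 1 and 2).
#
# All quantities are computed on normalized counts after discarding OTUs at
# or below a small floor (default 0.5 normalized counts): depth scaling can
# produce fractional phantom counts below half a read, and those carry no
# evidence of presence. The same filtered community is used for every index
# so that richness, exp(H) and 1/D are comparable.

#' Species richness above a floor
#'
#' @param x numeric vector of (normalized) counts for one sample.
#' @param floor detection floor; an OTU counts as present when its value is
#'   strictly greater than \code{floor}.
#' @return integer number of detected OTUs.
#' @export
richness <- function(x, floor = 0.5) {
  as.integer(sum(x > floor))
}

#' Shannon index (natural log)
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \ln p_i} over a proportion vector.
#'
#' @param p non-negative proportions; renormalized internally to sum to 1.
#' @return H in nats.
#' @export
shannon <- function(p) {
  if (all(p == 0)) stop("all-zero proportion vector")
  if (any(p < 0)) stop("negative proportions")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson index
#'
#' \eqn{D = \sum p_i^2}, the probability that two reads drawn with
#' replacement belong to the same OTU.
#'
#' @inheritParams shannon
#' @return D in (0, 1].
#' @export
simpson <- function(p) {
  if (all(p == 0)) stop("all-zero proportion vector")
  if (any(p < 0)) stop("negative proportions")
  p <- p / sum(p)
  sum(p^2)
}

#' Effective numbers of species
#'
#' Converts the Shannon and Simpson indices to the number of equally
#' abundant species that would produce the same index value: \eqn{\exp(H)}
#' (Hill number of order 1) and \eqn{1/D} (inverse Simpson, order 2).
#'
#' @param H Shannon index in nats.
#' @param D Simpson index in (0, 1].
#' @return named numeric vector \code{c(eff_shannon, eff_simpson)}.
#' @export
effective_numbers <- function(H, D) {
  if (D <= 0) stop("Simpson index must be > 0")
  if (H < 0) stop("Shannon index must be >= 0")
  c(eff_shannon = exp(H), eff_simpson = 1 / D)
}

#' Per-sample alpha-diversity table
#'
#' @param table a \code{norm_table} (normalized counts).
#' @param floor detection floor applied before computing proportions, so all
#'   five quantities describe the same filtered community; 0 disables it.
#' @return data.frame with one row per sample and columns \code{richness},
#'   \code{shannon}, \code{simpson}, \code{eff_shannon}, \code{eff_simpson}.
#'   A sample with no OTU above the floor gets richness 0 and \code{NA}
#'   indices.
#' @export
alpha_table <- function(table, floor = 0.5) {
  v <- table$values
  out <- data.frame(sample = colnames(v), richness = NA_integer_,
                    shannon = NA_real_, simpson = NA_real_,
                    eff_shannon = NA_real_, eff_simpson = NA_real_,
                    row.names = NULL)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    keep <- x > floor
    out$richness[j] <- as.integer(sum(keep))
    if (!any(keep)) next
    p <- x[keep] / sum(x[keep])
    H <- shannon(p)
    D <- simpson(p)
    eff <- effective_numbers(H, D)
    out$shannon[j] <- H
    out$simpson[j] <- D
    out$eff_shannon[j] <- eff[["eff_shannon"]]
    out$eff_simpson[j] <- eff[["eff_simpson"]]
  }
  out
}
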