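test_that("abundance cutoff and zero-masking follow the boundary conventions", {
  m <- matrix(c(0.4, 0.5, 1.2, 0), 1, 4)
  cut <- apply_abundance_cutoff(m, 0.5)
  expect_equal(unname(cut[1, ]), c(0, 0.5, 1.2, 0))   # 0.5 itself is kept
  expect_equal(apply_abundance_cutoff(m, 0), m)
  masked <- zeros_to_missing(cut)
  expect_equal(unname(masked[1, ]), c(NA, 0.5, 1.2, NA))
  expect_identical(sum(!is.na(masked)), 2L)
})

test_that("prevalence gate uses a strict more-than comparison", {
  groups <- rep(c("a", "b"), each = 10)
  x <- rbind(v1 = c(rep(1, 4), rep(NA, 6), rep(NA, 10)),   # 4/10 vs 0/10
             v2 = c(rep(1, 3), rep(NA, 7), rep(1, 3), rep(NA, 7)))  # 3 vs 3
  pg <- prevalence_gate(x, groups, 0.30)
  expect_true(pg$tested[["v1"]])        # 0.4 > 0.3
  expect_false(pg$tested[["v2"]])       # 0.3 is not > 0.3
  expect_equal(pg$prevalence["v1", ], c(a = 0.4, b = 0))
  pg0 <- prevalence_gate(x, groups, 0)
  expect_true(all(pg0$tested))
})

test_that("median gate compares group medians over detected values", {
  groups <- rep(c("a", "b"), each = 5)
  x <- rbind(low = c(rep(0.25, 5), rep(0.70, 5)),
             high = c(rep(0.8, 5), rep(1.2, 5)))
  mg <- median_gate(x, groups, 1.0)
  expect_false(mg$tested[["low"]])      # 0.25% -> 0.70% stays untested
  expect_true(mg$tested[["high"]])
  expect_equal(mg$medians["low", ], c(a = 0.25, b = 0.70))
  expect_true(all(median_gate(x, groups, 0)$tested))
})

test_that("rank tests match hand and enumeration results", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7)
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE))
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)               # 2 / choose(6, 3)
  expect_true(mw$exact)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$p, mw$p)  # symmetry
  expect_null(mann_whitney(numeric(), c(1, 2)))
})

test_that("exact Mann-Whitney equals exhaustive rank-split enumeration", {
  enum_p <- function(a, b) {
    n <- length(a) + length(b)
    vals <- c(a, b)
    u_obs <- sum(rank(vals)[seq_along(a)]) -
      length(a) * (length(a) + 1) / 2
    mu <- length(a) * length(b) / 2
    splits <- utils::combn(n, length(a))
    us <- apply(splits, 2, function(ia)
      sum(rank(vals)[ia]) - length(a) * (length(a) + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  }
  set.seed(17)
  for (rep in seq_len(20)) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(100, na + nb)        # no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p, enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("Fisher prevalence test is exact on small tables", {
  p <- fisher_prevalence(c(rep(FALSE, 5), rep(TRUE, 5)),
                         rep(c("a", "b"), each = 5))
  expect_equal(p$p, 2 / 252)            # hypergeometric enumeration
  eq <- fisher_prevalence(rep(c(TRUE, TRUE, FALSE, FALSE, TRUE), 2),
                          rep(c("a", "b"), each = 5))
  expect_equal(eq$p, 1)
  swap <- fisher_prevalence(c(rep(TRUE, 5), rep(FALSE, 5)),
                            rep(c("a", "b"), each = 5))
  expect_equal(swap$p, 2 / 252)         # group order irrelevant
})

test_that("BH adjustment is step-up with missing pass-through", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, NA, 0.5)), c(0.08, NA, 0.5))
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in order stats
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("serial comparison recovers a planted shift and respects gates", {
  set.seed(23)
  n <- 12
  groups <- rep(c("a", "b"), each = n)
  x <- matrix(rlnorm(20 * 2 * n, meanlog = 1, sdlog = 0.3), 20, 2 * n,
              dimnames = list(paste0("V", 1:20), NULL))
  x[1, groups == "b"] <- x[1, groups == "b"] * 6   # strong planted effect
  x <- 100 * sweep(x, 2, colSums(x), `/`)
  res <- serial_comparison(x, groups, filter_config(abundance_cutoff = 0,
                                                    prevalence_min = 0.3,
                                                    median_min = 0))
  expect_identical(res$results$variable[which.min(res$results$KW_p_adj)],
                   "V1")
  expect_true(all(res$results$KW_p_adj >= res$results$KW_p, na.rm = TRUE))
  # all gates disabled: every variable tested
  res0 <- serial_comparison(x, groups, filter_config(0, 0, 0))
  expect_identical(nrow(res0$results), 20L)
  expect_identical(nrow(res0$skipped), 0L)
  # two groups: pairwise block is the single Mann-Whitney per variable
  expect_identical(nrow(res0$pairwise), 20L)
  # skipped variables carry exactly one reason
  resg <- serial_comparison(x, groups, filter_config(2.0, 0.9, 1.0))
  expect_true(all(resg$skipped$reason %in% c("prevalence", "median")))
})

test_that("raising any gate never grows the tested set", {
  set.seed(29)
  groups <- rep(c("a", "b"), each = 8)
  x <- matrix(rlnorm(30 * 16, 0, 1.5), 30, 16,
              dimnames = list(paste0("V", 1:30), NULL))
  x <- 100 * sweep(x, 2, colSums(x), `/`)
  tested_set <- function(cfg)
    serial_comparison(x, groups, cfg)$results$variable
  base <- tested_set(filter_config(0.5, 0.30, 1.0))
  expect_true(all(tested_set(filter_config(1.0, 0.30, 1.0)) %in% base))
  expect_true(all(tested_set(filter_config(0.5, 0.50, 1.0)) %in% base))
  expect_true(all(tested_set(filter_config(0.5, 0.30, 2.0)) %in% base))
})

test_that("null data keep the raw KW size near nominal and BH below it", {
  set.seed(37)
  groups <- rep(c("a", "b"), each = 15)
  p_raw <- c(); p_adj <- c()
  for (rep in seq_len(40)) {   # 40 x 100 null variables (scaled for runtime)
    x <- matrix(rnorm(100 * 30), 100, 30)
    ps <- apply(x, 1, function(v) kruskal_wallis(v, groups)$p)
    p_raw <- c(p_raw, ps)
    p_adj <- c(p_adj, bh_adjust(ps))
  }
  frac <- mean(p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p_raw))
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_lte(mean(p_adj < 0.05), 0.05)
})

test_that("comparison plots render in all three styles", {
  set.seed(41)
  groups <- rep(c("a", "b"), each = 5)
  x <- matrix(c(rlnorm(5, 0, 0.1), rlnorm(5, 2, 0.1),
                rlnorm(10, 1, 0.2)), 2, 10, byrow = TRUE,
              dimnames = list(c("V1", "V2"), NULL))
  x <- 100 * sweep(x, 2, colSums(x), `/`)
  res <- serial_comparison(x, groups, filter_config(0, 0, 0))
  pdf(NULL)
  for (s in c("box", "violin", "dot"))
    expect_identical(comparison_plots(res, "V1", style = s), "V1")
  dev.off()
})
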