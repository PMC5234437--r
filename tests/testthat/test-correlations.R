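test_that("CLR transform matches closed forms and sums to zero", {
  x <- matrix(c(50, 25, 25), 3, 1,
              dimnames = list(paste0("t", 1:3), "s1"))
  clr <- clr_transform(x)
  g <- prod(c(0.5, 0.25, 0.25))^(1 / 3)
  expect_equal(unname(clr[, 1]),
               c(log(0.5 / g), log(0.25 / g), log(0.25 / g)))
  expect_equal(sum(clr[, 1]), 0)
  # uniform sample: all zeros; missing entries stay missing
  u <- matrix(c(25, 25, NA, 50), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  cu <- clr_transform(u)
  expect_equal(unname(cu[, 1]), c(0, 0))
  expect_true(is.na(cu[1, 2]))
  expect_equal(cu[2, 2], 0)        # single detected taxon re-closes to 1
  # detected values always sum to zero per sample
  set.seed(3)
  m <- matrix(rlnorm(60), 6, 10)
  m[sample(60, 15)] <- NA
  cm <- clr_transform(m)
  expect_true(all(abs(colSums(cm, na.rm = TRUE)) < 1e-10))
  # all-missing sample is dropped with a warning
  bad <- matrix(c(1, 2, NA, NA), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(out <- clr_transform(bad), "s2")
  expect_identical(colnames(out), "s1")
})

test_that("center_scale standardizes over non-missing values", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("v", NULL))
  expect_equal(unname(center_scale(x)[1, ]), c(-1, 0, 1))
  # idempotent on standardized input
  expect_equal(center_scale(center_scale(x)), center_scale(x),
               tolerance = 1e-12)
  xm <- matrix(c(1, 2, 3, NA), 1, 4, dimnames = list("v", NULL))
  expect_equal(unname(center_scale(xm)[1, ]), c(-1, 0, 1, NA))
  const <- rbind(v = c(1, 2, 3), flat = c(5, 5, 5))
  expect_warning(out <- center_scale(const), "flat")
  expect_identical(rownames(out), "v")
})

test_that("Pearson with p handles perfect, orthogonal and short cases", {
  pp <- pearson_with_p(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pp$r, 1); expect_equal(pp$p, 0); expect_identical(pp$n_obs, 3L)
  expect_equal(pearson_with_p(c(1, 2, 3), c(-1, -2, -3))$r, -1)
  # orthogonal after centering, n = 4
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  po <- pearson_with_p(x, y)
  expect_equal(po$r, 0); expect_equal(po$p, 1)
  # n_obs counts pairwise-complete observations
  pn <- pearson_with_p(c(1, 2, NA, 4), c(1, NA, 3, 5))
  expect_identical(pn$n_obs, 2L)
  expect_true(is.na(pn$p))
  expect_true(is.na(pearson_with_p(c(1, NA), c(NA, 1))$r))
  # cross-check the t-distribution p against cor.test
  set.seed(13)
  a <- rnorm(20); b <- a + rnorm(20)
  mine <- pearson_with_p(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value)
})

test_that("correlation analysis finds a planted meta-taxon association", {
  set.seed(19)
  n <- 40
  taxa <- matrix(rlnorm(15 * n, 1, 0.5), 15, n,
                 dimnames = list(paste0("OTU_", 1:15),
                                 paste0("S", seq_len(n))))
  taxa <- 100 * sweep(taxa, 2, colSums(taxa), `/`)
  clr5 <- clr_transform(zeros_to_missing(taxa))["OTU_5", ]
  meta <- rbind(ph = clr5 + rnorm(n, sd = 0.1),
                noise = rnorm(n))
  colnames(meta) <- colnames(taxa)
  recs <- correlation_analysis(meta, taxa, mode = "meta_vs_taxa",
                               abundance_cutoff = 0, prevalence_min = 0)
  expect_identical(nrow(recs), 30L)
  best <- recs[which.max(abs(recs$r)), ]
  expect_identical(best$var_x, "ph")
  expect_identical(best$var_y, "OTU_5")
  expect_identical(which.min(recs$p_adj), which.max(abs(recs$r)))
  expect_true(all(recs$p_adj >= recs$p, na.rm = TRUE))
  expect_true(all(recs$n_obs == n))
  # affine rescaling of a meta-variable leaves r untouched
  meta2 <- meta; meta2["ph", ] <- 3 - 7 * meta2["ph", ]
  recs2 <- correlation_analysis(meta2, taxa, mode = "meta_vs_taxa",
                                abundance_cutoff = 0, prevalence_min = 0)
  expect_equal(abs(recs2$r), abs(recs$r), tolerance = 1e-12)
})

test_that("modes control the pair set and prevalence filters taxa", {
  set.seed(43)
  n <- 20
  meta <- matrix(rnorm(4 * n), 4, n,
                 dimnames = list(paste0("m", 1:4), paste0("S", 1:n)))
  taxa <- matrix(rlnorm(6 * n, 2, 0.4), 6, n,
                 dimnames = list(paste0("t", 1:6), paste0("S", 1:n)))
  taxa <- 100 * sweep(taxa, 2, colSums(taxa), `/`)
  wm <- correlation_analysis(meta, NULL, mode = "within_meta")
  expect_identical(nrow(wm), 6L)                      # 4 choose 2
  # a taxon detected in under 30% of samples is absent from the records
  taxa["t6", ] <- 0
  taxa["t6", 1:5] <- 5                                # 5/20 = 25%
  mv <- correlation_analysis(meta, taxa, mode = "meta_vs_taxa",
                             abundance_cutoff = 0.5, prevalence_min = 0.30)
  expect_false("t6" %in% mv$var_y)
  # the 30% boundary itself is inclusive
  taxa["t6", 1:6] <- 5                                # 6/20 = 30%
  mv2 <- correlation_analysis(meta, taxa, mode = "meta_vs_taxa",
                              abundance_cutoff = 0.5, prevalence_min = 0.30)
  expect_true("t6" %in% mv2$var_y)
})

test_that("CLR removes the spurious correlations that closure induces", {
  set.seed(47)
  D <- 40; n <- 100
  raw_vc <- numeric(); clr_cc <- numeric()
  for (rep in seq_len(60)) {
    a <- matrix(1, D, n)
    a[1, ] <- exp(rnorm(n, log(4), 0.5))   # one taxon varies, others constant
    counts <- vapply(seq_len(n), function(j)
      rmultinom(1, 20000, a[, j])[, 1], numeric(D))
    rel <- 100 * sweep(counts, 2, colSums(counts), `/`)
    rownames(rel) <- paste0("t", seq_len(D))
    cr <- cor(t(rel))
    raw_vc <- c(raw_vc, mean(cr[1, -1]))
    cl <- cor(t(clr_transform(zeros_to_missing(rel))),
              use = "pairwise.complete.obs")
    cc <- cl[2:11, 2:11]
    clr_cc <- c(clr_cc, mean(abs(cc[upper.tri(cc)])))
  }
  # raw proportions: strong spurious negative correlation with the driver
  expect_lt(mean(raw_vc), -0.3)
  # CLR: pairs of truly constant taxa are centred on zero
  expect_lt(mean(clr_cc), 0.1)
})

test_that("BH-adjusted type-I error on null correlation data stays nominal", {
  set.seed(53)
  hits <- 0; total <- 0
  for (rep in seq_len(60)) {
    meta <- matrix(rnorm(3 * 25), 3, 25,
                   dimnames = list(paste0("m", 1:3), paste0("S", 1:25)))
    taxa <- matrix(rlnorm(8 * 25, 2, 0.3), 8, 25,
                   dimnames = list(paste0("t", 1:8), paste0("S", 1:25)))
    taxa <- 100 * sweep(taxa, 2, colSums(taxa), `/`)
    recs <- correlation_analysis(meta, taxa, abundance_cutoff = 0,
                                 prevalence_min = 0)
    hits <- hits + sum(recs$p_adj < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(recs$p_adj))
  }
  expect_lte(hits / total, 0.05)
})

test_that("correlation plots draw the circle matrix and scatters", {
  set.seed(59)
  meta <- matrix(rnorm(2 * 15), 2, 15,
                 dimnames = list(c("m1", "m2"), paste0("S", 1:15)))
  taxa <- matrix(rlnorm(2 * 15, 2, 0.3), 2, 15,
                 dimnames = list(c("t1", "t2"), paste0("S", 1:15)))
  taxa <- 100 * sweep(taxa, 2, colSums(taxa), `/`)
  meta["m1", ] <- clr_transform(taxa)["t1", ] + rnorm(15, sd = 0.05)
  recs <- correlation_analysis(meta, taxa, abundance_cutoff = 0,
                               prevalence_min = 0)
  pdf(NULL)
  expect_no_error(correlation_plots(recs))
  dev.off()
})
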