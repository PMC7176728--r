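test_that("median-of-ratios size factors match hand arithmetic", {
  x <- make_counts(matrix(c(10, 20, 30, 10, 20, 30), 3, 2))
  expect_equal(unname(size_factors(x)), c(1, 1))

  # sample2 = 2 x sample1: ratios are 1/sqrt(2) and sqrt(2) after rescaling
  y <- make_counts(cbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(unname(size_factors(y)), c(1 / sqrt(2), sqrt(2)))

  single <- make_counts(matrix(c(5, 9), 2, 1))
  expect_equal(unname(size_factors(single)), 1)

  # no gene expressed in every sample -> explicit error, no silent fallback
  z <- make_counts(cbind(c(0, 5), c(5, 0)))
  expect_error(size_factors(z), "pseudo-reference")

  expect_equal(prod(size_factors(y)), 1)  # geometric mean 1
})

test_that("size factors agree with the DESeq2 median-ratio estimator", {
  set.seed(11)
  m <- matrix(rnbinom(300, mu = 50, size = 5) + 1, 30, 10)
  x <- make_counts(m)
  ours <- size_factors(x)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("the variance-stabilizing transform is a scaled log2 with the expected fixed points", {
  x <- make_counts(matrix(c(0, 31, 8, 0, 31, 8), 3, 2))
  tm <- vst_transform(x)
  expect_equal(unname(tm$size_factors), c(1, 1))
  expect_equal(tm$values["G01", "S01"], 0)
  expect_equal(tm$values["G02", "S01"], 5)  # log2(32)

  # monotone within sample: rank order preserved from counts
  set.seed(1)
  y <- make_counts(matrix(rpois(60, 40), 20, 3))
  tmy <- vst_transform(y)
  for (j in 1:3)
    expect_equal(order(tmy$values[, j]), order(y$values[, j]))

  # doubling all counts of one sample changes transformed values only
  # through the vanishing +1 offset at large counts
  big <- make_counts(cbind(a = c(2000, 5000, 9000), b = 2 * c(2000, 5000, 9000)))
  tb <- vst_transform(big)
  expect_lt(max(abs(tb$values[, 1] - tb$values[, 2])), 0.02)
})

test_that("counts_to_tpm normalizes to one million with length weighting", {
  x <- make_counts(matrix(rep(25, 8), 4, 2))
  len <- setNames(rep(100, 4), rownames(x$values))
  tpm <- counts_to_tpm(x, len)
  expect_equal(unname(tpm$values[, 1]), rep(250000, 4))

  y <- make_counts(matrix(c(10, 10), 2, 1))
  tpm2 <- counts_to_tpm(y, setNames(c(1, 2), rownames(y$values)))
  expect_equal(unname(tpm2$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(unname(colSums(tpm2$values)), 1e6, tolerance = 1e-6)

  z <- make_counts(matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(counts_to_tpm(z, setNames(c(1, 1), rownames(z$values))),
               "zero-depth")
})

test_that("expression and variance filters use strict thresholds", {
  tm <- make_tm(rbind(c(5, 5), c(4, 8), c(9, 9), c(0, 4), c(5.1, 5.1)))
  out <- filter_expressed(tm, 5)
  expect_identical(rownames(out$matrix$values), c("G02", "G03", "G05"))
  expect_equal(sum(out$report$kept), 3)

  # variance: constant excluded, (0,4) has var 8 included, exactly 4 excluded
  tm2 <- make_tm(rbind(c(3, 3, 3), c(0, 4, 2), c(0, 2, 4)))
  # G02: var(c(0,4,2)) = 4 -> excluded (strict); G03: var(c(0,2,4)) = 4 -> excluded
  expect_identical(select_variable(tm2, 4), character(0))
  tm3 <- make_tm(rbind(c(0, 4), c(1, 1)))
  expect_identical(select_variable(tm3, 4), "G01")  # var 8 > 4
  expect_error(select_variable(make_tm(matrix(1, 2, 1)), 4), "2 samples")
})

test_that("the filter pipeline is idempotent", {
  set.seed(3)
  tm <- make_tm(matrix(runif(200, 0, 12), 20, 10))
  once <- filter_expressed(tm, 5)$matrix
  twice <- filter_expressed(once, 5)$matrix
  expect_identical(once$values, twice$values)
  expect_identical(select_variable(once, 4),
                   select_variable(twice, 4))
})

test_that("planted markers are invisible without contamination and variable with it", {
  hits_null <- 0
  hits_contam <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg0 <- simulation_config(f_same = 0, f_other = 0, seed = 100 + s,
                              samples_per_tissue = 20, n_background_genes = 80)
    sim0 <- simulate_bulk_study(cfg0)
    ids <- sim0$study$meta$sample_id[sim0$study$meta$tissue == "lung"]
    tm0 <- vst_transform(expression_matrix(
      sim0$study$expr$values[, ids], "counts"))
    vg0 <- select_variable(tm0, 4)
    if (!any(c("PRSS1", "PNLIP", "CELA3A", "CLPS") %in% vg0)) hits_null <- hits_null + 1

    cfg1 <- simulation_config(seed = 100 + s, samples_per_tissue = 20,
                              n_background_genes = 80, p_coseq = 0.5)
    sim1 <- simulate_bulk_study(cfg1)
    ids1 <- sim1$study$meta$sample_id[sim1$study$meta$tissue == "lung"]
    tm1 <- vst_transform(expression_matrix(
      sim1$study$expr$values[, ids1], "counts"))
    vg1 <- select_variable(tm1, 4)
    if (any(c("PRSS1", "PNLIP", "CELA3A", "CLPS") %in% vg1)) hits_contam <- hits_contam + 1
  }
  expect_gte(hits_null, ceiling(0.95 * n_seeds) - 1)
  expect_gte(hits_contam, n_seeds - 1)
})
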