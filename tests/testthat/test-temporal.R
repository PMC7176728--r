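make_flag_meta <- function() {
  sample_metadata(data.frame(
    sample_id = c("PAN1", "PAN2", "L1", "L2", "L3"),
    subject_id = c("P1", "P2", "P3", "P4", "P5"),
    tissue = c("pancreas", "pancreas", "lung", "lung", "lung"),
    isolation_date = c("2012-12-01", "2012-12-10", "2012-12-01", "2012-12-05", NA),
    sequencing_date = c("2013-01-09", "2013-01-20", "2013-01-09", "2013-01-05", NA),
    stringsAsFactors = FALSE))
}

test_that("batch flags are exact-date memberships with whole-day distances", {
  fl <- compute_flags(make_flag_meta(), "pancreas")
  expect_setequal(fl$sample_id, c("L1", "L2", "L3"))
  l1 <- fl[fl$sample_id == "L1", ]
  expect_true(l1$seq_same_day)
  expect_equal(l1$days_to_nearest_source_seq, 0)
  expect_true(l1$iso_same_day)
  l2 <- fl[fl$sample_id == "L2", ]
  expect_false(l2$seq_same_day)
  expect_equal(l2$days_to_nearest_source_seq, 4)
  l3 <- fl[fl$sample_id == "L3", ]
  expect_true(is.na(l3$seq_same_day))
  expect_equal(attr(fl, "n_missing_dates"), 1)
  expect_error(compute_flags(make_flag_meta(), "kidney"), "no samples of source")
})

test_that("tissue eligibility uses a strict off-day sample count", {
  fl <- data.frame(
    sample_id = paste0("S", 1:100),
    tissue = rep(c("A", "B"), c(41, 59)),
    seq_same_day = c(rep(FALSE, 41),          # A: 41 off-day -> eligible
                     rep(FALSE, 40), rep(TRUE, 19)),  # B: 40 off-day -> not
    iso_same_day = FALSE,
    days_to_nearest_source_seq = 1)
  class(fl) <- c("batch_flags", "data.frame")
  expect_identical(eligible_tissues(fl, 40), "A")
  expect_error(eligible_tissues(fl, 60), "no tissue")
})

test_that("rank-sum comparison matches exact enumeration and handles degenerate input", {
  mk <- function(x, y) {
    scores <- data.frame(sample_id = paste0("S", seq_along(c(x, y))),
                         score = c(x, y))
    fl <- data.frame(sample_id = scores$sample_id,
                     tissue = "t",
                     seq_same_day = rep(c(TRUE, FALSE), c(length(x), length(y))),
                     iso_same_day = FALSE, days_to_nearest_source_seq = 0)
    class(fl) <- c("batch_flags", "data.frame")
    list(scores = scores, flags = fl)
  }
  d <- mk(c(1, 2, 3), c(4, 5, 6))
  res <- rank_sum_compare(d$scores, d$flags, alternative = "less")
  expect_equal(res$statistic, 0)        # U = 0: every same-day below every off-day
  expect_equal(res$p_value, 1 / 20)     # one of choose(6,3) = 20 assignments
  expect_equal(res$method, "exact")

  d2 <- mk(c(1, 2, 3), c(1, 2, 3))
  res2 <- rank_sum_compare(d2$scores, d2$flags)
  expect_equal(res2$p_value, 1)

  d3 <- mk(numeric(0), c(1, 2))
  expect_error(rank_sum_compare(d3$scores, d3$flags), "non-empty")
})

test_that("exact and normal-approximation branches agree near the size boundary", {
  set.seed(31)
  x <- rnorm(20, 0.6); y <- rnorm(20)
  scores <- data.frame(sample_id = paste0("S", 1:40), score = c(x, y))
  fl <- data.frame(sample_id = scores$sample_id, tissue = "t",
                   seq_same_day = rep(c(TRUE, FALSE), each = 20),
                   iso_same_day = FALSE, days_to_nearest_source_seq = 0)
  class(fl) <- c("batch_flags", "data.frame")
  p_exact <- rank_sum_compare(scores, fl)$p_value   # 20 vs 20, tie-free: exact
  p_norm <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_norm) / p_exact, 0.1)
})

test_that("the mixed model recovers planted batch effects and a null", {
  sm <- simulate_mixed_scores(n_tissues = 6, samples_per_tissue = 150, seed = 5)
  fit <- fit_mixed_model(sm$scores, sm$flags, sm$meta, unique(sm$meta$tissue))
  expect_lt(abs(fit$beta_seq - 0.863), 0.1)
  expect_lt(abs(fit$beta_iso - 0.175), 0.1)
  expect_lt(abs(fit$sd_subject - 0.3), 0.1)
  expect_equal(fit$n, 900)

  null <- simulate_mixed_scores(n_tissues = 6, samples_per_tissue = 150,
                                beta_seq = 0, beta_iso = 0, seed = 6)
  fit0 <- fit_mixed_model(null$scores, null$flags, null$meta,
                          unique(null$meta$tissue))
  expect_true(abs(fit0$beta_seq) < 1.96 * fit0$se_seq + 1e-9 ||
                abs(fit0$beta_seq) < 0.1)
})

test_that("mixed-model estimates ignore tissue label names", {
  sm <- simulate_mixed_scores(n_tissues = 5, samples_per_tissue = 80, seed = 8)
  fit1 <- fit_mixed_model(sm$scores, sm$flags, sm$meta, unique(sm$meta$tissue))
  # bijectively rename tissues: reference coding changes, betas must not
  perm <- setNames(sprintf("z%02d", sample(5)), unique(sm$meta$tissue))
  sm$scores$tissue <- perm[sm$scores$tissue]
  sm$flags$tissue <- perm[sm$flags$tissue]
  sm$meta$tissue <- perm[sm$meta$tissue]
  fit2 <- fit_mixed_model(sm$scores, sm$flags, sm$meta, unique(sm$meta$tissue))
  expect_equal(fit2$beta_seq, fit1$beta_seq, tolerance = 1e-8)
  expect_equal(fit2$beta_iso, fit1$beta_iso, tolerance = 1e-8)
})

test_that("with no subject variance the random intercept is inert", {
  sm <- simulate_mixed_scores(n_tissues = 4, samples_per_tissue = 100,
                              sd_subject = 0, seed = 9)
  fit <- fit_mixed_model(sm$scores, sm$flags, sm$meta, unique(sm$meta$tissue))
  d <- merge(merge(sm$scores, sm$flags[, c("sample_id", "seq_same_day", "iso_same_day")],
                   by = "sample_id"), sm$meta[, c("sample_id", "subject_id")],
             by = "sample_id")
  ols <- stats::lm(score ~ seq_same_day + iso_same_day + tissue, data = d)
  expect_lt(abs(fit$beta_seq - coef(ols)[["seq_same_dayTRUE"]]), 0.01)
})

test_that("proximity summaries are monotone in window and threshold", {
  fl <- data.frame(sample_id = paste0("S", 1:8), tissue = "t",
                   seq_same_day = c(TRUE, rep(FALSE, 7)),
                   iso_same_day = FALSE,
                   days_to_nearest_source_seq = c(0, 1, 2, 3, 4, 5, 8, 10))
  class(fl) <- c("batch_flags", "data.frame")
  rc <- setNames(c(500, 400, 300, 200, 150, 120, 80, 500), fl$sample_id)
  all_in <- proximity_summary(rc, fl, read_threshold = 100, window_days = 10)
  expect_equal(all_in$fraction, 1)
  none <- proximity_summary(rc, fl, read_threshold = 100, window_days = 0)
  expect_equal(none$fraction, 0)
  f2 <- proximity_summary(rc, fl, 100, 2)$fraction
  f4 <- proximity_summary(rc, fl, 100, 4)$fraction
  expect_lte(f2, f4)
  # raising the read threshold cannot raise the fraction here
  f4_hi <- proximity_summary(rc, fl, 350, 4)$fraction
  expect_gte(f4, f4_hi)
  empty <- proximity_summary(rc, fl, read_threshold = 1e6, window_days = 4)
  expect_true(is.na(empty$fraction))
  expect_equal(empty$n_qualifying, 0L)
})

test_that("per-tissue OLS finds the same-day shift", {
  sm <- simulate_mixed_scores(n_tissues = 2, samples_per_tissue = 200,
                              sd_subject = 0, seed = 12)
  one <- sameday_ols(sm$scores, sm$flags, unique(sm$scores$tissue)[1])
  expect_lt(abs(one$beta - (0.863 + 0.175 * 0)) , 0.3)
  expect_lt(one$p_value, 1e-6)
})
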