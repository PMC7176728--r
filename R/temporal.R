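#' Batch co-occurrence flags relative to a source tissue
#'
#' For every non-source sample, tests exact calendar-date membership of its
#' sequencing (and isolation) date in the set of dates on which any
#' source-tissue sample was sequenced (isolated), and records the distance in
#' whole days to the nearest source sequencing day. Samples lacking a
#' sequencing date get `NA` flags and are excluded listwise by downstream
#' fits (counted in the `n_missing_dates` attribute).
#'
#' @param meta `sample_metadata`.
#' @param source_tissue Tissue that natively expresses the marker genes.
#' @return Data frame (`batch_flags`): `sample_id`, `tissue`, `seq_same_day`,
#'   `iso_same_day`, `days_to_nearest_source_seq`.
#' @export
compute_flags <- function(meta, source_tissue) {
  src <- meta[meta$tissue == source_tissue, , drop = FALSE]
  if (!nrow(src)) stop("no samples of source tissue '", source_tissue, "'")
  seq_days <- unique(src$sequencing_date[!is.na(src$sequencing_date)])
  iso_days <- unique(src$isolation_date[!is.na(src$isolation_date)])
  if (!length(seq_days)) stop("source tissue has no sequencing dates")
  rest <- meta[meta$tissue != source_tissue, , drop = FALSE]
  seq_same <- rest$sequencing_date %in% seq_days
  seq_same[is.na(rest$sequencing_date)] <- NA
  iso_same <- rest$isolation_date %in% iso_days
  iso_same[is.na(rest$isolation_date)] <- NA
  days <- vapply(seq_len(nrow(rest)), function(i) {
    d <- rest$sequencing_date[i]
    if (is.na(d)) return(NA_real_)
    min(abs(as.numeric(d - seq_days)))
  }, numeric(1))
  out <- data.frame(sample_id = rest$sample_id, tissue = rest$tissue,
                    seq_same_day = seq_same, iso_same_day = iso_same,
                    days_to_nearest_source_seq = days,
                    stringsAsFactors = FALSE)
  attr(out, "source_tissue") <- source_tissue
  attr(out, "n_missing_dates") <- sum(is.na(seq_same))
  class(out) <- c("batch_flags", "data.frame")
  out
}

#' Tissues eligible for the batch-association mixed model
#'
#' A tissue is eligible when, excluding the source tissue, it has strictly
#' more than `min_n` samples that were *not* sequenced on a source-tissue
#' day. This keeps the same-day indicator identifiable within every tissue.
#'
#' @param flags `batch_flags` from [compute_flags()].
#' @param min_n Strict lower bound on off-day sample counts (default 40).
#' @return Character vector of tissue names.
#' @export
eligible_tissues <- function(flags, min_n = 40) {
  stopifnot(inherits(flags, "batch_flags"))
  tab <- table(flags$tissue[!is.na(flags$seq_same_day) & !flags$seq_same_day])
  out <- names(tab)[tab > min_n]
  if (!length(out)) stop("no tissue has more than ", min_n, " off-day samples")
  out
}

#' Rank-sum comparison of scores by same-day sequencing
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of panel scores between samples
#' sequenced on a source-tissue day and the rest. Exact enumeration is used
#' when both groups have at most 20 observations and there are no ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param scores A `normalized_score_table` (or any data frame with
#'   `sample_id` and `score`).
#' @param flags `batch_flags`.
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @return List with `statistic` (W, same-day group first), `p_value`,
#'   `method`, `n_same`, `n_other`.
#' @export
rank_sum_compare <- function(scores, flags, alternative = "two.sided") {
  m <- merge(scores[, c("sample_id", "score")],
             flags[, c("sample_id", "seq_same_day")], by = "sample_id")
  m <- m[!is.na(m$seq_same_day) & !is.na(m$score), , drop = FALSE]
  x <- m$score[m$seq_same_day]
  y <- m$score[!m$seq_same_day]
  if (!length(x) || !length(y)) stop("both same-day and off-day groups must be non-empty")
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation",
       n_same = length(x), n_other = length(y))
}

#' Linear mixed model of panel score on batch flags
#'
#' Fits, by REML, `score ~ seq_same_day + iso_same_day + tissue +
#' (1 | subject)` over the samples of the eligible tissues: an intercept,
#' indicators for sharing a sequencing or isolation day with the source
#' tissue, tissue fixed effects (reference-level coding on the first tissue),
#' and a per-subject random intercept absorbing repeated sampling of the
#' same donor. Fixed effects are tested with Wald z-tests.
#'
#' @param scores A `normalized_score_table`.
#' @param flags `batch_flags`.
#' @param meta `sample_metadata` (for subject ids).
#' @param eligible Tissues to include (from [eligible_tissues()]).
#' @return An `association_result`: list with `coefficients` (data frame of
#'   estimate/SE/z/p per fixed effect), `beta_seq`, `beta_iso`,
#'   `se_seq`, `se_iso`, `sd_subject`, `sd_residual`, `n`, `tissues`,
#'   and the underlying `lme4` `fit`.
#' @export
fit_mixed_model <- function(scores, flags, meta, eligible) {
  d <- merge(scores[, c("sample_id", "tissue", "score")],
             flags[, c("sample_id", "seq_same_day", "iso_same_day")],
             by = "sample_id")
  d <- merge(d, meta[, c("sample_id", "subject_id")], by = "sample_id")
  d <- d[d$tissue %in% eligible, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("score", "seq_same_day", "iso_same_day")]), ,
         drop = FALSE]
  if (!nrow(d)) stop("no usable samples after eligibility and listwise deletion")
  d$tissue <- factor(d$tissue, levels = sort(unique(d$tissue)))
  for (tis in levels(d$tissue)) {
    sub <- d[d$tissue == tis, ]
    if (length(unique(sub$seq_same_day)) < 2 && nlevels(d$tissue) > 1 &&
        all(sub$seq_same_day))
      stop("tissue '", tis, "' is entirely same-day; design would be singular")
  }
  d$seq_same_day <- as.numeric(d$seq_same_day)
  d$iso_same_day <- as.numeric(d$iso_same_day)
  form <- if (nlevels(d$tissue) > 1)
    score ~ seq_same_day + iso_same_day + tissue + (1 | subject_id)
  else
    score ~ seq_same_day + iso_same_day + (1 | subject_id)
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      z = sm[, "Estimate"] / sm[, "Std. Error"],
                      row.names = NULL, stringsAsFactors = FALSE)
  coefs$p_value <- 2 * stats::pnorm(-abs(coefs$z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = coefs,
    beta_seq = coefs$estimate[coefs$term == "seq_same_day"],
    beta_iso = coefs$estimate[coefs$term == "iso_same_day"],
    se_seq = coefs$se[coefs$term == "seq_same_day"],
    se_iso = coefs$se[coefs$term == "iso_same_day"],
    sd_subject = vc$sdcor[vc$grp == "subject_id"],
    sd_residual = vc$sdcor[vc$grp == "Residual"],
    n = nrow(d), tissues = levels(d$tissue), fit = fit),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(paste0("association_result (n = %d, %d tissues)\n",
                     "  beta_seq = %.4f (SE %.4f), beta_iso = %.4f (SE %.4f)\n",
                     "  sd_subject = %.4f, sd_residual = %.4f\n"),
              x$n, length(x$tissues), x$beta_seq, x$se_seq,
              x$beta_iso, x$se_iso, x$sd_subject, x$sd_residual))
  invisible(x)
}

#' Per-tissue OLS of score on the same-day indicator
#'
#' Ordinary least squares of panel score on the sequencing same-day flag
#' within one tissue; the simple regression quoted alongside the mixed model.
#'
#' @param scores A `normalized_score_table`.
#' @param flags `batch_flags`.
#' @param tissue Tissue to restrict to.
#' @return List with `beta`, `se`, `p_value`, `n`.
#' @export
sameday_ols <- function(scores, flags, tissue) {
  d <- merge(scores[scores$tissue == tissue, c("sample_id", "score")],
             flags[, c("sample_id", "seq_same_day")], by = "sample_id")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$seq_same_day)) < 2)
    stop("tissue '", tissue, "' has only one flag level")
  fit <- stats::lm(score ~ seq_same_day, data = d)
  sm <- summary(fit)$coefficients
  list(beta = sm["seq_same_dayTRUE", "Estimate"],
       se = sm["seq_same_dayTRUE", "Std. Error"],
       p_value = sm["seq_same_dayTRUE", "Pr(>|t|)"], n = nrow(d))
}

#' Fraction of high-signal off-day samples near a source day
#'
#' Among samples *not* sequenced on a source day whose marker read count
#' exceeds `read_threshold`, the fraction sequenced within `window_days` of
#' the nearest source sequencing day.
#'
#' @param read_counts Named numeric vector of marker-gene read counts per
#'   sample (names are sample ids).
#' @param flags `batch_flags`.
#' @param read_threshold Count threshold (strict `>`, default 100).
#' @param window_days Window in days (inclusive `<=`, default 4).
#' @return List with `fraction` (`NA` if no sample qualifies), `n_qualifying`.
#' @export
proximity_summary <- function(read_counts, flags, read_threshold = 100,
                              window_days = 4) {
  stopifnot(inherits(flags, "batch_flags"))
  f <- flags[!is.na(flags$seq_same_day) & !flags$seq_same_day, , drop = FALSE]
  f <- f[f$sample_id %in% names(read_counts), , drop = FALSE]
  counts <- read_counts[f$sample_id]
  qual <- counts > read_threshold
  if (!any(qual))
    return(list(fraction = NA_real_, n_qualifying = 0L,
                note = "no off-day sample exceeds the read threshold"))
  within <- f$days_to_nearest_source_seq[qual] <= window_days
  list(fraction = mean(within), n_qualifying = sum(qual))
}
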