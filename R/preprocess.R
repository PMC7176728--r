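#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio of
#' that sample's count to the gene's geometric mean across samples, computed
#' over genes with nonzero counts in every sample. Factors are rescaled to
#' have geometric mean 1 so the transformed scale is anchored to the study.
#'
#' @param counts An `expr_matrix` with `value_kind = "counts"`.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts")
    stop("size factors are defined on raw counts, got value_kind = ", counts$value_kind)
  m <- counts$values
  if (ncol(m) == 1L) {
    f <- 1
    names(f) <- colnames(m)
    return(f)
  }
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no gene has nonzero counts in all samples; ",
         "a pseudo-reference fallback is deliberately not applied")
  sub <- m[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  f <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_geo)))
  f <- f / exp(mean(log(f)))
  f
}

#' Variance-stabilizing transform (size-factor scaled log2)
#'
#' Divides each sample's counts by its median-of-ratios size factor and
#' applies `log2(x + 1)`. This is a monotone, variance-stabilizing surrogate
#' for a dispersion-based transform: downstream correlation, clustering and
#' MAD-standardized scoring need only a common log-scale with depth removed,
#' not a particular mean-dispersion fit. The default thresholds used later
#' in the pipeline (mean > 5, variance > 4) are calibrated to this scale and
#' are exposed as arguments wherever they are applied.
#'
#' @param counts An `expr_matrix` of raw counts.
#' @return A `transformed_matrix`: list with `values` (log2 scale),
#'   `size_factors`.
#' @export
vst_transform <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts")
    stop("vst_transform expects raw counts, got value_kind = ", counts$value_kind)
  sf <- size_factors(counts)
  values <- log2(sweep(counts$values, 2, sf, "/") + 1)
  structure(list(values = values, size_factors = sf), class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("transformed_matrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert counts to TPM
#'
#' `tpm_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)` per
#' sample; columns sum to one million.
#'
#' @param counts An `expr_matrix` of raw counts.
#' @param gene_lengths Named numeric vector of positive lengths covering all
#'   genes in `counts` (bases; any consistent unit works).
#' @return An `expr_matrix` with `value_kind = "tpm"`.
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "expr_matrix"))
  genes <- gene_ids(counts)
  if (!all(genes %in% names(gene_lengths)))
    stop("gene_lengths missing entries for: ",
         paste(utils::head(setdiff(genes, names(gene_lengths))), collapse = ", "))
  len <- gene_lengths[genes]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- counts$values / len
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(counts$values)[denom == 0], collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expression_matrix(tpm, value_kind = "tpm")
}

#' Filter genes by mean transformed expression
#'
#' Keeps genes whose mean transformed value strictly exceeds the threshold;
#' used to drop low-expressed genes whose noisy ranks inflate correlations.
#'
#' @param tm A `transformed_matrix`.
#' @param mean_threshold Keep genes with mean value `>` this (default 5).
#' @return List with `matrix` (filtered `transformed_matrix`) and `report`
#'   (a `filter_report` with per-gene mean/variance and the kept flag).
#' @export
filter_expressed <- function(tm, mean_threshold = 5) {
  stopifnot(inherits(tm, "transformed_matrix"))
  means <- rowMeans(tm$values)
  vars <- if (ncol(tm$values) >= 2) apply(tm$values, 1, stats::var) else rep(NA_real_, nrow(tm$values))
  keep <- means > mean_threshold
  report <- structure(data.frame(
    gene_id = rownames(tm$values), mean = means, variance = vars,
    kept = keep, row.names = NULL, stringsAsFactors = FALSE),
    threshold = mean_threshold, class = c("filter_report", "data.frame"))
  out <- tm
  out$values <- tm$values[keep, , drop = FALSE]
  list(matrix = out, report = report)
}

#' Select highly variable genes
#'
#' Returns genes whose sample variance (unbiased, n-1 denominator) of
#' transformed values strictly exceeds the threshold.
#'
#' @param tm A `transformed_matrix`.
#' @param var_threshold Variance cutoff (default 4, strict `>`).
#' @return Character vector of gene ids.
#' @export
select_variable <- function(tm, var_threshold = 4) {
  stopifnot(inherits(tm, "transformed_matrix"))
  if (ncol(tm$values) < 2)
    stop("variance needs at least 2 samples")
  vars <- apply(tm$values, 1, stats::var)
  rownames(tm$values)[vars > var_threshold]
}
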