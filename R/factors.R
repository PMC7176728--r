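#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Composition-robust between-sample scaling. The reference sample is the one
#' whose library-size-scaled upper quartile is closest to the mean upper
#' quartile. For each sample, genes expressed in both it and the reference
#' contribute a log-ratio `M` and average abundance `A`; the most extreme
#' M-values (30% per tail) and A-values (5% per tail) are trimmed and the
#' remainder averaged with inverse-asymptotic-variance (precision) weights. The factor is `2^mean`,
#' and factors are rescaled to geometric mean 1. A pure depth change between
#' samples yields identical factors; only composition shifts move them.
#'
#' @param counts An `expr_matrix` of raw counts.
#' @param trim_m Per-tail trim fraction on M-values (default 0.3).
#' @param trim_a Per-tail trim fraction on A-values (default 0.05).
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$value_kind != "counts")
    stop("TMM is defined on raw counts")
  m <- counts$values
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero-depth sample(s)")
  uq <- apply(m, 2, function(col) stats::quantile(col, 0.75)) / lib
  ref_idx <- which.min(abs(uq - mean(uq)))
  ref <- m[, ref_idx]
  nR <- lib[ref_idx]
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair(m[, j], lib[j], ref, nR, trim_m, trim_a)
  }, numeric(1))
  names(f) <- colnames(m)
  f / exp(mean(log(f)))
}

# TMM factor for one sample against a fixed reference.
.tmm_pair <- function(obs, nO, ref, nR, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("sample shares no expressed genes with the TMM reference")
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(logR)
  rA <- rank(absE)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Drop lowly expressed genes on the TPM scale
#'
#' Removes genes with TPM below `tpm_threshold` in at least `fraction` of
#' samples.
#'
#' @param tpm An `expr_matrix` with `value_kind = "tpm"`.
#' @param tpm_threshold TPM cutoff (default 0.1, strict `<`).
#' @param fraction Fraction of samples (default 0.8, inclusive `>=`).
#' @return Character vector of kept gene ids.
#' @export
filter_low_tpm <- function(tpm, tpm_threshold = 0.1, fraction = 0.8) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$value_kind != "tpm") stop("filter_low_tpm expects TPM values")
  low_frac <- rowMeans(tpm$values < tpm_threshold)
  rownames(tpm$values)[low_frac < fraction]
}

#' Per-gene rank-based inverse-normal transform
#'
#' Replaces each gene's values by standard-normal quantiles of their ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))` (Blom offsets), with average ranks for
#' ties. Tames outliers while preserving order.
#'
#' @param values Numeric matrix, genes x samples.
#' @return Matrix of the same shape.
#' @export
inverse_normal <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  n <- ncol(values)
  if (n < 3) stop("need at least 3 samples")
  t(apply(values, 1, function(x) {
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
}

#' Estimate hidden expression factors (PCA)
#'
#' Principal-component factors of the gene-standardized matrix: each gene is
#' centered and scaled across samples, and the top-K right singular vectors
#' (orthonormal, samples x K) serve as hidden-confounder estimates. The
#' estimator sits behind a small contract (`factor_model`) so an alternative
#' hidden-factor method can be swapped in without touching the callers.
#'
#' @param values Numeric matrix, genes x samples.
#' @param k Number of factors, `0 <= k < min(genes, samples)`.
#' @return A `factor_model`: list with `k`, `factors` (samples x k,
#'   orthonormal columns), `loadings` (genes x k), `var_explained`.
#' @export
estimate_hidden_factors <- function(values, k) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (k < 0 || k >= min(dim(values)))
    stop("k must satisfy 0 <= k < min(genes, samples)")
  if (k == 0)
    return(structure(list(k = 0L,
                          factors = matrix(0, ncol(values), 0,
                                           dimnames = list(colnames(values), NULL)),
                          loadings = matrix(0, nrow(values), 0),
                          var_explained = numeric(0)),
                     class = "factor_model"))
  x <- t(scale(t(values)))
  x[is.na(x)] <- 0  # constant genes carry no direction
  sv <- svd(x, nu = k, nv = k)
  structure(list(k = as.integer(k),
                 factors = sv$v[, seq_len(k), drop = FALSE],
                 loadings = sv$u[, seq_len(k), drop = FALSE] %*%
                   diag(sv$d[seq_len(k)], k, k),
                 var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
            class = "factor_model")
}

#' Residualize expression on hidden factors
#'
#' Per gene, ordinary least-squares residuals of expression on the model's
#' factors plus an intercept. Residuals are orthogonal to every factor and
#' to the constant; with `k = 0` this reduces to per-gene centering.
#'
#' @param values Numeric matrix, genes x samples.
#' @param model A `factor_model` fit on the same samples.
#' @return Residual matrix, genes x samples.
#' @export
residualize <- function(values, model) {
  stopifnot(inherits(model, "factor_model"))
  if (model$k > 0 && nrow(model$factors) != ncol(values))
    stop("factor model sample count does not match the matrix")
  design <- cbind(1, model$factors)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("rank-deficient factor design")
  t(qr.resid(qr_d, t(values)))
}

#' Same-day regression beta for one gene
#'
#' Standardizes the gene's values (mean 0, SD 1) and regresses them on the
#' sequencing same-day indicator by OLS. The slope is the gene's same-day
#' shift in standard deviations; computed before factor correction and,
#' optionally, after residualizing on each requested number of factors.
#'
#' @param values Numeric matrix, genes x samples (normalized expression).
#' @param flags `batch_flags` covering the samples.
#' @param gene Gene id.
#' @param k_values Integer vector of factor counts to correct for
#'   (default none: before-correction only).
#' @param factor_values Matrix to estimate factors from (default `values`);
#'   lets factors be fit on the full transcriptome while testing one gene.
#' @return Data frame with one row per correction level: `gene`, `k`,
#'   `beta`, `se`, `p_value`, `n`.
#' @export
sameday_beta <- function(values, flags, gene, k_values = integer(0),
                         factor_values = values) {
  if (!gene %in% rownames(values)) stop("gene not in matrix: ", gene)
  ids <- intersect(colnames(values), flags$sample_id[!is.na(flags$seq_same_day)])
  if (length(ids) < 3) stop("need at least 3 flagged samples")
  flag <- flags$seq_same_day[match(ids, flags$sample_id)]
  if (length(unique(flag)) < 2) stop("all samples fall in one same-day group")
  one_fit <- function(y, k) {
    y <- as.numeric(scale(y))
    fit <- stats::lm(y ~ flag)
    sm <- summary(fit)$coefficients
    data.frame(gene = gene, k = k, beta = sm["flagTRUE", "Estimate"],
               se = sm["flagTRUE", "Std. Error"],
               p_value = sm["flagTRUE", "Pr(>|t|)"], n = length(y),
               stringsAsFactors = FALSE)
  }
  out <- one_fit(values[gene, ids], 0L)
  for (k in k_values) {
    model <- estimate_hidden_factors(factor_values[, ids, drop = FALSE], k)
    resid <- residualize(values[, ids, drop = FALSE], model)
    out <- rbind(out, one_fit(resid[gene, ], as.integer(k)))
  }
  rownames(out) <- NULL
  out
}
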