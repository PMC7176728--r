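#' Define a score panel
#'
#' A named set of marker genes whose MAD-standardized expression is averaged
#' into a per-sample contamination score.
#'
#' @param name Panel name.
#' @param genes Character vector of unique gene ids (>= 1).
#' @return A `score_panel`.
#' @export
score_panel <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("a panel needs at least one gene")
  if (anyDuplicated(genes)) stop("panel genes must be unique")
  structure(list(name = name, genes = genes), class = "score_panel")
}

#' Default contamination score panels
#'
#' The pancreas panel holds four highly expressed acinar genes (PRSS1,
#' CELA3A, PNLIP, CLPS); the esophagus panel the squamous keratins KRT4 and
#' KRT13. Any reads for these genes in unrelated tissues are suspect.
#'
#' @return Named list of `score_panel` objects.
#' @export
default_panels <- function() {
  list(
    pancreas = score_panel("pancreas", c("PRSS1", "CELA3A", "PNLIP", "CLPS")),
    esophagus = score_panel("esophagus", c("KRT4", "KRT13"))
  )
}

#' Per-sample normalized score for one gene within a tissue stratum
#'
#' `score_i = (x_i - mean(x)) / median(|x - median(x)|)` over the samples of
#' one tissue: a mean-centered numerator over a raw median-absolute-deviation
#' denominator (no consistency constant). A gene whose MAD is zero in the
#' stratum carries no usable variation and is flagged excluded rather than
#' scored.
#'
#' @param tm A `transformed_matrix`.
#' @param gene Gene id.
#' @param stratum_samples Sample ids forming the tissue stratum (>= 3).
#' @return List with `scores` (named numeric, `NA` if excluded) and
#'   `excluded` (logical).
#' @export
gene_score <- function(tm, gene, stratum_samples) {
  stopifnot(inherits(tm, "transformed_matrix"))
  if (!gene %in% rownames(tm$values)) stop("gene not in matrix: ", gene)
  missing <- setdiff(stratum_samples, colnames(tm$values))
  if (length(missing)) stop("samples not in matrix: ", paste(missing, collapse = ", "))
  if (length(stratum_samples) < 3) stop("stratum needs at least 3 samples")
  x <- tm$values[gene, stratum_samples]
  mad_raw <- stats::median(abs(x - stats::median(x)))
  if (mad_raw == 0)
    return(list(scores = stats::setNames(rep(NA_real_, length(x)), stratum_samples),
                excluded = TRUE))
  list(scores = (x - mean(x)) / mad_raw, excluded = FALSE)
}

#' Panel contamination scores per sample, within each tissue
#'
#' For every tissue stratum, computes the per-gene normalized scores and
#' averages them over the panel's non-excluded genes. Scores are strictly
#' tissue-internal: samples of other tissues never enter a stratum's mean or
#' MAD, so each tissue's score distribution is centered on its own behavior.
#'
#' @param tm A `transformed_matrix` covering the samples in `meta`.
#' @param panel A `score_panel`.
#' @param meta `sample_metadata` for the samples to score.
#' @param min_stratum Minimum samples per tissue stratum (default 3);
#'   smaller strata are skipped with a note in the `excluded` attribute.
#' @return Data frame (`normalized_score_table`): `sample_id`, `tissue`,
#'   `panel`, `score`, `n_genes_used`; per-gene component scores as extra
#'   `score.<gene>` columns. Attribute `excluded_genes` lists zero-MAD genes
#'   per tissue.
#' @export
panel_score <- function(tm, panel, meta, min_stratum = 3) {
  stopifnot(inherits(tm, "transformed_matrix"), inherits(panel, "score_panel"))
  meta <- meta[meta$sample_id %in% colnames(tm$values), , drop = FALSE]
  out <- list()
  excluded <- list()
  for (tis in unique(meta$tissue)) {
    ids <- meta$sample_id[meta$tissue == tis]
    if (length(ids) < min_stratum) {
      excluded[[tis]] <- sprintf("stratum too small (%d samples)", length(ids))
      next
    }
    genes <- intersect(panel$genes, rownames(tm$values))
    comp <- matrix(NA_real_, length(ids), length(genes),
                   dimnames = list(ids, genes))
    drop_genes <- character(0)
    for (g in genes) {
      gs <- gene_score(tm, g, ids)
      if (gs$excluded) drop_genes <- c(drop_genes, g) else comp[, g] <- gs$scores
    }
    used <- setdiff(genes, drop_genes)
    if (!length(used)) {
      stop(sprintf("all panel genes excluded (zero MAD) in tissue '%s'", tis))
    }
    if (length(drop_genes)) excluded[[tis]] <- drop_genes
    df <- data.frame(sample_id = ids, tissue = tis, panel = panel$name,
                     score = rowMeans(comp[, used, drop = FALSE]),
                     n_genes_used = length(used),
                     stringsAsFactors = FALSE, row.names = NULL)
    compdf <- as.data.frame(comp)
    names(compdf) <- paste0("score.", colnames(comp))
    out[[tis]] <- cbind(df, compdf, row.names = NULL)
  }
  if (!length(out)) stop("no tissue stratum large enough to score")
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "excluded_genes") <- excluded
  class(res) <- c("normalized_score_table", "data.frame")
  res
}

#' Expression-tier fractions for a gene outside its native tissue
#'
#' Among samples not belonging to `exclude_tissue`, the fraction of samples
#' falling in the TPM tiers `= 0`, `(0, 10)`, `[10, 100]`, `> 100`. Tier
#' boundaries are closed on the left of the middle tier, so a sample at
#' exactly TPM 10 (or 100) counts as `[10, 100]`.
#'
#' @param tpm An `expr_matrix` with `value_kind = "tpm"`.
#' @param gene Gene id.
#' @param meta `sample_metadata` (for tissue labels).
#' @param exclude_tissue Native tissue to drop before tallying.
#' @return Named numeric vector `zero`, `under10`, `mid`, `over100`
#'   (sums to 1).
#' @export
expression_tiers <- function(tpm, gene, meta, exclude_tissue) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$value_kind != "tpm") stop("expression_tiers expects TPM values")
  if (!gene %in% rownames(tpm$values)) stop("gene not in matrix: ", gene)
  keep <- meta$sample_id[meta$tissue != exclude_tissue]
  keep <- intersect(keep, colnames(tpm$values))
  if (!length(keep)) stop("no samples left after excluding tissue ", exclude_tissue)
  x <- tpm$values[gene, keep]
  n <- length(x)
  c(zero = sum(x == 0) / n,
    under10 = sum(x > 0 & x < 10) / n,
    mid = sum(x >= 10 & x <= 100) / n,
    over100 = sum(x > 100) / n)
}
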