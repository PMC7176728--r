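#' Construct a cell matrix
#'
#' Genes-by-cells container with a cell-type label per cell and a dataset
#' label.
#'
#' @param values Numeric matrix (genes x cells) of counts or TPM, with
#'   dimnames.
#' @param cell_type Character vector, one label per cell.
#' @param dataset_id Single dataset label (default `"dataset1"`).
#' @param value_kind `"counts"` or `"tpm"`.
#' @return A `cell_matrix`.
#' @export
cell_matrix <- function(values, cell_type, dataset_id = "dataset1",
                        value_kind = c("counts", "tpm")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must be a matrix with gene rownames and cell colnames")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(cell_type) != ncol(values))
    stop("cell_type must have one label per cell")
  if (any(is.na(cell_type) | !nzchar(cell_type)))
    stop("every cell needs a non-empty cell_type label")
  structure(list(values = values, cell_type = as.character(cell_type),
                 dataset_id = dataset_id, value_kind = value_kind),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix [%s, %s]: %d genes x %d cells (%d cell types)\n",
              x$dataset_id, x$value_kind, nrow(x$values), ncol(x$values),
              length(unique(x$cell_type))))
  invisible(x)
}

#' Transcripts per 10,000 (TP10K)
#'
#' From TPM, `TP10K = TPM / 100` (a per-ten-thousand denominator); from raw
#' counts, `TP10K = 1e4 * count / cell total`. The per-10,000 scale puts
#' shallow single-cell libraries on comparable footing across studies.
#'
#' @param x A `cell_matrix`, or a numeric matrix/vector of TPM values.
#' @return Same shape as the input, on the TP10K scale (a `cell_matrix` in,
#'   a `cell_matrix` out, tagged `"tpm"`).
#' @export
tp10k <- function(x) {
  if (inherits(x, "cell_matrix")) {
    v <- x$values
    if (x$value_kind == "tpm") {
      v <- v / 100
    } else {
      totals <- colSums(v)
      if (any(totals == 0))
        stop("zero-total cell(s): ",
             paste(colnames(v)[totals == 0], collapse = ", "))
      v <- sweep(v, 2, totals, "/") * 1e4
    }
    out <- x
    out$values <- v
    out$value_kind <- "tpm"
    attr(out, "scale") <- "tp10k"
    return(out)
  }
  if (any(x < 0)) stop("TPM values must be non-negative")
  x / 100
}

#' Log-transformed TP10K
#'
#' `E = log2(TP10K + 1)`; the added 1 limits the influence of zeros.
#'
#' @param x TP10K values (matrix or vector).
#' @return `log2(x + 1)`.
#' @export
log_tp10k <- function(x) {
  if (any(x < 0)) stop("TP10K values must be non-negative")
  log2(x + 1)
}

#' Exclude doublet-like cells on a marker gene
#'
#' Recipient cells whose marker TP10K exceeds the threshold are treated as
#' probable doublets/multiplets (a hybrid of recipient and source profiles)
#' and removed before averaging.
#'
#' @param tp10k_matrix Numeric TP10K matrix (genes x cells) or a TP10K
#'   `cell_matrix`.
#' @param gene Marker gene id.
#' @param cells Cell ids to screen.
#' @param threshold_tp10k Exclusion threshold (strict `>`, default 1000).
#' @return List with `kept` and `excluded` cell id vectors.
#' @export
exclude_doublet_like <- function(tp10k_matrix, gene, cells,
                                 threshold_tp10k = 1000) {
  v <- if (inherits(tp10k_matrix, "cell_matrix")) tp10k_matrix$values else tp10k_matrix
  if (!gene %in% rownames(v)) stop("gene not in matrix: ", gene)
  missing <- setdiff(cells, colnames(v))
  if (length(missing)) stop("cells not in matrix: ", paste(missing, collapse = ", "))
  x <- v[gene, cells]
  list(kept = cells[x <= threshold_tp10k], excluded = cells[x > threshold_tp10k])
}

#' Percent contamination of a recipient cell type by a marker gene
#'
#' `100 * mean(marker TP10K over kept recipient cells) / mean(marker TP10K
#' over source cells)`. Doublet-like recipient cells (above the TP10K
#' threshold) are excluded from the numerator; source cells enter the
#' denominator as-is. Cells, not reads, are the unit of averaging.
#'
#' @param cm A `cell_matrix` (counts or TPM).
#' @param gene Marker gene id.
#' @param source_type Cell type natively expressing the gene.
#' @param recipient_type Cell type being assessed.
#' @param threshold_tp10k Doublet exclusion threshold (default 1000).
#' @return A `contamination_estimate`: list with `gene`, `source_type`,
#'   `recipient_type`, `dataset`, `n_recipient_used`, `n_excluded`,
#'   `mean_recipient_tp10k`, `mean_source_tp10k`, `percent_contamination`,
#'   `excluded_cells`.
#' @export
percent_contamination <- function(cm, gene, source_type, recipient_type,
                                  threshold_tp10k = 1000) {
  stopifnot(inherits(cm, "cell_matrix"))
  tk <- tp10k(cm)
  for (ct in c(source_type, recipient_type))
    if (!ct %in% tk$cell_type) stop("cell type absent: ", ct)
  src_cells <- colnames(tk$values)[tk$cell_type == source_type]
  rec_cells <- colnames(tk$values)[tk$cell_type == recipient_type]
  split <- exclude_doublet_like(tk, gene, rec_cells, threshold_tp10k)
  mean_src <- mean(tk$values[gene, src_cells])
  if (mean_src == 0) stop("source cells do not express ", gene)
  mean_rec <- if (length(split$kept)) mean(tk$values[gene, split$kept]) else 0
  structure(list(gene = gene, source_type = source_type,
                 recipient_type = recipient_type, dataset = cm$dataset_id,
                 n_recipient_used = length(split$kept),
                 n_excluded = length(split$excluded),
                 mean_recipient_tp10k = mean_rec,
                 mean_source_tp10k = mean_src,
                 percent_contamination = 100 * mean_rec / mean_src,
                 excluded_cells = split$excluded),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "contamination_estimate [%s]: %s in %s = %.3f%% of %s (n = %d, %d excluded)\n",
    x$dataset, x$gene, x$recipient_type, x$percent_contamination,
    x$source_type, x$n_recipient_used, x$n_excluded))
  invisible(x)
}

#' Presence/absence contrast of a marker across datasets
#'
#' For each dataset, the fraction of recipient cells with any marker signal
#' and their mean TP10K; contamination by a highly expressed gene should
#' appear only in datasets where the source cell type was co-processed.
#'
#' @param datasets List of `cell_matrix` objects, each containing the
#'   recipient cell type.
#' @param gene Marker gene id.
#' @param recipient_type Recipient cell type label.
#' @param source_present Logical vector, one entry per dataset.
#' @return Data frame with `dataset`, `source_present`, `n_cells`,
#'   `positive_fraction`, `mean_tp10k`; attribute `contrast` holds the mean
#'   positive fraction in source-present vs source-absent datasets (`NA`
#'   when a side is empty).
#' @export
cross_dataset_contrast <- function(datasets, gene, recipient_type,
                                   source_present) {
  if (length(datasets) != length(source_present))
    stop("source_present must have one entry per dataset")
  rows <- lapply(seq_along(datasets), function(i) {
    tk <- tp10k(datasets[[i]])
    cells <- colnames(tk$values)[tk$cell_type == recipient_type]
    if (!length(cells))
      stop("dataset ", tk$dataset_id, " lacks recipient type ", recipient_type)
    x <- if (gene %in% rownames(tk$values)) tk$values[gene, cells] else rep(0, length(cells))
    data.frame(dataset = tk$dataset_id, source_present = source_present[i],
               n_cells = length(cells), positive_fraction = mean(x > 0),
               mean_tp10k = mean(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  contrast <- c(
    present = if (any(out$source_present)) mean(out$positive_fraction[out$source_present]) else NA_real_,
    absent = if (any(!out$source_present)) mean(out$positive_fraction[!out$source_present]) else NA_real_)
  attr(out, "contrast") <- contrast
  out
}
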