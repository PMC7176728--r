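#' Construct an expression matrix
#'
#' A light container for a dense genes-by-samples matrix tagged with the kind
#' of values it holds. All downstream operations check the tag so that, e.g.,
#' size factors are never estimated from TPM.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   rownames (gene ids) and colnames (sample ids).
#' @param value_kind One of `"counts"`, `"tpm"`, `"transformed"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `value_kind`.
#' @export
expression_matrix <- function(values, value_kind = c("counts", "tpm", "transformed")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  structure(list(values = values, value_kind = value_kind), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from GCT, TSV or MatrixMarket files
#'
#' Supported encodings:
#' * `tsv`: tab-delimited, header row of sample ids, first column gene ids.
#' * `gct`: GCT version 1.2 (a `#1.2` line, a dimensions line, then a table
#'   with `Name` and `Description` columns). The Description column is read
#'   and discarded.
#' * `mtx`: MatrixMarket triplet file accompanied by `<stem>.genes.txt` and
#'   `<stem>.samples.txt` label files (one id per line).
#'
#' @param path Path to the matrix file.
#' @param format One of `"auto"`, `"gct"`, `"tsv"`, `"mtx"`; `"auto"` picks
#'   by file extension.
#' @param value_kind Tag to attach; see [expression_matrix()].
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv", "mtx"),
                            value_kind = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gct = "gct", mtx = "mtx", "tsv")
  }
  values <- switch(format,
    tsv = .read_expr_tsv(path),
    gct = .read_expr_gct(path),
    mtx = .read_expr_mtx(path)
  )
  expression_matrix(values, value_kind = value_kind)
}

.read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("format error in ", path, ": need a gene id column plus >=1 sample column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("format error in ", path, ": non-numeric expression values")
  rownames(m) <- genes
  m
}

.read_expr_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2 || trimws(lines[1]) != "#1.2")
    stop("format error in ", path, " line 1: expected GCT version line '#1.2'")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\t")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2]))
    stop("format error in ", path, " line 2: expected '<ngenes>\\t<nsamples>'")
  df <- utils::read.delim(path, skip = 2, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(tolower(names(df)[1:2]), c("name", "description")))
    stop("format error in ", path, " line 3: expected 'Name' and 'Description' columns")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != dims[1] || ncol(m) != dims[2])
    stop(sprintf("consistency error in %s: header states %d x %d but table is %d x %d",
                 path, dims[1], dims[2], nrow(m), ncol(m)))
  m
}

.read_expr_mtx <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  gene_file <- paste0(stem, ".genes.txt")
  sample_file <- paste0(stem, ".samples.txt")
  for (f in c(gene_file, sample_file))
    if (!file.exists(f)) stop("missing MTX label file: ", f)
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(gene_file)
  samples <- readLines(sample_file)
  if (nrow(m) != length(genes) || ncol(m) != length(samples))
    stop(sprintf("consistency error: %s is %d x %d but label files give %d genes, %d samples",
                 path, nrow(m), ncol(m), length(genes), length(samples)))
  dimnames(m) <- list(genes, samples)
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; used for fixtures and stage outputs.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param format `"tsv"`, `"gct"` or `"mtx"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = "na", m, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paste0(stem, ".mtx"))
    writeLines(rownames(m), paste0(stem, ".genes.txt"))
    writeLines(colnames(m), paste0(stem, ".samples.txt"))
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a tab-delimited table with columns `sample_id`, `subject_id`,
#' `tissue`, `isolation_date`, `sequencing_date`. Dates must be ISO-8601
#' calendar dates (`YYYY-MM-DD`); batch membership downstream means exact
#' date equality, so no other representation is accepted. Empty date fields
#' are recorded as missing, never imputed.
#'
#' @param path Path to the TSV file.
#' @return A `sample_metadata` data frame with `Date` columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  sample_metadata(df)
}

#' Construct/validate sample metadata
#'
#' @param df A data frame with the columns listed in [read_metadata()].
#' @return A validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "subject_id", "tissue", "isolation_date", "sequencing_date")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!nzchar(trimws(df$tissue))))
    stop("empty tissue label in row(s): ",
         paste(which(!nzchar(trimws(df$tissue))), collapse = ", "))
  for (col in c("isolation_date", "sequencing_date"))
    df[[col]] <- .parse_iso_dates(df[[col]], col)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

.parse_iso_dates <- function(x, col) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[is.na(x) | !nzchar(trimws(x))] <- NA_character_
  ok <- is.na(x) | grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (!all(ok))
    stop(sprintf("value error in %s row %d: '%s' is not an ISO-8601 date (YYYY-MM-DD)",
                 col, which(!ok)[1], x[which(!ok)[1]]))
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(d)
  if (any(bad))
    stop(sprintf("value error in %s row %d: '%s' is not a valid calendar date",
                 col, which(bad)[1], x[which(bad)[1]]))
  d
}

#' Join an expression matrix with sample metadata
#'
#' Restricts both sides to their common samples (order taken from the
#' expression matrix) and reports what was dropped from each side.
#'
#' @param expr An `expr_matrix`.
#' @param meta A `sample_metadata` data frame.
#' @return An `expr_study`: list with `expr`, `meta`, `dropped_expr`
#'   (sample ids present only in the matrix) and `dropped_meta`.
#' @export
align_study <- function(expr, meta) {
  stopifnot(inherits(expr, "expr_matrix"))
  meta <- if (inherits(meta, "sample_metadata")) meta else sample_metadata(meta)
  common <- intersect(sample_ids(expr), meta$sample_id)
  if (!length(common))
    stop("no samples shared between expression matrix and metadata")
  dropped_expr <- setdiff(sample_ids(expr), common)
  dropped_meta <- setdiff(meta$sample_id, common)
  expr2 <- expression_matrix(expr$values[, common, drop = FALSE], expr$value_kind)
  meta2 <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  structure(list(expr = expr2, meta = meta2,
                 dropped_expr = dropped_expr, dropped_meta = dropped_meta),
            class = "expr_study")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("expr_study: %d genes x %d samples, %d tissue(s)\n",
              nrow(x$expr$values), ncol(x$expr$values),
              length(unique(x$meta$tissue))))
  if (length(x$dropped_expr) || length(x$dropped_meta))
    cat(sprintf("  dropped: %d expression-only, %d metadata-only sample(s)\n",
                length(x$dropped_expr), length(x$dropped_meta)))
  invisible(x)
}

#' Read per-sample genotypes from a VCF file
#'
#' Parses an uncompressed VCF v4.x text file, keeping CHROM, POS, ID, REF,
#' ALT and the per-sample GT field. Genotypes are reported as allele-pair
#' strings on the `REF`/`ALT` alphabet (e.g. `"C/G"`); `.` alleles become
#' `NA`. Only the first ALT allele is used (bi-allelic interpretation).
#'
#' @param path Path to a plain-text VCF.
#' @return A data frame with one row per site: `chrom`, `pos`, `site_id`,
#'   `ref`, `alt`, then one column per sample holding genotype strings.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("format error in ", path, ": no #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (!length(samples)) stop("format error in ", path, ": VCF has no sample columns")
  body <- lines[-seq_len(hdr[1])]
  body <- body[!grepl("^#", body)]
  if (!length(body)) stop("format error in ", path, ": VCF has no records")
  recs <- strsplit(body, "\t")
  parse_rec <- function(f) {
    gt_index <- match("GT", strsplit(f[9], ":")[[1]])
    if (is.na(gt_index)) stop("format error: record without GT in FORMAT")
    alleles <- c(f[4], strsplit(f[5], ",")[[1]][1])
    gts <- vapply(f[-(1:9)], function(s) {
      gt <- strsplit(s, ":")[[1]][gt_index]
      parts <- strsplit(gt, "[/|]")[[1]]
      if (length(parts) != 2 || any(parts == "."))
        return(NA_character_)
      paste(alleles[as.integer(parts) + 1L], collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    c(f[1], f[2], f[3], f[4], strsplit(f[5], ",")[[1]][1], gts)
  }
  tab <- t(vapply(recs, parse_rec, character(5 + length(samples))))
  out <- data.frame(chrom = tab[, 1], pos = as.integer(tab[, 2]),
                    site_id = tab[, 3], ref = tab[, 4], alt = tab[, 5],
                    stringsAsFactors = FALSE)
  gt <- as.data.frame(tab[, -(1:5), drop = FALSE], stringsAsFactors = FALSE)
  names(gt) <- samples
  cbind(out, gt)
}

#' Read a bam-readcount-style allele count table
#'
#' Tab-delimited with columns `chrom`, `pos`, `ref`, `depth`, then one field
#' per observed base formatted `base:count` (e.g. `A:10`). An optional leading
#' `sample_id` (and `tissue`) column is supported, matching what
#' [write_allele_counts()] emits.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `sample_id`, `tissue` (possibly `NA`),
#'   `chrom`, `pos`, `ref`, `depth`, and `count_A`, `count_C`, `count_G`,
#'   `count_T`.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "depth")
  if (!all(required %in% names(df)))
    stop("schema error: allele count table needs columns ", paste(required, collapse = ", "))
  base_cols <- setdiff(names(df), c("sample_id", "tissue", required))
  counts <- matrix(0L, nrow(df), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (col in base_cols) {
    vals <- strsplit(as.character(df[[col]]), ":")
    for (i in seq_along(vals)) {
      v <- vals[[i]]
      if (length(v) == 2 && v[1] %in% colnames(counts))
        counts[i, v[1]] <- counts[i, v[1]] + as.integer(v[2])
    }
  }
  if (any(rowSums(counts) != df$depth))
    stop("consistency error: depth does not equal the sum of per-base counts")
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(df)) df$sample_id else NA_character_,
    tissue = if ("tissue" %in% names(df)) df$tissue else NA_character_,
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref,
    depth = as.integer(df$depth), stringsAsFactors = FALSE)
  colnames(counts) <- paste0("count_", colnames(counts))
  cbind(out, counts)
}

#' Write a bam-readcount-style allele count table
#'
#' @param df A data frame as returned by [read_allele_counts()].
#' @param path Output path.
#' @export
write_allele_counts <- function(df, path) {
  bases <- c("A", "C", "G", "T")
  out <- data.frame(sample_id = df$sample_id, tissue = df$tissue,
                    chrom = df$chrom, pos = df$pos, ref = df$ref,
                    depth = df$depth, stringsAsFactors = FALSE)
  for (b in bases)
    out[[b]] <- paste0(b, ":", df[[paste0("count_", b)]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
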