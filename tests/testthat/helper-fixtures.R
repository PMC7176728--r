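# Shared fixture builders; everything is generated in code.

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, value_kind = "counts")
}

make_tm <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  structure(list(values = m, size_factors = rep(1, ncol(m))),
            class = "transformed_matrix")
}

make_meta <- function(n, tissue = "lung", subject = NULL,
                      iso = "2013-01-05", seq = "2013-01-09") {
  ids <- sprintf("%s_S%02d", tissue[1], seq_len(n))
  sample_metadata(data.frame(
    sample_id = ids,
    subject_id = if (is.null(subject)) paste0("P", seq_len(n)) else subject,
    tissue = rep(tissue, length.out = n),
    isolation_date = rep(iso, length.out = n),
    sequencing_date = rep(seq, length.out = n),
    stringsAsFactors = FALSE))
}

# Planted-block matrix: `block` genes with pairwise Kendall tau ~ tau_target
# (Gaussian copula: rho = sin(tau * pi / 2)), plus independent noise genes.
make_block_tm <- function(n_samples = 200, block = 4, noise = 50,
                          tau_target = 0.8, seed = 1) {
  set.seed(seed)
  rho <- sin(tau_target * pi / 2)
  z <- rnorm(n_samples)
  bl <- t(sapply(seq_len(block), function(i)
    sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)))
  ns <- matrix(rnorm(noise * n_samples), noise, n_samples)
  genes <- c(sprintf("BLK%d", seq_len(block)), sprintf("NSE%02d", seq_len(noise)))
  make_tm(rbind(bl, ns), genes = genes)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
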