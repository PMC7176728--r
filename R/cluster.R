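#' Pairwise Kendall tau-b matrix
#'
#' Tie-corrected Kendall rank correlation between every pair of genes across
#' samples. Transformed counts contain ties, so the tau-b variant is used.
#'
#' @param tm A `transformed_matrix`.
#' @param genes Gene ids to correlate (default: all genes in `tm`).
#' @return A `tau_matrix`: list with `tau` (symmetric matrix, unit diagonal)
#'   and `n_samples`.
#' @export
kendall_matrix <- function(tm, genes = NULL) {
  stopifnot(inherits(tm, "transformed_matrix"))
  if (is.null(genes)) genes <- rownames(tm$values)
  missing <- setdiff(genes, rownames(tm$values))
  if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
  if (length(genes) < 2) stop("need at least 2 genes")
  x <- t(tm$values[genes, , drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 samples")
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("tau undefined for constant gene(s): ", paste(genes[const], collapse = ", "))
  tau <- stats::cor(x, method = "kendall")
  diag(tau) <- 1
  tau <- (tau + t(tau)) / 2
  structure(list(tau = tau, n_samples = nrow(x)), class = "tau_matrix")
}

#' Critical tau threshold for cluster acceptance
#'
#' Minimum mean within-cluster correlation required of a reported gene
#' cluster. Built from the large-sample null distribution of Kendall's tau,
#' `sd0 = sqrt(2(2n+5) / (9 n (n-1)))`, with a Bonferroni correction over
#' the `m = g(g-1)/2` gene pairs under consideration:
#' `tau_crit = z_{1 - alpha/(2m)} * sd0`, capped at 0.99. The threshold
#' tightens with more genes and loosens with more samples.
#'
#' @param n_samples Number of samples (>= 3).
#' @param n_genes Number of genes under consideration (>= 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Threshold in (0, 0.99].
#' @export
tau_critical <- function(n_samples, n_genes = 2, alpha = 0.05) {
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (n_genes < 2) stop("n_genes must be >= 2")
  m <- n_genes * (n_genes - 1) / 2
  sd0 <- sqrt(2 * (2 * n_samples + 5) / (9 * n_samples * (n_samples - 1)))
  crit <- stats::qnorm(1 - alpha / (2 * m)) * sd0
  min(crit, 0.99)
}

.mean_pairwise_tau <- function(tau, members) {
  sub <- tau[members, members, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Detect co-varying gene clusters
#'
#' Average-linkage hierarchical clustering on distance `1 - tau`. The
#' dendrogram is cut at the coarsest level (fewest clusters) at which every
#' cluster of at least `min_size` genes has mean pairwise tau at or above
#' `tau_crit`; genes not in a qualifying cluster are returned as singletons.
#'
#' @param tau A `tau_matrix` from [kendall_matrix()].
#' @param tau_crit Threshold from [tau_critical()].
#' @param min_size Minimum cluster size (default 2).
#' @return List with `clusters` (each a `gene_cluster`: list of `genes`,
#'   `mean_tau`, `label`) and `singletons` (character vector).
#' @export
detect_clusters <- function(tau, tau_crit, min_size = 2) {
  stopifnot(inherits(tau, "tau_matrix"))
  tm <- tau$tau
  genes <- rownames(tm)
  d <- stats::as.dist(1 - tm)
  hc <- stats::hclust(d, method = "average")
  chosen <- NULL
  for (k in seq_len(length(genes))) {
    groups <- stats::cutree(hc, k = k)
    ok <- TRUE
    for (g in unique(groups)) {
      members <- genes[groups == g]
      if (length(members) >= min_size &&
          .mean_pairwise_tau(tm, members) < tau_crit) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      chosen <- groups
      break
    }
  }
  if (is.null(chosen)) chosen <- seq_along(genes)  # all singletons
  clusters <- list()
  singletons <- character(0)
  for (g in unique(chosen)) {
    members <- genes[chosen == g]
    if (length(members) >= min_size) {
      clusters[[length(clusters) + 1L]] <- structure(
        list(genes = members,
             mean_tau = .mean_pairwise_tau(tm, members),
             label = "unlabeled", evidence = NULL),
        class = "gene_cluster")
    } else {
      singletons <- c(singletons, members)
    }
  }
  list(clusters = clusters, singletons = singletons)
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("gene_cluster [%s]: %d genes, mean tau %.3f\n",
              x$label, length(x$genes), x$mean_tau))
  invisible(x)
}

#' Label clusters by marker-set overlap
#'
#' A cluster is labeled `contamination` when at least half of its members
#' belong to a single foreign tissue's marker set; `sex` when all members are
#' in the supplied sex-gene set; otherwise `unlabeled`.
#'
#' @param clusters List of `gene_cluster` objects from [detect_clusters()].
#' @param marker_sets Named list mapping tissue to a character vector of
#'   marker genes (e.g. tissue-enriched gene lists, or simulated truth).
#' @param own_tissue Tissue the clustered samples come from; its own marker
#'   set never triggers a contamination label.
#' @param sex_genes Optional character vector (e.g. Y genes plus XIST).
#' @return The clusters with `label` and `evidence` filled in.
#' @export
label_contamination_clusters <- function(clusters, marker_sets, own_tissue,
                                         sex_genes = character(0)) {
  lapply(clusters, function(cl) {
    n <- length(cl$genes)
    if (length(sex_genes) && all(cl$genes %in% sex_genes)) {
      cl$label <- "sex"
      cl$evidence <- list(set = "sex", overlap = n)
      return(cl)
    }
    foreign <- marker_sets[setdiff(names(marker_sets), own_tissue)]
    if (length(foreign)) {
      overlap <- vapply(foreign, function(s) sum(cl$genes %in% s), numeric(1))
      best <- which.max(overlap)
      if (overlap[best] >= n / 2) {
        cl$label <- "contamination"
        cl$evidence <- list(set = names(foreign)[best], overlap = overlap[[best]])
        return(cl)
      }
    }
    cl$label <- "unlabeled"
    cl
  })
}

#' Export clusters as a tidy table
#'
#' @param clusters List of `gene_cluster` objects.
#' @return Data frame with columns `cluster`, `gene`, `mean_tau`, `label`.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), gene = character(0),
                      mean_tau = numeric(0), label = character(0)))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, gene = cl$genes, mean_tau = cl$mean_tau,
               label = cl$label, stringsAsFactors = FALSE)
  }))
}
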