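#' Configuration for the synthetic bulk study generator
#'
#' Defines a multi-tissue negative-binomial expression study with
#' tissue-enriched marker genes and batch-dependent contamination. Defaults
#' describe a pancreas-like source tissue whose four acinar markers carry
#' native TPM magnitudes in the tens of thousands (PRSS1 at 99,100 TPM being
#' the extreme), four unrelated recipient tissues, and contamination
#' fractions that are largest on shared sequencing days and decay
#' exponentially with distance in days from the nearest source day.
#'
#' @param tissues Character vector of tissue names (first is arbitrary;
#'   `source_tissue` marks the contaminating one).
#' @param source_tissue Tissue natively expressing the marker panel.
#' @param samples_per_tissue Samples per tissue; one subject contributes one
#'   sample to every tissue.
#' @param n_background_genes Number of ubiquitous background genes.
#' @param marker_sets Named list: tissue -> named numeric vector of marker
#'   genes with native mean TPM in that tissue.
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of per-sample library sizes (reads).
#' @param nb_dispersion Negative-binomial dispersion for native counts
#'   (`size = 1/dispersion`).
#' @param n_sequencing_days Number of calendar sequencing days; roughly one
#'   third host source-tissue runs.
#' @param p_coseq Probability that a non-source sample shares a sequencing
#'   day with a source sample.
#' @param f_same Mean contamination fraction on shared sequencing days.
#' @param f_other Mean contamination fraction on non-shared days at zero day
#'   distance, before decay.
#' @param decay_half_life_days Half-life (days) of the off-day mean
#'   fraction: mean is `f_other * 2^(-delta/half_life)`.
#' @param f_iso_multiplier Multiplier on the latent mean fraction when the
#'   sample also shares an isolation day with the source tissue.
#' @param subject_sd SD of the per-subject random effect on the log latent
#'   contamination fraction.
#' @param beta_seq,beta_iso Target same-day effects on the score scale, used
#'   by [simulate_mixed_scores()].
#' @param seed Integer seed fixing all randomness.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    tissues = c("pancreas", "lung", "adipose", "artery", "nerve"),
    source_tissue = "pancreas",
    samples_per_tissue = 40,
    n_background_genes = 300,
    marker_sets = list(pancreas = c(PRSS1 = 99100, PNLIP = 33660,
                                    CELA3A = 27130, CLPS = 51640)),
    library_size_mean = 1e6,
    library_size_cv = 0.1,
    nb_dispersion = 0.1,
    n_sequencing_days = 30,
    p_coseq = 0.5,
    f_same = 5e-3,
    f_other = 5e-4,
    decay_half_life_days = 2,
    f_iso_multiplier = 1.5,
    subject_sd = 0.5,
    beta_seq = 0.863,
    beta_iso = 0.175,
    seed = 1) {
  cfg <- as.list(environment())
  if (!source_tissue %in% tissues) stop("source_tissue must be one of tissues")
  if (!source_tissue %in% names(marker_sets))
    stop("marker_sets must include the source tissue")
  if (!(f_other >= 0 && f_other <= f_same && f_same <= 1))
    stop("need 0 <= f_other <= f_same <= 1")
  if (samples_per_tissue < 1 || n_background_genes < 1 ||
      library_size_mean <= 0 || nb_dispersion <= 0 ||
      n_sequencing_days < 2 || decay_half_life_days <= 0)
    stop("counts, means, dispersions and half-life must be positive")
  if (p_coseq < 0 || p_coseq > 1) stop("p_coseq must be in [0, 1]")
  bg_ids <- sprintf("BG%04d", seq_len(n_background_genes))
  marker_ids <- unlist(lapply(marker_sets, names), use.names = FALSE)
  if (anyDuplicated(marker_ids)) stop("marker genes must be unique across tissues")
  if (length(intersect(marker_ids, bg_ids)))
    stop("marker genes overlap background gene ids: ",
         paste(intersect(marker_ids, bg_ids), collapse = ", "))
  cfg$background_genes <- bg_ids
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-tissue bulk study with planted contamination
#'
#' Native expression is negative-binomial around tissue-specific TPM
#' proportions: marker genes at their configured TPM in their own tissue and
#' exactly zero elsewhere; background genes shared by all tissues.
#' Contaminant reads are *added* to native counts (foreign template on top
#' of a recipient in which the markers are natively absent): a contaminated
#' sample gains `Binomial(library_size, f_i * p_g)` reads for each source
#' marker gene `g` with native TPM proportion `p_g`. The sample fraction
#' `f_i` is exponential with mean `f_same` on shared sequencing days and
#' `f_other * 2^(-delta_days / half_life)` otherwise, scaled by
#' `f_iso_multiplier` on shared isolation days and by a per-subject
#' log-normal random effect. Source-tissue samples are never contaminated.
#'
#' @param config A `simulation_config`.
#' @return List with `study` (an `expr_study` of counts plus metadata),
#'   `truth` (per-sample data frame: `f_true`, `donor_sample`, `coseq`,
#'   `delta_days`, ...), and `gene_lengths` (named vector; all equal so TPM
#'   is proportional to counts).
#' @export
simulate_bulk_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tissues <- config$tissues
  src <- config$source_tissue
  n_sub <- config$samples_per_tissue
  subjects <- sprintf("SUBJ%03d", seq_len(n_sub))

  # calendar: sequencing days, roughly a third of which host source runs;
  # isolation happens on its own grid 30 days earlier
  day0 <- as.Date("2013-01-01")
  seq_days <- day0 + seq_len(config$n_sequencing_days) - 1
  n_src_days <- max(2L, round(config$n_sequencing_days / 3))
  src_seq_days <- sort(sample(seq_days, n_src_days))
  off_seq_days <- setdiff(seq_days, src_seq_days)
  iso_days <- seq_days - 30
  src_iso_days <- sort(sample(iso_days, n_src_days))
  off_iso_days <- setdiff(iso_days, src_iso_days)

  meta_rows <- list()
  for (tis in tissues) {
    for (s in subjects) {
      if (tis == src) {
        sd_ <- sample(src_seq_days, 1)
        id_ <- sample(src_iso_days, 1)
      } else {
        sd_ <- if (stats::runif(1) < config$p_coseq)
          sample(src_seq_days, 1) else sample(off_seq_days, 1)
        id_ <- if (stats::runif(1) < config$p_coseq)
          sample(src_iso_days, 1) else sample(off_iso_days, 1)
      }
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = paste(s, tis, sep = "-"), subject_id = s, tissue = tis,
        isolation_date = as.Date(id_, origin = "1970-01-01"),
        sequencing_date = as.Date(sd_, origin = "1970-01-01"),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)

  # gene catalogue: background shared everywhere, markers tissue-exclusive
  bg <- config$background_genes
  marker_tpm <- config$marker_sets
  all_markers <- unlist(lapply(marker_tpm, names), use.names = FALSE)
  genes <- c(all_markers, bg)
  bg_w <- stats::rlnorm(length(bg), 0, 1.5)
  bg_w <- bg_w / sum(bg_w)

  # per-tissue expected TPM proportions
  props <- sapply(tissues, function(tis) {
    p <- stats::setNames(numeric(length(genes)), genes)
    own <- marker_tpm[[tis]]
    share <- 0
    if (!is.null(own)) {
      p[names(own)] <- own / 1e6
      share <- sum(own) / 1e6
    }
    p[bg] <- bg_w * (1 - share)
    p
  })

  src_p <- props[, src]
  src_markers <- names(marker_tpm[[src]])
  u_subj <- stats::setNames(stats::rnorm(n_sub, 0, config$subject_sd), subjects)

  lib_meanlog <- log(config$library_size_mean) - log(1 + config$library_size_cv^2) / 2
  lib_sdlog <- sqrt(log(1 + config$library_size_cv^2))

  n_samp <- nrow(meta)
  counts <- matrix(0L, length(genes), n_samp,
                   dimnames = list(genes, meta$sample_id))
  truth <- data.frame(sample_id = meta$sample_id, subject_id = meta$subject_id,
                      tissue = meta$tissue, f_true = 0,
                      donor_sample = NA_character_, coseq = NA,
                      delta_days = NA_real_, stringsAsFactors = FALSE)

  src_samples <- meta[meta$tissue == src, , drop = FALSE]

  for (i in seq_len(n_samp)) {
    tis <- meta$tissue[i]
    L <- round(stats::rlnorm(1, lib_meanlog, lib_sdlog))
    mu <- props[, tis] * L
    nz <- mu > 0
    native <- numeric(length(genes))
    native[nz] <- stats::rnbinom(sum(nz), mu = mu[nz], size = 1 / config$nb_dispersion)
    counts[, i] <- native
    if (tis == src) next

    co <- meta$sequencing_date[i] %in% src_seq_days
    delta <- min(abs(as.numeric(meta$sequencing_date[i] - src_seq_days)))
    iso_co <- meta$isolation_date[i] %in% src_iso_days
    base_mean <- if (co) config$f_same else
      config$f_other * 2^(-delta / config$decay_half_life_days)
    m_i <- base_mean * (if (iso_co) config$f_iso_multiplier else 1) *
      exp(u_subj[meta$subject_id[i]])
    f_i <- if (m_i > 0) stats::rexp(1, rate = 1 / m_i) else 0
    f_i <- min(f_i, 1)
    truth$coseq[i] <- co
    truth$delta_days[i] <- delta
    truth$f_true[i] <- f_i
    if (f_i > 0) {
      added <- stats::rbinom(length(src_markers), size = L,
                             prob = pmin(1, f_i * src_p[src_markers]))
      counts[src_markers, i] <- counts[src_markers, i] + added
      pool <- src_samples$sample_id[src_samples$sequencing_date ==
                                      .nearest_day(meta$sequencing_date[i],
                                                   src_seq_days)]
      truth$donor_sample[i] <- if (length(pool)) sample(pool, 1) else NA_character_
    }
  }

  expr <- expression_matrix(counts, value_kind = "counts")
  study <- align_study(expr, sample_metadata(meta))
  attr(truth, "marker_sets") <- lapply(marker_tpm, names)
  attr(truth, "config") <- config
  list(study = study, truth = truth,
       gene_lengths = stats::setNames(rep(1000, length(genes)), genes))
}

.nearest_day <- function(d, pool) pool[which.min(abs(as.numeric(d - pool)))]

#' Simulate panel scores directly from the batch linear mixed model
#'
#' Generates scores from the additive model `Y = beta0 + beta_seq * seq_flag
#' + beta_iso * iso_flag + tissue effect + subject intercept + noise`, with
#' one subject contributing one sample per tissue; used for parameter
#' recovery studies of [fit_mixed_model()].
#'
#' @param n_tissues,samples_per_tissue Study shape (subjects =
#'   `samples_per_tissue`, crossed with tissues).
#' @param beta_seq,beta_iso True same-day effects.
#' @param sd_subject,sd_residual Random-intercept and residual SDs.
#' @param p_seq_same,p_iso_same Marginal probabilities of the flags.
#' @param beta0 Intercept.
#' @param tissue_effect_sd SD of the (fixed) non-reference tissue effects.
#' @param seed Integer seed.
#' @return List with `scores`, `flags`, `meta` (ready for
#'   [fit_mixed_model()]) and `truth` (the generating parameters, including
#'   the drawn tissue effects).
#' @export
simulate_mixed_scores <- function(n_tissues = 15, samples_per_tissue = 400,
                                  beta_seq = 0.863, beta_iso = 0.175,
                                  sd_subject = 0.3, sd_residual = 0.5,
                                  p_seq_same = 0.4, p_iso_same = 0.4,
                                  beta0 = 0, tissue_effect_sd = 0.5,
                                  seed = 1) {
  set.seed(seed)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  subjects <- sprintf("SUBJ%04d", seq_len(samples_per_tissue))
  tissue_eff <- stats::setNames(c(0, stats::rnorm(n_tissues - 1, 0, tissue_effect_sd)),
                                tissues)
  u <- stats::setNames(stats::rnorm(length(subjects), 0, sd_subject), subjects)
  grid <- expand.grid(subject_id = subjects, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$subject_id, grid$tissue, sep = "-")
  seq_flag <- stats::runif(nrow(grid)) < p_seq_same
  iso_flag <- stats::runif(nrow(grid)) < p_iso_same
  y <- beta0 + beta_seq * seq_flag + beta_iso * iso_flag +
    tissue_eff[grid$tissue] + u[grid$subject_id] +
    stats::rnorm(nrow(grid), 0, sd_residual)
  scores <- data.frame(sample_id = grid$sample_id, tissue = grid$tissue,
                       panel = "synthetic", score = as.numeric(y),
                       stringsAsFactors = FALSE)
  flags <- data.frame(sample_id = grid$sample_id, tissue = grid$tissue,
                      seq_same_day = seq_flag, iso_same_day = iso_flag,
                      days_to_nearest_source_seq = ifelse(seq_flag, 0, NA),
                      stringsAsFactors = FALSE)
  class(flags) <- c("batch_flags", "data.frame")
  meta <- data.frame(sample_id = grid$sample_id, subject_id = grid$subject_id,
                     tissue = grid$tissue, stringsAsFactors = FALSE)
  list(scores = scores, flags = flags, meta = meta,
       truth = list(beta_seq = beta_seq, beta_iso = beta_iso,
                    sd_subject = sd_subject, sd_residual = sd_residual,
                    tissue_effects = tissue_eff))
}

#' Simulate DNA genotypes and RNA allele counts for a contaminated study
#'
#' Places `sites_per_gene` bi-allelic coding sites in each source marker
#' gene plus `control_sites` sites in the ubiquitous control genes, draws
#' Hardy-Weinberg genotypes per subject, and emits per-sample allele counts:
#' native-tissue RNA at high depth from the subject's own genotype, and
#' queried-tissue RNA as binomial draws from the mixture fraction
#' `lambda = contaminant marker reads / total marker reads` at the locus
#' (markers are natively absent in recipients, so marker-site reads in a
#' contaminated sample are effectively all foreign). Control-gene sites mix
#' nothing.
#'
#' @param study,truth Output of [simulate_bulk_study()].
#' @param config The `simulation_config` used.
#' @param sites_per_gene Sites per marker gene (default 3).
#' @param control_sites Total sites across the control genes (default 20).
#' @param native_depth RNA depth in the native tissue (default 5000).
#' @param depth_scale Queried-tissue site depth as a fraction of the gene's
#'   contaminant reads (default 0.3); control sites use Poisson depth around
#'   `control_depth`.
#' @param control_depth Mean depth at control sites (default 500).
#' @return List with `sites` (one row per sample x site: genotypes, native
#'   and queried counts, `true_lambda`, donor information) and `genotypes`
#'   (site x subject genotype table for donor matching).
#' @export
simulate_variant_readcounts <- function(study, truth, config,
                                        sites_per_gene = 3, control_sites = 20,
                                        native_depth = 5000, depth_scale = 0.3,
                                        control_depth = 500) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1000L)
  src <- config$source_tissue
  src_markers <- names(config$marker_sets[[src]])
  if (!length(src_markers) || sites_per_gene < 1)
    stop("site list empty: no marker sites to simulate")
  control_genes <- c("GAPDH", "RAB7A")
  bases <- c("A", "C", "G", "T")

  site_rows <- list()
  mk_sites <- function(genes, n_per) {
    for (g in genes) {
      for (k in seq_len(n_per)) {
        ref <- sample(bases, 1)
        alt <- sample(setdiff(bases, ref), 1)
        site_rows[[length(site_rows) + 1L]] <<- data.frame(
          site_id = sprintf("%s_site%d", g, k), gene = g,
          chrom = "chr1", pos = length(site_rows) * 1000L + 500L,
          ref = ref, alt = alt, maf = stats::runif(1, 0.1, 0.5),
          stringsAsFactors = FALSE)
      }
    }
  }
  mk_sites(src_markers, sites_per_gene)
  mk_sites(control_genes, max(1L, ceiling(control_sites / length(control_genes))))
  sites <- do.call(rbind, site_rows)

  subjects <- unique(truth$subject_id)
  geno <- matrix(NA_character_, nrow(sites), length(subjects),
                 dimnames = list(sites$site_id, subjects))
  for (i in seq_len(nrow(sites))) {
    q <- sites$maf[i]
    n_alt <- stats::rbinom(length(subjects), 2, q)
    geno[i, ] <- vapply(n_alt, function(k) {
      paste(c(rep(sites$ref[i], 2 - k), rep(sites$alt[i], k)), collapse = "/")
    }, character(1))
  }

  counts <- study$expr$values
  meta <- study$meta
  rows <- list()
  rec <- truth[truth$tissue != src, , drop = FALSE]
  for (i in seq_len(nrow(rec))) {
    samp <- rec$sample_id[i]
    subj <- rec$subject_id[i]
    donor_samp <- rec$donor_sample[i]
    donor_subj <- if (!is.na(donor_samp))
      meta$subject_id[meta$sample_id == donor_samp] else NA_character_
    for (j in seq_len(nrow(sites))) {
      g <- sites$gene[j]
      is_marker <- g %in% src_markers
      gt <- geno[j, subj]
      own_frac <- mean(strsplit(gt, "/")[[1]] == sites$alt[j])
      nat_alt <- stats::rbinom(1, native_depth, own_frac)
      if (is_marker) {
        total_marker <- counts[g, samp]
        added <- if (rec$f_true[i] > 0) total_marker else 0  # recipients: all marker reads foreign
        lambda <- if (total_marker > 0) added / total_marker else 0
        depth_q <- stats::rpois(1, depth_scale * total_marker)
        donor_frac <- if (!is.na(donor_subj))
          mean(strsplit(geno[j, donor_subj], "/")[[1]] == sites$alt[j]) else own_frac
        mix <- (1 - lambda) * own_frac + lambda * donor_frac
      } else {
        lambda <- 0
        depth_q <- stats::rpois(1, control_depth)
        mix <- own_frac
      }
      q_alt <- stats::rbinom(1, depth_q, mix)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sites$site_id[j], gene = g, ref = sites$ref[j],
        alt = sites$alt[j], sample_id = samp, subject_id = subj,
        tissue = rec$tissue[i], dna_genotype = gt,
        native_depth = native_depth, native_alt = nat_alt,
        query_depth = depth_q, query_alt = q_alt,
        true_lambda = lambda, donor_sample = donor_samp,
        donor_subject = donor_subj, stringsAsFactors = FALSE)
    }
  }
  genotypes <- data.frame(site_id = sites$site_id, gene = sites$gene,
                          ref = sites$ref, alt = sites$alt,
                          as.data.frame(geno, stringsAsFactors = FALSE),
                          stringsAsFactors = FALSE, check.names = FALSE)
  list(sites = do.call(rbind, rows), genotypes = genotypes)
}

#' Configuration for the single-cell generator
#'
#' @param marker_gene Highly expressed, source-exclusive gene (default INS).
#' @param source_type Cell type natively expressing the marker.
#' @param recipient_types Cell types with zero native marker expression.
#' @param n_source_cells,n_recipient_cells Cells per type.
#' @param n_background_genes Shared background genes.
#' @param marker_proportion Fraction of a source cell's reads from the
#'   marker (0.3 keeps true doublets above the 1000-TP10K exclusion line
#'   while ambient levels stay far below it).
#' @param ambient_fraction Ambient contamination level: recipient marker
#'   reads accrue at this fraction of the source rate.
#' @param doublet_rate Probability a recipient cell is a doublet (its
#'   profile summed with a fresh source-cell profile).
#' @param cell_libsize Mean reads per cell.
#' @param dataset_id Dataset label.
#' @param seed Integer seed.
#' @return A validated `sc_simulation_config` list.
#' @export
sc_simulation_config <- function(marker_gene = "INS", source_type = "beta",
                                 recipient_types = c("endothelial", "mesenchymal"),
                                 n_source_cells = 200, n_recipient_cells = 300,
                                 n_background_genes = 100,
                                 marker_proportion = 0.3,
                                 ambient_fraction = 0.02, doublet_rate = 0.01,
                                 cell_libsize = 5000, dataset_id = "sim_sc",
                                 seed = 1) {
  cfg <- as.list(environment())
  if (marker_proportion <= 0 || marker_proportion >= 1)
    stop("marker_proportion must be in (0, 1)")
  if (ambient_fraction < 0 || doublet_rate < 0 || doublet_rate > 1)
    stop("ambient_fraction >= 0 and doublet_rate in [0, 1] required")
  if (n_source_cells < 1 || n_recipient_cells < 1 || cell_libsize <= 0)
    stop("cell counts and library size must be positive")
  structure(cfg, class = "sc_simulation_config")
}

#' Simulate a single-cell dataset with ambient marker contamination
#'
#' Source cells express the marker at a high, configurable share of their
#' reads; recipient cells are natively marker-free but receive Poisson
#' ambient marker counts at `ambient_fraction` of the source rate, so the
#' recipient/source mean TP10K ratio recovers the ambient fraction. A
#' configurable proportion of recipient cells are doublets: their profile is
#' summed with an independently drawn source-cell profile, lifting their
#' marker TP10K above the exclusion threshold.
#'
#' @param config An `sc_simulation_config`.
#' @return List with `cells` (a `cell_matrix` of counts) and `truth` (list:
#'   `doublets` cell ids, `ambient_fraction`, `config`).
#' @export
simulate_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sc_simulation_config"))
  set.seed(config$seed)
  bg <- sprintf("SCBG%03d", seq_len(config$n_background_genes))
  genes <- c(config$marker_gene, bg)
  w <- stats::rlnorm(length(bg), 0, 1)
  w <- w / sum(w)
  mp <- config$marker_proportion

  draw_source <- function() {
    L <- stats::rpois(1, config$cell_libsize)
    marker <- stats::rbinom(1, L, mp)
    c(marker, stats::rpois(length(bg), (L - marker) * w))
  }
  draw_recipient <- function() {
    L <- stats::rpois(1, config$cell_libsize)
    ambient <- stats::rpois(1, config$ambient_fraction * mp * L)
    c(ambient, stats::rpois(length(bg), L * w))
  }

  cols <- list(); types <- character(0); ids <- character(0)
  for (i in seq_len(config$n_source_cells)) {
    cols[[length(cols) + 1L]] <- draw_source()
    types <- c(types, config$source_type)
    ids <- c(ids, sprintf("%s_%s_%03d", config$dataset_id, config$source_type, i))
  }
  doublets <- character(0)
  for (ct in config$recipient_types) {
    for (i in seq_len(config$n_recipient_cells)) {
      prof <- draw_recipient()
      id <- sprintf("%s_%s_%03d", config$dataset_id, ct, i)
      if (stats::runif(1) < config$doublet_rate) {
        prof <- prof + draw_source()
        doublets <- c(doublets, id)
      }
      cols[[length(cols) + 1L]] <- prof
      types <- c(types, ct)
      ids <- c(ids, id)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(genes, ids)
  cells <- cell_matrix(m, cell_type = types, dataset_id = config$dataset_id,
                       value_kind = "counts")
  list(cells = cells,
       truth = list(doublets = doublets,
                    ambient_fraction = config$ambient_fraction,
                    config = config))
}
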