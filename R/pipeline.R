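#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list, fills defaults, and collects
#' every problem instead of failing on the first.
#'
#' @param config Path to a YAML file or a named list.
#' @return A `pipeline_config` list, or an error listing all problems.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(
    simulate = FALSE, counts = NULL, metadata = NULL, counts_format = "auto",
    source_tissue = "pancreas", panels = NULL,
    mean_threshold = 5, var_threshold = 4, alpha = 0.05,
    min_cluster_size = 2, min_n = 40, read_threshold = 100, window_days = 4,
    sc_threshold_tp10k = 1000, out_dir = NULL, seed = 1,
    simulate_args = list())
  cfg <- utils::modifyList(defaults, config)
  errors <- character(0)
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$counts)) errors <- c(errors, "either simulate: true or a counts path is required")
    else if (!file.exists(cfg$counts)) errors <- c(errors, paste("counts file not found:", cfg$counts))
    if (is.null(cfg$metadata)) errors <- c(errors, "a metadata path is required unless simulate: true")
    else if (!file.exists(cfg$metadata)) errors <- c(errors, paste("metadata file not found:", cfg$metadata))
    if (is.null(cfg$panels) || !length(cfg$panels))
      errors <- c(errors, paste0("no marker panel configured for source tissue '",
                                 cfg$source_tissue, "'"))
  }
  for (fld in c("mean_threshold", "var_threshold", "min_n", "read_threshold",
                "window_days", "sc_threshold_tp10k"))
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 0)
      errors <- c(errors, paste0(fld, " must be a non-negative number"))
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    errors <- c(errors, "alpha must be in (0, 1)")
  if (!is.numeric(cfg$min_cluster_size) || cfg$min_cluster_size < 2)
    errors <- c(errors, "min_cluster_size must be >= 2")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the contamination-detection pipeline end to end
#'
#' Stages, in order: per-tissue normalization and filtering; Kendall-tau
#' clustering of highly variable genes with marker-based labeling; panel
#' contamination scores within each tissue; batch flags, rank-sum
#' comparison, eligibility screen and the linear mixed model; proximity
#' summary for the source panel's lead gene. Variant-concordance and
#' single-cell stages run through their own entry points
#' ([flag_incongruency_table()], [percent_contamination()]) on the inputs
#' they need. Deterministic given the config seed.
#'
#' @param config A `pipeline_config` (see [validate_config()]) or anything
#'   it accepts.
#' @return A `contamination_report` list: `clusters` (per-tissue cluster
#'   tables), `scores`, `flags`, `rank_sum`, `eligible`, `association`,
#'   `proximity`, `notes`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  notes <- character(0)

  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = cfg$seed), cfg$simulate_args))
    sim <- simulate_bulk_study(sim_cfg)
    study <- sim$study
    truth <- sim$truth
    if (is.null(cfg$panels))
      cfg$panels <- attr(truth, "marker_sets")
    cfg$source_tissue <- sim_cfg$source_tissue
  } else {
    expr <- read_expression(cfg$counts, format = cfg$counts_format)
    meta <- read_metadata(cfg$metadata)
    study <- align_study(expr, meta)
    truth <- NULL
  }
  meta <- study$meta
  counts <- study$expr
  panels <- lapply(names(cfg$panels), function(nm) score_panel(nm, cfg$panels[[nm]]))
  names(panels) <- names(cfg$panels)
  marker_sets <- cfg$panels

  # stage 1-2: per-tissue normalization, variable genes, clusters
  clusters <- list()
  tms <- list()
  for (tis in unique(meta$tissue)) {
    ids <- meta$sample_id[meta$tissue == tis]
    sub <- expression_matrix(counts$values[, ids, drop = FALSE], "counts")
    tm <- vst_transform(sub)
    tms[[tis]] <- tm
    filt <- filter_expressed(tm, cfg$mean_threshold)
    n_expressed <- nrow(filt$matrix$values)
    if (n_expressed < 2 || length(ids) < 3) {
      notes <- c(notes, sprintf("tissue %s: too few expressed genes or samples for clustering", tis))
      next
    }
    vg <- select_variable(filt$matrix, cfg$var_threshold)
    if (length(vg) < 2) {
      clusters[[tis]] <- cluster_table(list())
      next
    }
    tau <- kendall_matrix(filt$matrix, vg)
    crit <- tau_critical(length(ids), n_expressed, cfg$alpha)
    det <- detect_clusters(tau, crit, cfg$min_cluster_size)
    labeled <- label_contamination_clusters(det$clusters, marker_sets, tis)
    tab <- cluster_table(labeled)
    attr(tab, "tau_critical") <- crit
    attr(tab, "singletons") <- det$singletons
    clusters[[tis]] <- tab
  }

  # stage 3: panel scores, per tissue, per panel
  scores <- list()
  for (pn in names(panels)) {
    per_tissue <- list()
    for (tis in setdiff(unique(meta$tissue), pn)) {
      sub_meta <- meta[meta$tissue == tis, , drop = FALSE]
      res <- tryCatch(
        panel_score(tms[[tis]], panels[[pn]], sub_meta),
        error = function(e) {
          notes <<- c(notes, sprintf("panel %s, tissue %s: %s", pn, tis,
                                     conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) per_tissue[[tis]] <- res
    }
    if (length(per_tissue))
      scores[[pn]] <- do.call(rbind, c(per_tissue, make.row.names = FALSE))
  }

  # stage 4: batch attribution for the source tissue
  flags <- compute_flags(meta, cfg$source_tissue)
  src_panel <- cfg$source_tissue
  rank_sum <- NULL
  association <- NULL
  eligible <- character(0)
  if (!is.null(scores[[src_panel]])) {
    rank_sum <- tryCatch(rank_sum_compare(scores[[src_panel]], flags),
                         error = function(e) {
                           notes <<- c(notes, paste("rank_sum:", conditionMessage(e)))
                           NULL
                         })
    eligible <- tryCatch(eligible_tissues(flags, cfg$min_n),
                         error = function(e) {
                           notes <<- c(notes, paste("eligibility:", conditionMessage(e)))
                           character(0)
                         })
    if (length(eligible))
      association <- tryCatch(
        fit_mixed_model(scores[[src_panel]], flags, meta, eligible),
        error = function(e) {
          notes <<- c(notes, paste("mixed model:", conditionMessage(e)))
          NULL
        })
  }

  lead_gene <- marker_sets[[src_panel]][1]
  proximity <- NULL
  if (lead_gene %in% rownames(counts$values)) {
    rc <- counts$values[lead_gene, flags$sample_id]
    proximity <- proximity_summary(rc, flags, cfg$read_threshold, cfg$window_days)
  }

  report <- structure(list(
    clusters = clusters, scores = scores, flags = flags,
    rank_sum = rank_sum, eligible = eligible, association = association,
    proximity = proximity, truth = truth, notes = notes, config = cfg),
    class = "contamination_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("contamination_report\n")
  for (tis in names(x$clusters)) {
    tab <- x$clusters[[tis]]
    n_contam <- length(unique(tab$cluster[tab$label == "contamination"]))
    cat(sprintf("  %s: %d cluster(s), %d labeled contamination\n",
                tis, length(unique(tab$cluster)), n_contam))
  }
  if (!is.null(x$rank_sum))
    cat(sprintf("  rank-sum same-day vs off-day: p = %.3g\n", x$rank_sum$p_value))
  if (!is.null(x$association))
    cat(sprintf("  mixed model: beta_seq = %.3f, beta_iso = %.3f\n",
                x$association$beta_seq, x$association$beta_iso))
  if (!is.null(x$proximity) && !is.na(x$proximity$fraction))
    cat(sprintf("  proximity: %.1f%% of high-count off-day samples within window\n",
                100 * x$proximity$fraction))
  if (length(x$notes)) cat("  notes:", length(x$notes), "\n")
  invisible(x)
}

#' Write a contamination report as TSV/JSON files
#'
#' @param report A `contamination_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tis in names(report$clusters))
    utils::write.table(report$clusters[[tis]],
                       file.path(dir, paste0("clusters_", tis, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (pn in names(report$scores))
    utils::write.table(report$scores[[pn]],
                       file.path(dir, paste0("scores_", pn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$flags, file.path(dir, "batch_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    rank_sum = report$rank_sum,
    eligible_tissues = report$eligible,
    association = if (!is.null(report$association))
      report$association$coefficients else NULL,
    proximity = report$proximity,
    notes = report$notes)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
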