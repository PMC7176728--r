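#' Expected alternative-allele fraction at a site
#'
#' RNA editing and preferential allele expression make DNA dosage a poor
#' predictor of RNA allele balance, so the expectation for a queried tissue
#' is taken from the same donor's native-tissue RNA whenever that tissue was
#' sequenced deeply enough; otherwise it falls back to genotype dosage
#' (0, 1/2, 1) with a flag.
#'
#' @param dna_genotype Genotype string on the ref/alt alphabet, e.g. `"C/G"`.
#' @param ref,alt Reference and alternative alleles at the site.
#' @param native_alt_count,native_depth Alt reads and total depth in the
#'   donor's native (source) tissue RNA.
#' @param min_native_depth Depth below which the dosage fallback is used
#'   (default 50).
#' @return List with `fraction` (expected alt fraction in `[0,1]`) and
#'   `source` (`"native_rna"` or `"dosage_fallback"`).
#' @export
expected_allele_fraction <- function(dna_genotype, ref, alt,
                                     native_alt_count = NA, native_depth = NA,
                                     min_native_depth = 50) {
  if (is.na(dna_genotype)) stop("genotype missing")
  alleles <- strsplit(dna_genotype, "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2 || !all(alleles %in% c(ref, alt)))
    stop("genotype '", dna_genotype, "' not on the {", ref, ",", alt, "} alphabet")
  if (!is.na(native_depth) && native_depth >= min_native_depth) {
    return(list(fraction = native_alt_count / native_depth, source = "native_rna"))
  }
  list(fraction = sum(alleles == alt) / 2, source = "dosage_fallback")
}

#' Flag a DNA/RNA allelic incongruency
#'
#' A site in a queried tissue is flagged when the observed alt fraction
#' deviates from the expected fraction by at least `min_abs_dev` *and* a
#' two-sided exact binomial test of the alt count against the expected
#' fraction survives a Bonferroni correction over `n_tests` sites at level
#' `alpha`. Sites below `min_depth` get the verdict `insufficient_depth`.
#'
#' @param alt_count,depth Observed alt reads and total depth in the queried
#'   tissue.
#' @param expected_fraction Expected alt fraction (see
#'   [expected_allele_fraction()]).
#' @param min_depth Minimum usable depth (default 50).
#' @param min_abs_dev Minimum absolute deviation (default 0.05).
#' @param alpha Family-wise significance level (default 1e-3).
#' @param n_tests Number of sites tested in the family (Bonferroni divisor,
#'   default 1).
#' @return An `incongruency_record`: list with `observed_fraction`,
#'   `expected_fraction`, `deviation`, `p_value`, `p_adjusted`, `verdict`
#'   (`"flagged"`, `"consistent"` or `"insufficient_depth"`).
#' @export
flag_incongruency <- function(alt_count, depth, expected_fraction,
                              min_depth = 50, min_abs_dev = 0.05,
                              alpha = 1e-3, n_tests = 1) {
  if (alt_count < 0 || depth < alt_count) stop("need 0 <= alt_count <= depth")
  if (expected_fraction < 0 || expected_fraction > 1)
    stop("expected_fraction must be in [0, 1]")
  obs <- alt_count / depth
  dev <- abs(obs - expected_fraction)
  if (depth < min_depth) {
    return(structure(list(observed_fraction = obs,
                          expected_fraction = expected_fraction,
                          deviation = dev, p_value = NA_real_,
                          p_adjusted = NA_real_,
                          verdict = "insufficient_depth"),
                     class = "incongruency_record"))
  }
  p <- as.numeric(stats::binom.test(alt_count, depth, p = expected_fraction,
                                    alternative = "two.sided")$p.value)
  p_adj <- min(1, p * n_tests)
  verdict <- if (dev >= min_abs_dev && p_adj <= alpha) "flagged" else "consistent"
  structure(list(observed_fraction = obs, expected_fraction = expected_fraction,
                 deviation = dev, p_value = p, p_adjusted = p_adj,
                 verdict = verdict),
            class = "incongruency_record")
}

#' @export
print.incongruency_record <- function(x, ...) {
  cat(sprintf("incongruency_record [%s]: observed %.3f vs expected %.3f (p = %.3g)\n",
              x$verdict, x$observed_fraction, x$expected_fraction, x$p_value))
  invisible(x)
}

#' Apply incongruency flagging to a table of sites
#'
#' Vectorized convenience over [flag_incongruency()], with the Bonferroni
#' family size set to the number of depth-sufficient sites in the table.
#'
#' @param sites Data frame with columns `alt_count`, `depth`,
#'   `expected_fraction` (extra columns are carried through).
#' @param min_depth,min_abs_dev,alpha Thresholds as in [flag_incongruency()].
#' @return The input with `observed_fraction`, `deviation`, `p_value`,
#'   `p_adjusted`, `verdict` columns appended.
#' @export
flag_incongruency_table <- function(sites, min_depth = 50, min_abs_dev = 0.05,
                                    alpha = 1e-3) {
  stopifnot(all(c("alt_count", "depth", "expected_fraction") %in% names(sites)))
  n_tests <- sum(sites$depth >= min_depth)
  recs <- lapply(seq_len(nrow(sites)), function(i) {
    flag_incongruency(sites$alt_count[i], sites$depth[i],
                      sites$expected_fraction[i], min_depth = min_depth,
                      min_abs_dev = min_abs_dev, alpha = alpha,
                      n_tests = max(1L, n_tests))
  })
  sites$observed_fraction <- vapply(recs, `[[`, numeric(1), "observed_fraction")
  sites$deviation <- vapply(recs, `[[`, numeric(1), "deviation")
  sites$p_value <- vapply(recs, `[[`, numeric(1), "p_value")
  sites$p_adjusted <- vapply(recs, `[[`, numeric(1), "p_adjusted")
  sites$verdict <- vapply(recs, `[[`, character(1), "verdict")
  sites
}

#' Control-gene incongruency summary
#'
#' Applies the same flagging to sites in ubiquitously expressed control
#' genes (defaults GAPDH and RAB7A), where no contamination-driven
#' incongruency is expected: a nonzero flag count indicates either real
#' sample mixing of the controls or a miscalibrated test.
#'
#' @param sites Data frame as for [flag_incongruency_table()], with a `gene`
#'   column.
#' @param control_genes Character vector (default `c("GAPDH", "RAB7A")`).
#' @param ... Thresholds passed through.
#' @return List with `n_sites`, `n_flagged`, `flagged` (the flagged rows).
#' @export
control_gene_check <- function(sites, control_genes = c("GAPDH", "RAB7A"), ...) {
  if (!length(control_genes) || !nrow(sites))
    return(list(n_sites = 0L, n_flagged = 0L, flagged = sites[0, , drop = FALSE]))
  ctrl <- sites[sites$gene %in% control_genes, , drop = FALSE]
  if (!nrow(ctrl))
    return(list(n_sites = 0L, n_flagged = 0L, flagged = ctrl))
  res <- flag_incongruency_table(ctrl, ...)
  flagged <- res[res$verdict == "flagged", , drop = FALSE]
  list(n_sites = nrow(ctrl), n_flagged = nrow(flagged), flagged = flagged)
}

#' Match a flagged incongruency to a candidate contaminant donor
#'
#' Candidates are source-tissue samples sequenced within `window_days` of
#' the recipient's sequencing day (default: the same day). Candidates
#' carrying the foreign allele are ranked by expected contribution:
#' homozygous carriers above heterozygous ones. A unique top carrier gives
#' resolution `"unique"`; several equally ranked carriers `"tied"`; no
#' carrier `"unresolved"`.
#'
#' @param foreign_allele The allele observed in the recipient but absent
#'   from its own genotype.
#' @param candidates Data frame with columns `sample_id`, `genotype`
#'   (e.g. `"C/G"`), `sequencing_date` (`Date`).
#' @param recipient_seq_date The recipient sample's sequencing date.
#' @param window_days Batch window in days (default 0 = same day only).
#' @return A `donor_match`: list with `resolution`, `donors` (ranked sample
#'   ids), `carrier_copies` (named copy counts), `n_candidates`.
#' @export
match_contaminant_donor <- function(foreign_allele, candidates,
                                    recipient_seq_date, window_days = 0) {
  cand <- candidates[!is.na(candidates$sequencing_date) &
                       abs(as.numeric(candidates$sequencing_date -
                                        recipient_seq_date)) <= window_days, ,
                     drop = FALSE]
  copies <- vapply(cand$genotype, function(gt) {
    if (is.na(gt)) return(0L)
    sum(strsplit(gt, "/", fixed = TRUE)[[1]] == foreign_allele)
  }, integer(1), USE.NAMES = FALSE)
  names(copies) <- cand$sample_id
  carriers <- copies[copies > 0]
  if (!length(carriers)) {
    resolution <- "unresolved"
    donors <- character(0)
  } else {
    top <- carriers[carriers == max(carriers)]
    donors <- names(sort(carriers, decreasing = TRUE))
    resolution <- if (length(top) == 1L) "unique" else "tied"
  }
  structure(list(resolution = resolution, donors = donors,
                 carrier_copies = copies, n_candidates = nrow(cand)),
            class = "donor_match")
}

#' @export
print.donor_match <- function(x, ...) {
  cat(sprintf("donor_match [%s]: %d candidate(s)", x$resolution, x$n_candidates))
  if (length(x$donors)) cat(", top: ", x$donors[1])
  cat("\n")
  invisible(x)
}
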