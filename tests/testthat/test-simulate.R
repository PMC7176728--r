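test_that("configs validate their invariants", {
  expect_error(simulation_config(f_same = 0.001, f_other = 0.01), "f_other <= f_same")
  expect_error(simulation_config(p_coseq = 1.5), "p_coseq")
  expect_error(simulation_config(
    marker_sets = list(pancreas = c(BG0001 = 1000))), "overlap background")
  expect_error(sc_simulation_config(marker_proportion = 1.2), "marker_proportion")
  cfg <- simulation_config()
  expect_s3_class(cfg, "simulation_config")
})

test_that("identical seed and config give bit-identical studies", {
  cfg <- simulation_config(seed = 77, samples_per_tissue = 15,
                           n_background_genes = 60)
  a <- simulate_bulk_study(cfg)
  b <- simulate_bulk_study(cfg)
  expect_identical(a$study$expr$values, b$study$expr$values)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_bulk_study(simulation_config(seed = 78, samples_per_tissue = 15,
                                              n_background_genes = 60))
  expect_false(identical(a$study$expr$values, c_$study$expr$values))
})

test_that("zero contamination rates leave recipient marker counts at exactly zero", {
  cfg <- simulation_config(f_same = 0, f_other = 0, seed = 5,
                           samples_per_tissue = 10, n_background_genes = 40)
  sim <- simulate_bulk_study(cfg)
  rec <- sim$truth$sample_id[sim$truth$tissue != "pancreas"]
  markers <- c("PRSS1", "PNLIP", "CELA3A", "CLPS")
  expect_true(all(sim$study$expr$values[markers, rec] == 0))
  expect_true(all(sim$truth$f_true == 0))
  expect_true(all(is.na(sim$truth$donor_sample)))
})

test_that("contaminant counts follow the binomial thinning of the marker proportion", {
  # one marker at 10% of the source transcriptome, same-day mean fraction 1e-3:
  # expected contaminant count = E[f] * L * p = 100
  cfg <- simulation_config(
    tissues = c("pancreas", "lung", "adipose"), samples_per_tissue = 250,
    n_background_genes = 40,
    marker_sets = list(pancreas = c(MARK = 1e5)),
    library_size_mean = 1e6, library_size_cv = 0,
    f_same = 1e-3, f_other = 1e-3, decay_half_life_days = 1e6,
    f_iso_multiplier = 1, subject_sd = 0, p_coseq = 1, seed = 31)
  sim <- simulate_bulk_study(cfg)
  rec <- sim$truth[sim$truth$tissue != "pancreas", ]
  counts <- sim$study$expr$values["MARK", rec$sample_id]
  n <- length(counts)
  expect_equal(n, 500)
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("contamination decays monotonically with distance from a source day", {
  cfg <- simulation_config(samples_per_tissue = 150, n_background_genes = 30,
                           tissues = c("pancreas", "lung"), p_coseq = 0.4,
                           subject_sd = 0, seed = 91)
  sim <- simulate_bulk_study(cfg)
  tr <- sim$truth[sim$truth$tissue != "pancreas", ]
  m_same <- mean(tr$f_true[tr$coseq])
  m_near <- mean(tr$f_true[!tr$coseq & tr$delta_days <= 2])
  m_far <- mean(tr$f_true[!tr$coseq & tr$delta_days > 2])
  expect_gt(m_same, m_near)
  expect_gt(m_near, m_far)
})

test_that("source-tissue samples are untouched by contamination injection", {
  base <- list(seed = 13, samples_per_tissue = 12, n_background_genes = 50)
  off <- simulate_bulk_study(do.call(simulation_config,
                                     c(base, f_same = 0, f_other = 0)))
  on <- simulate_bulk_study(do.call(simulation_config, base))
  src <- off$study$meta$sample_id[off$study$meta$tissue == "pancreas"]
  expect_identical(off$study$expr$values[, src], on$study$expr$values[, src])
})

test_that("simulated allele counts obey the planted mixture", {
  cfg <- simulation_config(seed = 21, samples_per_tissue = 25,
                           n_background_genes = 50)
  sim <- simulate_bulk_study(cfg)
  vr <- simulate_variant_readcounts(sim$study, sim$truth, cfg)
  s <- vr$sites
  # control sites never mix and match the subject's own genotype fraction
  ctrl <- s[s$gene %in% c("GAPDH", "RAB7A"), ]
  expect_true(all(ctrl$true_lambda == 0))
  hom_ref <- ctrl[vapply(seq_len(nrow(ctrl)), function(i)
    !grepl(ctrl$alt[i], ctrl$dna_genotype[i], fixed = TRUE), logical(1)), ]
  expect_true(all(hom_ref$query_alt == 0 | hom_ref$query_depth == 0))

  # marker sites in contaminated samples carry the donor's alleles
  mk <- s[!s$gene %in% c("GAPDH", "RAB7A") & s$true_lambda == 1 &
            s$query_depth >= 100 & !is.na(s$donor_subject), ]
  expect_gt(nrow(mk), 0)
  for (i in seq_len(min(nrow(mk), 30))) {
    row <- mk[i, ]
    donor_gt <- vr$genotypes[vr$genotypes$site_id == row$site_id, row$donor_subject]
    donor_frac <- mean(strsplit(donor_gt, "/")[[1]] == row$alt)
    expect_lt(abs(row$query_alt / row$query_depth - donor_frac), 0.2)
  }
  expect_error(simulate_variant_readcounts(sim$study, sim$truth, cfg,
                                           sites_per_gene = 0), "site list empty")
})

test_that("single-cell generator plants ambient signal and doublets as configured", {
  clean <- simulate_sc_dataset(sc_simulation_config(
    ambient_fraction = 0, doublet_rate = 0, seed = 41))
  rec <- clean$cells$cell_type != "beta"
  expect_true(all(clean$cells$values["INS", rec] == 0))
  expect_length(clean$truth$doublets, 0)

  # over seeds, the recipient/source mean TP10K ratio approaches the
  # planted ambient fraction
  ratios <- vapply(1:10, function(s) {
    sim <- simulate_sc_dataset(sc_simulation_config(
      ambient_fraction = 0.05, doublet_rate = 0, n_recipient_cells = 150,
      seed = 400 + s))
    tk <- tp10k(sim$cells)
    mean(tk$values["INS", tk$cell_type == "endothelial"]) /
      mean(tk$values["INS", tk$cell_type == "beta"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.05), 0.01)

  dbl <- simulate_sc_dataset(sc_simulation_config(
    ambient_fraction = 0.02, doublet_rate = 0.05, seed = 43))
  expect_gt(length(dbl$truth$doublets), 0)
  tk <- tp10k(dbl$cells)
  expect_true(all(tk$values["INS", dbl$truth$doublets] > 1000))
})
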