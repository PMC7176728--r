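test_that("expected allele fractions come from native RNA, with dosage fallback", {
  # homozygous reference, deep native RNA entirely reference
  e1 <- expected_allele_fraction("C/C", ref = "C", alt = "G",
                                 native_alt_count = 0, native_depth = 85803)
  expect_equal(e1$fraction, 0)
  expect_equal(e1$source, "native_rna")

  # heterozygote with 51% major allele natively -> expected alt ~ 0.49
  e2 <- expected_allele_fraction("T/C", ref = "T", alt = "C",
                                 native_alt_count = round(0.49 * 72978),
                                 native_depth = 72978)
  expect_equal(e2$fraction, 0.49, tolerance = 1e-4)

  # shallow native RNA: fall back to dosage
  e3 <- expected_allele_fraction("T/C", ref = "T", alt = "C",
                                 native_alt_count = 10, native_depth = 20)
  expect_equal(e3$fraction, 0.5)
  expect_equal(e3$source, "dosage_fallback")

  expect_error(expected_allele_fraction(NA, "C", "G"), "genotype missing")
  expect_error(expected_allele_fraction("A/T", "C", "G"), "alphabet")
})

test_that("incongruency flagging needs both a large deviation and a significant test", {
  # homozygous-C sample showing 87% foreign G at depth 204 -> flagged
  r1 <- flag_incongruency(alt_count = 177, depth = 204, expected_fraction = 0)
  expect_equal(r1$verdict, "flagged")
  expect_equal(r1$observed_fraction, 177 / 204, tolerance = 1e-6)

  # small deviation fails the deviation gate even when nominally significant
  r2 <- flag_incongruency(480, 1000, 0.5)
  expect_equal(r2$verdict, "consistent")
  expect_lt(r2$deviation, 0.05)

  # perfect concordance
  r3 <- flag_incongruency(0, 204, 0)
  expect_equal(r3$verdict, "consistent")
  expect_equal(r3$p_value, 1)

  r4 <- flag_incongruency(10, 30, 0)
  expect_equal(r4$verdict, "insufficient_depth")

  # Bonferroni: a borderline p survives alone but not across 1000 sites
  p_one <- flag_incongruency(60, 1000, 0.5)      # dev 0.06, p ~ 0
  expect_equal(p_one$verdict, "flagged")
  borderline <- flag_incongruency(445, 1000, 0.5, n_tests = 1000)
  expect_equal(borderline$verdict, "consistent")
})

test_that("flag verdicts are symmetric under allele relabeling", {
  set.seed(51)
  for (i in 1:25) {
    depth <- sample(60:500, 1)
    alt <- rbinom(1, depth, runif(1))
    exp_f <- runif(1)
    a <- flag_incongruency(alt, depth, exp_f)
    b <- flag_incongruency(depth - alt, depth, 1 - exp_f)
    expect_identical(a$verdict, b$verdict)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  }
})

test_that("control genes show no incongruencies under the null and many with planted mixing", {
  set.seed(52)
  n <- 287
  geno_frac <- sample(c(0, 0.5, 1), n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  depth <- rpois(n, 500)
  null_sites <- data.frame(
    gene = rep(c("GAPDH", "RAB7A"), length.out = n),
    alt_count = rbinom(n, depth, geno_frac),
    depth = depth, expected_fraction = geno_frac)
  chk <- control_gene_check(null_sites)
  expect_equal(chk$n_sites, n)
  expect_equal(chk$n_flagged, 0)

  # positive control: planted 40% foreign mixing flips the verdicts
  mixed <- null_sites
  donor_frac <- 1 - geno_frac
  mixed$alt_count <- rbinom(n, depth, 0.6 * geno_frac + 0.4 * donor_frac)
  chk2 <- control_gene_check(mixed)
  expect_gt(chk2$n_flagged, n / 2)

  empty <- control_gene_check(null_sites, control_genes = character(0))
  expect_equal(empty$n_sites, 0L)
})

test_that("donor matching resolves the six-candidate same-day scenario", {
  cands <- data.frame(
    sample_id = paste0("ESO", 1:6),
    genotype = c("C/C", "C/C", "G/G", "C/C", "C/C", "C/C"),
    sequencing_date = as.Date("2013-01-09"))
  dm <- match_contaminant_donor("G", cands, as.Date("2013-01-09"))
  expect_equal(dm$resolution, "unique")
  expect_equal(dm$donors[1], "ESO3")
  expect_equal(dm$n_candidates, 6)

  # nobody carries the foreign allele
  cands2 <- cands; cands2$genotype <- "C/C"
  expect_equal(match_contaminant_donor("G", cands2, as.Date("2013-01-09"))$resolution,
               "unresolved")

  # two homozygous carriers tie
  cands3 <- cands; cands3$genotype[5] <- "G/G"
  dm3 <- match_contaminant_donor("G", cands3, as.Date("2013-01-09"))
  expect_equal(dm3$resolution, "tied")
  expect_setequal(dm3$donors[1:2], c("ESO3", "ESO5"))

  # heterozygous carrier ranks below a homozygous one
  cands4 <- cands; cands4$genotype[1] <- "C/G"
  dm4 <- match_contaminant_donor("G", cands4, as.Date("2013-01-09"))
  expect_equal(dm4$resolution, "unique")
  expect_equal(dm4$donors[1], "ESO3")

  # the batch window excludes off-day candidates
  cands5 <- cands
  cands5$sequencing_date[3] <- as.Date("2013-01-12")
  dm5 <- match_contaminant_donor("G", cands5, as.Date("2013-01-09"), window_days = 0)
  expect_equal(dm5$resolution, "unresolved")
  dm6 <- match_contaminant_donor("G", cands5, as.Date("2013-01-09"), window_days = 4)
  expect_equal(dm6$resolution, "unique")
})
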