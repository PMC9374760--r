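test_that("geometric mean, RADM and their contracts", {
  expect_equal(geometric_mean(c(100, 400)), 200)
  expect_equal(geometric_mean(7), 7)
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(numeric()), "empty")

  expect_equal(radm(c(8, 12)), c(0.2, 0.2))
  expect_equal(radm(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(radm(c(0, 10)), c(1, 1))
  expect_error(radm(c(-1, 1)), "zero")

  # properties on random positive vectors: permutation invariance, scale
  # equivariance, AM-GM
  set.seed(5)
  for (i in 1:20) {
    v <- rlnorm(sample(2:10, 1), 0, 1)
    expect_equal(geometric_mean(sample(v)), geometric_mean(v))
    expect_equal(geometric_mean(3.7 * v), 3.7 * geometric_mean(v))
    expect_lte(geometric_mean(v), mean(v) + 1e-12)
  }
})

test_that("QC filtering within a biological replicate", {
  expect_equal(filter_qc_within_bio_rep(c("Good", "Good", "Good",
                                          "MaybePoor", "MaybePoor")),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(filter_qc_within_bio_rep(c("Good", "MaybePoor", "MaybePoor")),
               c(TRUE, TRUE, TRUE))
  expect_equal(filter_qc_within_bio_rep(character()), logical())
  expect_false(any(filter_qc_within_bio_rep(c("Discarded", "Discarded"))))
})

test_that("technical and biological aggregation", {
  a <- aggregate_technical(rep(3.2, 6))
  expect_equal(a$value, 3.2)
  expect_equal(a$cv, 0)
  expect_equal(aggregate_technical(c(1, 4))$value, 2)

  expect_equal(aggregate_biological(c(100, 225))$value, 150)
  expect_equal(aggregate_biological(5)$value, 5)
  expect_true(is.na(aggregate_biological(5)$cv))
  expect_equal(aggregate_biological(c(2, 2))$cv, 0)
})

test_that("peptide-form merging and discard rules", {
  expect_equal(merge_peptide_forms(c(90, 10), redundant = c(FALSE, TRUE)), 90)
  expect_equal(merge_peptide_forms(c(90, 10)), 100)
  expect_equal(merge_peptide_forms(42), 42)
})

test_that("copies/cell conversion", {
  expect_equal(copies_per_cell(1, 1, 230), 138509.2375, tolerance = 1e-6)
  expect_equal(copies_per_cell(1, 1, 460), 2 * copies_per_cell(1, 1, 230))
  expect_equal(copies_per_cell(0, 1, 230), 0)
  expect_error(copies_per_cell(1, 0, 230), "> 0")
})

test_that("protein rollup and consistency classes", {
  r <- protein_rollup(c(1e5, 4e5))
  expect_equal(r$copies_per_cell, 2e5)
  expect_equal(r$consistency, "semi_consistent") # fold 4 boundary: <=4
  expect_equal(protein_rollup(1e4)$consistency, "consistent")
  expect_equal(protein_rollup(c(1e5, 1e6))$consistency, "inconsistent")
  expect_equal(protein_rollup(c(1e5, 1.5e5))$consistency, "consistent")
})

test_that("rollup is invariant to input row order", {
  truth <- generate_truth(12, seed = 81)
  pl <- run_pipeline(truth, sim_seed = 82)
  meas <- pl$measurements
  set.seed(83)
  shuffled <- meas[sample(nrow(meas))]
  r1 <- rollup_peptides(meas, catalog = truth_catalog(truth))
  r2 <- rollup_peptides(shuffled, catalog = truth_catalog(truth))
  expect_equal(r2$proteins, r1$proteins)
  expect_equal(r2$peptides, r1$peptides)
})

test_that("redundant forms are dropped and surviving forms summed", {
  base <- data.table::data.table(
    sample_id = "B1-1", tech_rep = 1L, bio_rep = 1L, protein_ug = 1,
    qc = "Good")
  meas <- rbind(
    data.table::data.table(base, peptide_key = "TMDAGCK",
                           light_fmol_corrected = 90),
    data.table::data.table(base, peptide_key = "TM[Ox]DAGCK",
                           light_fmol_corrected = 10),
    data.table::data.table(base, peptide_key = "VVVQQK",
                           light_fmol_corrected = 90),
    data.table::data.table(base, peptide_key = "VVVQ[De]QK",
                           light_fmol_corrected = 10))
  cat_dt <- data.table::data.table(
    peptide_key = c("TMDAGCK", "TM[Ox]DAGCK", "VVVQQK", "VVVQ[De]QK"),
    protein = c("P1", "P1", "P2", "P2"),
    redundant_lower_form = c(FALSE, TRUE, FALSE, FALSE))
  res <- rollup_peptides(meas, catalog = cat_dt, pg_per_cell = 230)
  per_ug <- res$peptides$fmol_per_ug
  names(per_ug) <- res$peptides$protein
  expect_equal(unname(per_ug["P1"]), 90)   # oxidized form discarded
  expect_equal(unname(per_ug["P2"]), 100)  # unflagged forms summed
  expect_true("TM[Ox]DAGCK" %in% res$discarded$peptide_key)
})

test_that("non-unique, low-confidence and PTM-confounded peptides drop", {
  base <- data.table::data.table(
    sample_id = "B1-1", tech_rep = 1L, bio_rep = 1L, protein_ug = 1,
    qc = "Good")
  meas <- data.table::rbindlist(lapply(c("AAAK", "CCCK", "DDDK", "EEEK"),
    function(p) data.table::data.table(base, peptide_key = p,
                                       light_fmol_corrected = 5)))
  cat_dt <- data.table::data.table(
    peptide_key = c("AAAK", "CCCK", "DDDK", "EEEK"),
    protein = paste0("P", 1:4),
    unique_to_target = c(FALSE, TRUE, TRUE, TRUE),
    id_confidence_ok = c(TRUE, FALSE, TRUE, TRUE),
    ptm_confound = c(FALSE, FALSE, TRUE, FALSE))
  res <- rollup_peptides(meas, catalog = cat_dt)
  expect_equal(res$proteins$protein, "P4")
  expect_setequal(res$discarded$peptide_key, c("AAAK", "CCCK", "DDDK"))
})

test_that("tier-2 CV summary", {
  # identical replicates: CV 0, everything passes
  meas <- data.table::data.table(
    sample_id = rep(c("B1-1", "B1-2"), each = 2),
    tech_rep = rep(1:2, 2), bio_rep = 1L, protein_ug = 1,
    peptide_key = "AAAK", qc = "Good",
    light_fmol_corrected = 4)
  s <- cv_and_tier2_summary(meas)
  expect_equal(s$fraction_pass, 1)
  expect_equal(s$per_peptide$cv, 0)
  expect_equal(cv_and_tier2_summary(meas[0])$n_assays, 0L)
})
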