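test_that("common transitions: intersection of quantitative light/heavy", {
  tr <- toy_transitions()
  cm <- common_transitions(tr)
  expect_setequal(cm$fragment_ion, c("y5", "y7")) # y9 is heavy-only

  # non-quantitative in one label drops the transition
  tr2 <- data.table::copy(tr)
  tr2[label == "light" & fragment_ion == "y7", quantitative := FALSE]
  expect_equal(common_transitions(tr2)$fragment_ion, "y5")

  # disjoint sets -> empty
  tr3 <- data.table::copy(tr)
  tr3[label == "light", fragment_ion := paste0("b", 1:2)]
  expect_equal(nrow(common_transitions(tr3)), 0L)

  # precursor signals are never used for quantitation
  tr4 <- rbind(tr, data.table::data.table(
    sample_id = "S1", tech_rep = 1L, peptide_key = "ELVISLIVESK",
    precursor_charge = 2L, fragment_ion = "precursor",
    product_charge = 2L, label = c("light", "heavy"), area = 1e6,
    quantitative = TRUE))
  expect_setequal(common_transitions(tr4)$fragment_ion, c("y5", "y7"))
})

test_that("light/heavy ratio over common transitions", {
  r <- light_heavy_ratio(toy_transitions(light = c(300, 700),
                                         heavy = c(600, 1400)))
  expect_equal(r$ratio, 0.5)             # 1000 / 2000
  expect_equal(r$n_common_transitions, 2L)

  same <- toy_transitions(light = c(10, 20), heavy = c(10, 20))
  expect_equal(light_heavy_ratio(same)$ratio, 1)

  zero <- toy_transitions(heavy = c(0, 0))
  zero <- zero[!(label == "heavy" & fragment_ion == "y9")]
  expect_equal(light_heavy_ratio(zero)$qc, "Discarded")
})

test_that("to_fmol multiplies by the nominal heavy spike", {
  m <- list(ratio = 0.5)
  expect_equal(to_fmol(m, 10)$light_fmol_raw, 5)
  expect_equal(to_fmol(list(ratio = 1), 1)$light_fmol_raw, 1)
  skipped <- to_fmol(m, 0)
  expect_equal(skipped$qc, "Discarded")
})

test_that("bleed-through estimation and correction rules", {
  blanks <- data.table::data.table(
    peptide_key = c("AAK", "AAK", "CCK"),
    heavy_std_fmol = c(100, 10, 100),
    ratio = c(0.005, 0.009, 0))
  bt <- estimate_bleedthrough(blanks)
  expect_equal(bt[peptide_key == "AAK" & heavy_std_fmol == 100,
                  bleed_fraction], 0.005)
  expect_equal(bt[peptide_key == "AAK" & is.na(heavy_std_fmol),
                  bleed_fraction], 0.007) # pooled mean fallback
  expect_equal(bt[peptide_key == "CCK" & heavy_std_fmol == 100,
                  bleed_fraction], 0)
  # spiked control peptides are excluded
  expect_false("AAK" %in% estimate_bleedthrough(blanks, "AAK")$peptide_key)

  # correction: subtract, discard when bleed > 20% of light
  kept <- correct_bleedthrough(list(light_fmol_raw = 10, heavy_fmol = 100,
                                    qc = NA), 0.005)
  expect_equal(kept$light_fmol_corrected, 9.5)
  dropped <- correct_bleedthrough(list(light_fmol_raw = 2, heavy_fmol = 100,
                                       qc = NA), 0.005)
  expect_equal(dropped$qc, "Discarded")   # 0.5 > 20% of 2
  clean <- correct_bleedthrough(list(light_fmol_raw = 7, heavy_fmol = 10,
                                     qc = NA), 0)
  expect_equal(clean$light_fmol_corrected, 7)
})

test_that("QC classifier: the printed rules and the clean case", {
  expect_equal(classify_qc(2, 5e5, 5e5, 10, 40), "MaybePoor")  # <=2 transitions
  expect_equal(classify_qc(5, 5e5, 5e5, 1, 12), "MaybePoor")   # 1 fmol, >10
  expect_equal(classify_qc(5, 5e5, 5e5, 10, 501), "MaybePoor") # 10 fmol, >500
  expect_equal(classify_qc(5, 5e5, 5e5, 100, 1.9), "MaybePoor")# 100 fmol, <2
  expect_equal(classify_qc(5, 9999, 5e5, 10, 40), "MaybePoor") # light floor
  expect_equal(classify_qc(5, 5e5, 9999, 10, 40), "MaybePoor") # heavy floor
  expect_equal(classify_qc(5, 5e5, 5e5, 10, 40), "Good")
})

test_that("QC classifier agrees with the brute-force oracle", {
  set.seed(42)
  n <- 2000 # the full 1e4-point sweep runs in the acceptance suite
  g <- data.frame(
    n_common = sample(0:8, n, replace = TRUE),
    light_area = 10^runif(n, 2, 7),
    heavy_area = 10^runif(n, 2, 7),
    level = sample(c(1, 10, 100), n, replace = TRUE),
    light_fmol = 10^runif(n, -2, 3))
  got <- classify_qc(g$n_common, g$light_area, g$heavy_area, g$level,
                     g$light_fmol)
  want <- mapply(qc_oracle, g$n_common, g$light_area, g$heavy_area,
                 g$level, g$light_fmol)
  expect_identical(got, unname(want))
})

test_that("quantify_peptides: scale invariance with the floor disabled", {
  truth <- generate_truth(6, include_luciferase = FALSE, seed = 61)
  design <- generate_design()
  tr <- simulate_transitions(truth, design, seed = 62)
  m1 <- quantify_peptides(tr, design, area_floor = 0)
  tr2 <- data.table::copy(tr)[, area := area * 37]
  m2 <- quantify_peptides(tr2, design, area_floor = 0)
  expect_equal(m2$ratio, m1$ratio, tolerance = 1e-12)
  expect_equal(m2$light_fmol_corrected, m1$light_fmol_corrected,
               tolerance = 1e-12)
  expect_identical(m2$qc, m1$qc)
})

test_that("blank correction is exact on noise-free synthetic data", {
  truth <- generate_truth(8, tech_cv = 0, bio_cv = 0,
                          bleed_range = c(0.002, 0.01),
                          include_luciferase = FALSE, seed = 71)
  design <- generate_design()
  tr <- simulate_transitions(truth, design, seed = 72)
  meas <- quantify_peptides(tr, design)
  truth_fmol <- merge(
    meas[qc %in% c("Good", "MaybePoor")],
    merge(truth$peptides, truth$proteins, by = "protein"),
    by = "peptide_key")
  truth_fmol[, expected := prmquant:::.copies_to_fmol(true_copies_per_cell,
                                                      protein_ug, 230)]
  expect_equal(truth_fmol$light_fmol_corrected, truth_fmol$expected,
               tolerance = 1e-12)
  # and the estimated bleed equals the generating bleed exactly
  bt <- estimate_bleedthrough(meas[is_blank == TRUE & !is.na(ratio),
                                   .(peptide_key, heavy_std_fmol, ratio)])
  chk <- merge(bt[!is.na(heavy_std_fmol)], truth$peptides, by = "peptide_key")
  expect_equal(chk$bleed_fraction.x, chk$bleed_fraction.y, tolerance = 1e-12)
})
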