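# Independent oracles and fixture builders shared across the test files.
library(data.table)

# Run the full simulate -> quantify -> rollup pipeline on a fresh truth.
run_pipeline <- function(truth, design = generate_design(), pg_per_cell = 230,
                         sim_seed = 1L, ...) {
  tr <- simulate_transitions(truth, design, pg_per_cell = pg_per_cell,
                             seed = sim_seed)
  cat_dt <- truth_catalog(truth)
  meas <- quantify_peptides(tr, design,
                            spike_peptides = cat_dt[is_spike == TRUE, peptide_key],
                            ...)
  res <- rollup_peptides(meas, catalog = cat_dt, pg_per_cell = pg_per_cell)
  list(truth = truth, design = design, transitions = tr, measurements = meas,
       rollup = res)
}

# Brute-force Quantitation Quality oracle: every rule written out one by
# one, deliberately not sharing code with classify_qc().
qc_oracle <- function(n_common, light_area, heavy_area, level, light_fmol,
                      floor = 10000) {
  stopifnot(length(n_common) == 1L)
  if (n_common <= 2) return("MaybePoor")
  if (light_area < floor) return("MaybePoor")
  if (heavy_area < floor) return("MaybePoor")
  if (level == 1 && light_fmol > 10) return("MaybePoor")
  if (level == 10 && light_fmol > 500) return("MaybePoor")
  if (level == 100 && light_fmol < 2) return("MaybePoor")
  "Good"
}

# Brute-force uniqueness oracle: for a query peptide, digest every protein
# afresh and compare I/L-collapsed sequences.
uniqueness_oracle <- function(proteome, peptide, missed_cleavages = 2L) {
  key <- chartr("I", "L", peptide)
  hits <- character()
  for (acc in names(proteome)) {
    peps <- digest_tryptic(proteome[[acc]], missed_cleavages)$sequence
    if (key %in% chartr("I", "L", peps)) hits <- c(hits, acc)
  }
  hits
}

# A tiny hand-checkable transition table: one peptide, one run, two
# fragments in both labels plus one heavy-only fragment.
toy_transitions <- function(light = c(300, 700), heavy = c(600, 1400),
                            sample_id = "S1", peptide = "ELVISLIVESK") {
  rbind(
    data.table(sample_id = sample_id, tech_rep = 1L, peptide_key = peptide,
               precursor_charge = 2L, fragment_ion = c("y5", "y7"),
               product_charge = 1L, label = "light", area = light,
               quantitative = TRUE),
    data.table(sample_id = sample_id, tech_rep = 1L, peptide_key = peptide,
               precursor_charge = 2L, fragment_ion = c("y5", "y7", "y9"),
               product_charge = 1L, label = "heavy", area = c(heavy, 500),
               quantitative = TRUE))
}
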