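# Transition-level areas -> per-run peptide fmol: light/heavy ratios over
# common transitions, blank-based bleed-through estimation/correction, and
# the Good / Maybe Poor Quantitation Quality classifier.

#' Common quantitative transitions of one peptide in one run
#'
#' A transition belongs to the common set when the same
#' (precursor charge, fragment ion, product charge) is present *and* flagged
#' quantitative in both the light and the heavy channel. MS1/precursor
#' signals are reviewed upstream but never used for quantitation; rows whose
#' `fragment_ion` starts with `"precursor"` are excluded here.
#'
#' @param records data.frame/data.table of transition rows for one peptide
#'   in one run (`fragment_ion`, `product_charge`, `precursor_charge`,
#'   `label`, `quantitative`).
#' @return data.table of the common transition ids.
#' @export
common_transitions <- function(records) {
  r <- data.table::as.data.table(records)
  r <- r[quantitative == TRUE & !startsWith(tolower(fragment_ion), "precursor")]
  key <- c("precursor_charge", "fragment_ion", "product_charge")
  light <- unique(r[label == "light", ..key])
  heavy <- unique(r[label == "heavy", ..key])
  merge(light, heavy, by = key)
}

#' Light/heavy peak-area ratio over common transitions
#'
#' `ratio = (sum of light areas) / (sum of heavy areas)` summed over the
#' common transition set only.
#'
#' @param records transition rows for one peptide in one run.
#' @return list: `ratio`, `sum_light_area`, `sum_heavy_area`,
#'   `n_common_transitions`, `qc` (`"Discarded"` with a `reason` when the
#'   common set is empty or the heavy sum is zero, otherwise `NA` pending
#'   classification).
#' @export
light_heavy_ratio <- function(records) {
  r <- data.table::as.data.table(records)
  common <- common_transitions(r)
  out <- list(ratio = NA_real_, sum_light_area = NA_real_,
              sum_heavy_area = NA_real_, n_common_transitions = nrow(common),
              qc = NA_character_, reason = NA_character_)
  if (nrow(common) == 0L) {
    out$qc <- "Discarded"; out$reason <- "no common quantitative transitions"
    return(out)
  }
  key <- c("precursor_charge", "fragment_ion", "product_charge")
  r <- merge(r, common, by = key)
  out$sum_light_area <- sum(r[label == "light", area])
  out$sum_heavy_area <- sum(r[label == "heavy", area])
  if (out$sum_heavy_area <= 0) {
    out$qc <- "Discarded"; out$reason <- "zero heavy signal"
    return(out)
  }
  out$ratio <- out$sum_light_area / out$sum_heavy_area
  out
}

#' Convert a light/heavy ratio to light fmol per injection
#'
#' @param measurement list/row with `ratio`.
#' @param heavy_std_fmol nominal heavy-standard spike of the sample
#'   (fmol of each standard per injection).
#' @return the measurement with `heavy_fmol` and `light_fmol_raw` added, or
#'   marked skipped when the sample carries no heavy standard (level 0).
#' @export
to_fmol <- function(measurement, heavy_std_fmol) {
  m <- measurement
  if (heavy_std_fmol <= 0) {
    m$qc <- "Discarded"
    m$reason <- "no heavy standard in sample (level 0)"
    m$heavy_fmol <- 0
    m$light_fmol_raw <- NA_real_
    return(m)
  }
  m$heavy_fmol <- heavy_std_fmol
  m$light_fmol_raw <- m$ratio * heavy_std_fmol
  m
}

#' Estimate per-peptide heavy-standard bleed-through from blank runs
#'
#' The bleed-through of a heavy standard is the light/heavy ratio observed
#' in blank samples (standards, no biological material). When blanks exist
#' at several spike levels a level-matched table is returned together with
#' the pooled mean used as fallback.
#'
#' @param blank_measurements per-run measurement table restricted to blank
#'   samples (`peptide_key`, `heavy_std_fmol`, `ratio`).
#' @param spike_peptides peptide keys whose light signal in blanks is a
#'   deliberate spike (e.g. luciferase positive-control peptides); their
#'   bleed-through is set to 0 since the blank ratio does not measure
#'   standard impurity for them.
#' @return data.table with `peptide_key`, `heavy_std_fmol` (NA rows carry
#'   the pooled mean), `bleed_fraction`.
#' @export
estimate_bleedthrough <- function(blank_measurements, spike_peptides = character()) {
  b <- data.table::as.data.table(blank_measurements)
  b <- b[!is.na(ratio) & heavy_std_fmol > 0]
  b <- b[!peptide_key %in% spike_peptides]
  if (nrow(b) == 0L) {
    return(data.table::data.table(peptide_key = character(),
                                  heavy_std_fmol = numeric(),
                                  bleed_fraction = numeric()))
  }
  by_level <- b[, .(bleed_fraction = mean(ratio)),
                by = .(peptide_key, heavy_std_fmol)]
  pooled <- b[, .(heavy_std_fmol = NA_real_, bleed_fraction = mean(ratio)),
              by = peptide_key]
  rbind(by_level, pooled)
}

# resolve one peptide/level to a bleed fraction: level-matched, else pooled,
# else 0 (absent from all blanks)
.lookup_bleed <- function(bleed_table, peptide, level) {
  hit <- bleed_table[peptide_key == peptide & heavy_std_fmol == level,
                     bleed_fraction]
  if (length(hit)) return(hit[1L])
  hit <- bleed_table[peptide_key == peptide & is.na(heavy_std_fmol),
                     bleed_fraction]
  if (length(hit)) return(hit[1L])
  0
}

#' Correct a measurement for heavy-standard bleed-through
#'
#' Subtracts `bleed_fraction * heavy_fmol` from the raw light fmol. If the
#' bleed-through exceeds 20% of the total light abundance the measurement is
#' discarded (so corrected values can never go negative).
#'
#' @param measurement list/row with `light_fmol_raw` and `heavy_fmol`.
#' @param bleed_fraction blank light/heavy ratio for this peptide (and
#'   spike level, when level-matched).
#' @param max_bleed_share discard threshold, default 0.20.
#' @return measurement with `bleed_fraction` and `light_fmol_corrected`
#'   filled in, possibly `qc = "Discarded"`.
#' @export
correct_bleedthrough <- function(measurement, bleed_fraction,
                                 max_bleed_share = 0.20) {
  m <- measurement
  m$bleed_fraction <- bleed_fraction
  contrib <- bleed_fraction * m$heavy_fmol
  if (is.na(m$light_fmol_raw)) {
    m$light_fmol_corrected <- NA_real_
    return(m)
  }
  if (contrib > max_bleed_share * m$light_fmol_raw) {
    m$qc <- "Discarded"
    m$reason <- "bleed-through > 20% of light abundance"
    m$light_fmol_corrected <- NA_real_
  } else {
    m$light_fmol_corrected <- m$light_fmol_raw - contrib
  }
  m
}

#' Quantitation Quality classification of one measurement
#'
#' `MaybePoor` when any rule fires, else `Good`:
#' * number of quantitated common transitions <= 2,
#' * summed peak area (light **or** heavy) below the sensitivity floor
#'   (default 10000),
#' * extreme light/heavy ratio relative to the nominal spike level:
#'   heavy = 1 fmol and light > 10 fmol; heavy = 10 fmol and light > 500
#'   fmol; heavy = 100 fmol and light < 2 fmol.
#'
#' @param n_common_transitions integer.
#' @param sum_light_area,sum_heavy_area summed areas over the common set.
#' @param heavy_std_fmol nominal spike level of the sample.
#' @param light_fmol light fmol per injection (raw, ratio x level).
#' @param area_floor sensitivity floor, default 10000; set to 0 to disable.
#' @return `"Good"` or `"MaybePoor"` (vectorized).
#' @export
classify_qc <- function(n_common_transitions, sum_light_area, sum_heavy_area,
                        heavy_std_fmol, light_fmol, area_floor = 10000) {
  poor <- n_common_transitions <= 2L |
    sum_light_area < area_floor | sum_heavy_area < area_floor |
    (heavy_std_fmol == 1 & light_fmol > 10) |
    (heavy_std_fmol == 10 & light_fmol > 500) |
    (heavy_std_fmol == 100 & light_fmol < 2)
  ifelse(poor, "MaybePoor", "Good")
}

#' Quantify all peptides: transition areas to per-run corrected fmol
#'
#' The per-run driver: for every (sample, technical replicate, peptide) it
#' computes the light/heavy ratio over common transitions, converts it to
#' fmol via the sample's nominal heavy spike, estimates bleed-through from
#' the blank runs, corrects (or discards) each measurement, and classifies
#' Quantitation Quality.
#'
#' @param transitions transition table ([read_transition_report()] or
#'   [simulate_transitions()]).
#' @param design sample design table ([read_design_table()] or
#'   [generate_design()]).
#' @param bleed_mode `"level"` (level-matched blank ratios, pooled-mean
#'   fallback) or `"pooled"` (always the pooled mean).
#' @param area_floor QC sensitivity floor, see [classify_qc()].
#' @param spike_peptides see [estimate_bleedthrough()].
#' @param max_bleed_share see [correct_bleedthrough()].
#' @return data.table, one row per (sample, tech rep, peptide): sums,
#'   ratio, fmol fields, `bleed_fraction`, `qc`, `reason`, plus the design
#'   columns `bio_rep`, `protein_ug`, `heavy_std_fmol`, `is_blank`.
#' @export
quantify_peptides <- function(transitions, design,
                              bleed_mode = c("level", "pooled"),
                              area_floor = 10000,
                              spike_peptides = character(),
                              max_bleed_share = 0.20) {
  bleed_mode <- match.arg(bleed_mode)
  tr <- data.table::as.data.table(transitions)
  de <- data.table::as.data.table(design)

  unknown <- setdiff(unique(tr$sample_id), de$sample_id)
  if (length(unknown))
    stop("transition report references samples absent from the design: ",
         paste(unknown, collapse = ", "))

  # ratio over common quantitative transitions, vectorized per run/peptide
  tr <- tr[quantitative == TRUE & !startsWith(tolower(fragment_ion), "precursor")]
  key <- c("sample_id", "tech_rep", "peptide_key",
           "precursor_charge", "fragment_ion", "product_charge")
  wide <- data.table::dcast(tr, sample_id + tech_rep + peptide_key +
                              precursor_charge + fragment_ion + product_charge ~ label,
                            value.var = "area", fun.aggregate = sum, fill = NA_real_)
  if (!"light" %in% names(wide)) wide[, light := NA_real_]
  if (!"heavy" %in% names(wide)) wide[, heavy := NA_real_]
  common <- wide[!is.na(light) & !is.na(heavy)]
  meas <- common[, .(n_common_transitions = .N,
                     sum_light_area = sum(light),
                     sum_heavy_area = sum(heavy)),
                 by = .(sample_id, tech_rep, peptide_key)]
  # runs where the peptide appears but has no common transition
  all_runs <- unique(wide[, .(sample_id, tech_rep, peptide_key)])
  meas <- merge(all_runs, meas, by = c("sample_id", "tech_rep", "peptide_key"),
                all.x = TRUE)
  meas[is.na(n_common_transitions), n_common_transitions := 0L]

  meas <- merge(meas,
                de[, .(sample_id, bio_rep, protein_ug, heavy_std_fmol, is_blank)],
                by = "sample_id")
  meas[, `:=`(ratio = NA_real_, qc = NA_character_, reason = NA_character_)]
  meas[n_common_transitions == 0L,
       `:=`(qc = "Discarded", reason = "no common quantitative transitions")]
  meas[n_common_transitions > 0L & sum_heavy_area <= 0,
       `:=`(qc = "Discarded", reason = "zero heavy signal")]
  meas[is.na(qc), ratio := sum_light_area / sum_heavy_area]

  # bleed-through from blanks
  blanks <- meas[is_blank == TRUE & !is.na(ratio)]
  bleed_table <- estimate_bleedthrough(
    blanks[, .(peptide_key, heavy_std_fmol, ratio)], spike_peptides)
  if (bleed_mode == "pooled") bleed_table <- bleed_table[is.na(heavy_std_fmol)]

  # fmol conversion (non-blank, level > 0)
  meas[is.na(qc) & !is_blank & heavy_std_fmol <= 0,
       `:=`(qc = "Discarded", reason = "no heavy standard in sample (level 0)")]
  meas[, heavy_fmol := heavy_std_fmol]
  meas[, light_fmol_raw := ifelse(is.na(qc) & !is_blank, ratio * heavy_std_fmol,
                                  NA_real_)]

  # level-matched bleed fraction with pooled fallback, then 0
  lvl <- bleed_table[!is.na(heavy_std_fmol)]
  pooled <- bleed_table[is.na(heavy_std_fmol),
                        .(peptide_key, pooled_bleed = bleed_fraction)]
  meas <- merge(meas, lvl, by = c("peptide_key", "heavy_std_fmol"), all.x = TRUE)
  meas <- merge(meas, pooled, by = "peptide_key", all.x = TRUE)
  meas[is.na(bleed_fraction), bleed_fraction := pooled_bleed]
  meas[is.na(bleed_fraction), bleed_fraction := 0]
  meas[, pooled_bleed := NULL]

  meas[, bleed_fmol := bleed_fraction * heavy_fmol]
  meas[, light_fmol_corrected := NA_real_]
  meas[is.na(qc) & !is_blank & bleed_fmol > max_bleed_share * light_fmol_raw,
       `:=`(qc = "Discarded", reason = "bleed-through > 20% of light abundance")]
  meas[is.na(qc) & !is_blank,
       light_fmol_corrected := light_fmol_raw - bleed_fmol]

  # QC classification for quantified, non-blank measurements
  meas[is.na(qc) & !is_blank,
       qc := classify_qc(n_common_transitions, sum_light_area, sum_heavy_area,
                         heavy_std_fmol, light_fmol_raw, area_floor)]
  meas[is.na(qc) & is_blank, qc := "Blank"]
  data.table::setcolorder(meas, c("sample_id", "tech_rep", "peptide_key"))
  meas[order(sample_id, tech_rep, peptide_key)]
}
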