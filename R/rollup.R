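# Replicate aggregation and protein rollup: geometric means across technical
# replicates (including the stable-isotope dilution series), then across
# biological replicates, then across target peptides; plus the RADM/CV
# diagnostics and the peptide-form merging / discard rules.

#' Geometric mean
#'
#' @param values positive numeric vector.
#' @return `exp(mean(log(values)))`.
#' @examples
#' geometric_mean(c(100, 400)) # 200
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("geometric_mean of empty vector")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric_mean requires finite positive values; discard others first")
  exp(mean(log(values)))
}

#' Relative absolute deviation from the mean (RADM)
#'
#' `|(x - M)/M|` element-wise, with `M` the *arithmetic* mean.
#'
#' @param values numeric vector with nonzero arithmetic mean.
#' @return numeric vector of the same length.
#' @examples
#' radm(c(8, 12)) # 0.2 0.2
#' @export
radm <- function(values) {
  m <- mean(values)
  if (m == 0) stop("RADM undefined: arithmetic mean is zero")
  abs((values - m) / m)
}

# sample CV; NA for a single value
.cv <- function(values) {
  if (length(values) < 2L) return(NA_real_)
  stats::sd(values) / mean(values)
}

#' Retain measurements of one peptide within one biological replicate
#'
#' If at least two measurements are classified `Good`, all `MaybePoor`
#' measurements are dropped; otherwise both classes are retained.
#' `Discarded` measurements are never retained.
#'
#' @param qc character vector of QC classes
#'   (`"Good"`, `"MaybePoor"`, `"Discarded"`).
#' @return logical vector: which measurements to keep.
#' @export
filter_qc_within_bio_rep <- function(qc) {
  keep <- qc != "Discarded"
  if (sum(qc == "Good") >= 2L) keep <- keep & qc != "MaybePoor"
  keep
}

#' Aggregate one peptide's technical replicates within a biological replicate
#'
#' Input values must already be normalized to fmol per microgram of injected
#' cell protein so that the stable-isotope dilution series can be pooled
#' with the LC-MS technical replicates (a maximum of 6 values with 2
#' technical replicates at 3 dilution levels).
#'
#' @param fmol_per_ug positive values retained by [filter_qc_within_bio_rep()].
#' @return list with `value` (geometric mean), `radm`, `cv`, `n_used`.
#' @export
aggregate_technical <- function(fmol_per_ug) {
  list(value = geometric_mean(fmol_per_ug),
       radm = radm(fmol_per_ug),
       cv = .cv(fmol_per_ug),
       n_used = length(fmol_per_ug))
}

#' Aggregate one peptide across biological replicates
#'
#' @param per_bio_values positive per-biological-replicate abundances.
#' @return list with `value` (geometric mean) and `cv` (NA with one rep).
#' @export
aggregate_biological <- function(per_bio_values) {
  list(value = geometric_mean(per_bio_values), cv = .cv(per_bio_values))
}

#' Merge quantified forms of the same target peptide
#'
#' Forms flagged as redundant lower-abundance forms (e.g. an oxidized form
#' of a peptide whose unmodified form dominates) are dropped; the remaining
#' forms of the same target peptide are summed.
#'
#' @param abundances numeric abundances of the forms.
#' @param redundant logical, same length: drop this form before summing.
#' @return single merged abundance.
#' @export
merge_peptide_forms <- function(abundances, redundant = rep(FALSE, length(abundances))) {
  kept <- abundances[!redundant]
  if (length(kept) == 0L) return(NA_real_)
  sum(kept)
}

#' Roll peptide abundances up to one protein
#'
#' Geometric mean across the target peptides, with a peptide-to-protein
#' consistency class derived from the maximum pairwise fold difference.
#'
#' @param peptide_values positive copies/cell values of the retained peptides.
#' @param max_fold_consistent,max_fold_semi fold-difference thresholds:
#'   max/min < `max_fold_consistent` is `consistent`, up to `max_fold_semi`
#'   is `semi_consistent`, beyond is `inconsistent`.
#' @return list with `copies_per_cell`, `n_peptides_used`, `consistency`,
#'   `max_fold`.
#' @export
protein_rollup <- function(peptide_values, max_fold_consistent = 2,
                           max_fold_semi = 4) {
  stopifnot(length(peptide_values) >= 1L)
  fold <- max(peptide_values) / min(peptide_values)
  consistency <- if (length(peptide_values) == 1L || fold < max_fold_consistent) {
    "consistent"
  } else if (fold <= max_fold_semi) "semi_consistent" else "inconsistent"
  list(copies_per_cell = geometric_mean(peptide_values),
       n_peptides_used = length(peptide_values),
       consistency = consistency,
       max_fold = fold)
}

#' Aggregate per-run peptide measurements to peptide and protein abundances
#'
#' The full rollup: QC filtering within each biological replicate, geometric
#' mean across up to 6 technical/dilution replicates, geometric mean across
#' biological replicates, conversion to copies/cell, peptide-form merging,
#' peptide discard rules, and geometric-mean protein rollup with a
#' consistency class.
#'
#' @param measurements per-run peptide measurement table from
#'   [quantify_peptides()] (needs `sample_id`, `tech_rep`, `peptide_key`,
#'   `bio_rep`, `protein_ug`, `light_fmol_corrected`, `qc`).
#' @param catalog optional peptide catalog (`peptide_key`, `protein`,
#'   `base_sequence`, and logical `unique_to_target`, `id_confidence_ok`,
#'   `ptm_confound`, `redundant_lower_form`, `is_spike`). Without a catalog
#'   every peptide key is treated as its own clean singleton target of a
#'   protein with the same name.
#' @param pg_per_cell median protein mass per cell (pg), default 230.
#' @param max_fold_consistent,max_fold_semi see [protein_rollup()].
#' @param exclude_inconsistent drop `inconsistent` peptide pairs from the
#'   protein geometric mean (default keeps them and only flags the protein).
#' @return list of data.tables: `peptides` (one row per retained peptide:
#'   per-bio-rep values, technical/biological CV, RADM summary, copies/cell),
#'   `proteins` (copies/cell, n peptides, consistency), `per_bio`
#'   (peptide x biological replicate detail: geometric mean, technical CV,
#'   replicates used), and `discarded` (peptide keys with reasons).
#' @export
rollup_peptides <- function(measurements, catalog = NULL, pg_per_cell = 230,
                            max_fold_consistent = 2, max_fold_semi = 4,
                            exclude_inconsistent = FALSE) {
  m <- data.table::as.data.table(measurements)
  need <- c("peptide_key", "bio_rep", "protein_ug", "light_fmol_corrected", "qc")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("measurements missing columns: ", paste(miss, collapse = ", "))
  discarded <- data.table::data.table(peptide_key = character(), reason = character())

  m <- m[!is.na(bio_rep)]
  m <- m[qc != "Discarded"]
  bad <- m[!is.finite(light_fmol_corrected) | light_fmol_corrected <= 0]
  if (nrow(bad)) {
    discarded <- rbind(discarded, unique(bad[, .(peptide_key,
      reason = "nonpositive corrected fmol in some runs")]))
    m <- m[is.finite(light_fmol_corrected) & light_fmol_corrected > 0]
  }
  if (nrow(m) == 0L) {
    return(list(peptides = data.table::data.table(), proteins = data.table::data.table(),
                per_bio = data.table::data.table(), discarded = discarded))
  }
  m[, fmol_per_ug := light_fmol_corrected / protein_ug]

  # QC filter within each (peptide, bio rep), then geometric mean over <=6
  m <- m[, .SD[filter_qc_within_bio_rep(qc)], by = .(peptide_key, bio_rep)]
  per_bio <- m[, {
    a <- aggregate_technical(fmol_per_ug)
    .(value = a$value, tech_cv = a$cv, n_used = a$n_used,
      max_radm = max(a$radm))
  }, by = .(peptide_key, bio_rep)]

  peptides <- per_bio[, {
    b <- aggregate_biological(value)
    .(fmol_per_ug = b$value, biological_cv = b$cv,
      technical_cv = mean(tech_cv, na.rm = TRUE),
      n_bio_reps = .N, n_replicates_used = sum(n_used),
      max_radm = max(max_radm))
  }, by = peptide_key]
  peptides[, copies_per_cell := .fmol_per_ug_to_copies(fmol_per_ug, pg_per_cell)]
  per_bio_out <- data.table::copy(per_bio)

  # attach catalog (or a pass-through catalog of clean singleton targets)
  if (is.null(catalog)) {
    cat_dt <- data.table::data.table(
      peptide_key = peptides$peptide_key,
      protein = peptides$peptide_key,
      base_sequence = strip_modifications(peptides$peptide_key),
      unique_to_target = TRUE, id_confidence_ok = TRUE,
      ptm_confound = FALSE, redundant_lower_form = FALSE, is_spike = FALSE)
  } else {
    cat_dt <- data.table::as.data.table(catalog)
    for (col in c("unique_to_target", "id_confidence_ok")) {
      if (!col %in% names(cat_dt)) cat_dt[, (col) := TRUE]
    }
    for (col in c("ptm_confound", "redundant_lower_form", "is_spike")) {
      if (!col %in% names(cat_dt)) cat_dt[, (col) := FALSE]
    }
    if (!"base_sequence" %in% names(cat_dt))
      cat_dt[, base_sequence := strip_modifications(peptide_key)]
  }
  peptides <- merge(peptides, cat_dt, by = "peptide_key", all.x = TRUE)
  orphan <- peptides[is.na(protein)]
  if (nrow(orphan)) {
    discarded <- rbind(discarded,
      orphan[, .(peptide_key, reason = "peptide absent from catalog")])
    peptides <- peptides[!is.na(protein)]
  }

  # merge peptide forms sharing (protein, base_sequence)
  red <- peptides[redundant_lower_form == TRUE]
  if (nrow(red)) discarded <- rbind(discarded,
    red[, .(peptide_key, reason = "redundant lower-abundance peptide form")])
  peptides <- peptides[, {
    keep <- !redundant_lower_form
    if (!any(keep)) NULL else .(
      peptide_key = peptide_key[keep][which.max(copies_per_cell[keep])],
      n_forms = sum(keep),
      copies_per_cell = merge_peptide_forms(copies_per_cell[keep]),
      fmol_per_ug = merge_peptide_forms(fmol_per_ug[keep]),
      technical_cv = mean(technical_cv[keep], na.rm = TRUE),
      biological_cv = mean(biological_cv[keep], na.rm = TRUE),
      max_radm = max(max_radm[keep]),
      n_replicates_used = sum(n_replicates_used[keep]),
      unique_to_target = all(unique_to_target[keep]),
      id_confidence_ok = all(id_confidence_ok[keep]),
      ptm_confound = any(ptm_confound[keep]),
      is_spike = any(is_spike[keep]))
  }, by = .(protein, base_sequence)]

  # peptide discard rules
  drop <- peptides[!unique_to_target | !id_confidence_ok | ptm_confound]
  if (nrow(drop)) {
    discarded <- rbind(discarded, drop[, .(peptide_key,
      reason = fifelse(!unique_to_target, "not unique to target protein",
        fifelse(!id_confidence_ok, "low-confidence identification",
                "PTM confounds quantification")))])
    peptides <- peptides[unique_to_target & id_confidence_ok & !ptm_confound]
  }

  proteins <- peptides[, {
    vals <- copies_per_cell
    r <- protein_rollup(vals, max_fold_consistent, max_fold_semi)
    if (exclude_inconsistent && r$consistency == "inconsistent" && length(vals) > 2L) {
      # drop the single farthest-from-median peptide and re-roll
      keep <- seq_along(vals)[-which.max(abs(log(vals) - stats::median(log(vals))))]
      r <- protein_rollup(vals[keep], max_fold_consistent, max_fold_semi)
    }
    .(copies_per_cell = r$copies_per_cell, n_peptides_used = r$n_peptides_used,
      consistency = r$consistency, max_fold = r$max_fold,
      is_spike = any(is_spike))
  }, by = protein]

  list(peptides = peptides[order(protein, base_sequence)],
       proteins = proteins[order(protein)],
       per_bio = per_bio_out[order(peptide_key, bio_rep)],
       discarded = discarded)
}

#' Per-peptide CV diagnostics and the Tier-2 precision summary
#'
#' Computes, for each peptide, the CV across all retained replicate-level
#' measurements (technical and biological pooled), and reports the fraction
#' of peptide assays with CV below a threshold (Tier 2 targeted assays
#' typically achieve < 20-35% CV).
#'
#' @param measurements per-run measurement table as in [rollup_peptides()].
#' @param cv_threshold default 0.35.
#' @return list: `per_peptide` data.table (`peptide_key`, `cv`, `n`),
#'   `n_assays`, `n_pass`, `fraction_pass`.
#' @export
cv_and_tier2_summary <- function(measurements, cv_threshold = 0.35) {
  m <- data.table::as.data.table(measurements)
  if (nrow(m) == 0L) {
    return(list(per_peptide = data.table::data.table(),
                n_assays = 0L, n_pass = 0L, fraction_pass = NA_real_))
  }
  m <- m[qc != "Discarded" & !is.na(bio_rep) &
           is.finite(light_fmol_corrected) & light_fmol_corrected > 0]
  m[, fmol_per_ug := light_fmol_corrected / protein_ug]
  m <- m[, .SD[filter_qc_within_bio_rep(qc)], by = .(peptide_key, bio_rep)]
  per <- m[, .(cv = .cv(fmol_per_ug), n = .N), by = peptide_key]
  per <- per[!is.na(cv)]
  list(per_peptide = per[order(peptide_key)],
       n_assays = nrow(per),
       n_pass = sum(per$cv < cv_threshold),
       fraction_pass = if (nrow(per)) mean(per$cv < cv_threshold) else NA_real_)
}
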