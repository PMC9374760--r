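# Ground-truthed synthetic data: a forward model of the SID-PRM experiment
# (log-uniform true copies/cell, per-transition response factors, lognormal
# technical and biological noise, heavy-standard bleed-through, a Table-1
# style dilution/blank design) plus an RNA-seq counts table log-linearly
# related to protein abundance. The generator is the oracle for every
# downstream stage.

# lognormal multiplier with median 1 and coefficient of variation cv
.lognormal_cv_sigma <- function(cv) sqrt(log1p(cv^2))

.rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = .lognormal_cv_sigma(cv))
}

# random tryptic-looking peptide sequences (end in K/R, no internal K/R,P)
.random_peptides <- function(n, len_range = c(8L, 15L)) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]] # no K/R internally
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(seq(len_range[1], len_range[2]), need, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1))
    out <- unique(c(out, seqs))
  }
  out[seq_len(n)]
}

#' Generate the ground truth of a synthetic SID-PRM experiment
#'
#' True protein abundances are drawn log-uniformly over `abundance_range`
#' (default the observed span of absolute macrophage protein abundances,
#' 1,332 to 2.27e8 copies/cell). Each protein gets `peptides_per_protein`
#' target peptides; each peptide gets `n_transitions` fragment transitions
#' with response factors (area per fmol) drawn log-uniformly over two
#' decades, and a heavy-standard bleed-through fraction drawn uniformly
#' over `bleed_range` (standards show 0-1% light impurity). A firefly
#' luciferase spike (20 fmol/injection, i.e. 1 pmol per 50x preparation)
#' can be included as an ordinary target protein with known light amount,
#' giving a built-in positive control.
#'
#' @param n_proteins number of (non-spike) target proteins.
#' @param peptides_per_protein default 2.
#' @param abundance_range copies/cell range, default `c(1.332e3, 2.27e8)`.
#' @param n_transitions fragment transitions per peptide, default 5.
#' @param rf_range response-factor range (area per fmol), default `c(1e3, 1e5)`.
#' @param bleed_range bleed-through fraction range, default `c(0, 0.01)`.
#' @param tech_cv technical (injection-to-injection) CV of the measured
#'   light/heavy ratio, default 0.15.
#' @param bio_cv biological (animal-to-animal) CV of true abundance,
#'   default 0.10.
#' @param include_luciferase add the spiked positive-control protein.
#' @param luciferase_fmol known spike, fmol/injection, default 20.
#' @param seed RNG seed; the truth is deterministic given the seed.
#' @return object of class `prm_truth`: list with data.tables `proteins`
#'   (`protein`, `true_copies_per_cell`, `is_spike`, `spike_fmol`),
#'   `peptides` (`protein`, `peptide_key`, `bleed_fraction`),
#'   `transitions` (`peptide_key`, `fragment_ion`, `product_charge`,
#'   `precursor_charge`, `response_factor`) and the noise/seed parameters.
#' @export
generate_truth <- function(n_proteins, peptides_per_protein = 2L,
                           abundance_range = c(1.332e3, 2.27e8),
                           n_transitions = 5L, rf_range = c(1e3, 1e5),
                           bleed_range = c(0, 0.01),
                           tech_cv = 0.15, bio_cv = 0.10,
                           include_luciferase = TRUE, luciferase_fmol = 20,
                           seed = 1L) {
  stopifnot(n_proteins >= 1L, peptides_per_protein >= 1L)
  if (any(abundance_range <= 0) || diff(abundance_range) < 0)
    stop("abundance_range must be positive and non-decreasing")
  set.seed(seed)
  prot <- sprintf("P%04d", seq_len(n_proteins))
  copies <- 10^stats::runif(n_proteins, log10(abundance_range[1]),
                            log10(abundance_range[2]))
  proteins <- data.table::data.table(protein = prot,
                                     true_copies_per_cell = copies,
                                     is_spike = FALSE, spike_fmol = NA_real_)
  if (include_luciferase) {
    proteins <- rbind(proteins, data.table::data.table(
      protein = "LUC_PHOPY", true_copies_per_cell = NA_real_,
      is_spike = TRUE, spike_fmol = luciferase_fmol))
  }
  n_pep <- nrow(proteins) * peptides_per_protein
  peptides <- data.table::data.table(
    protein = rep(proteins$protein, each = peptides_per_protein),
    peptide_key = .random_peptides(n_pep),
    bleed_fraction = stats::runif(n_pep, bleed_range[1], bleed_range[2]))
  transitions <- data.table::data.table(
    peptide_key = rep(peptides$peptide_key, each = n_transitions),
    precursor_charge = 2L,
    fragment_ion = rep(paste0("y", seq(3L, 2L + n_transitions)), n_pep),
    product_charge = 1L)
  transitions[, response_factor :=
    10^stats::runif(.N, log10(rf_range[1]), log10(rf_range[2]))]
  structure(list(proteins = proteins, peptides = peptides,
                 transitions = transitions,
                 tech_cv = tech_cv, bio_cv = bio_cv, seed = seed),
            class = "prm_truth")
}

#' @export
print.prm_truth <- function(x, ...) {
  cat("Synthetic SID-PRM ground truth\n",
      " proteins: ", nrow(x$proteins),
      " (", sum(x$proteins$is_spike), " spiked)\n",
      " peptides: ", nrow(x$peptides),
      ", transitions/peptide: ",
      nrow(x$transitions) / nrow(x$peptides), "\n",
      " tech CV ", x$tech_cv, ", bio CV ", x$bio_cv,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Peptide catalog of a synthetic truth
#'
#' The catalog [rollup_peptides()] needs to map peptide keys to proteins:
#' all synthetic peptides are unique, confidently identified and
#' unconfounded; spike-protein peptides carry `is_spike = TRUE`.
#'
#' @param truth a [generate_truth()] object.
#' @return catalog data.table.
#' @export
truth_catalog <- function(truth) {
  stopifnot(inherits(truth, "prm_truth"))
  cat_dt <- merge(truth$peptides[, .(protein, peptide_key)],
                  truth$proteins[, .(protein, is_spike)], by = "protein")
  cat_dt[, `:=`(base_sequence = strip_modifications(peptide_key),
                unique_to_target = TRUE, id_confidence_ok = TRUE,
                ptm_confound = FALSE, redundant_lower_form = FALSE)]
  cat_dt[]
}

#' Generate a dilution-series sample design
#'
#' Default topology mirrors the absolute-quantitation design: one blank per
#' nonzero heavy-standard level (standards only, no cell lysate, 1 LC-MS
#' technical replicate each) and, per biological replicate, one sample per
#' level including level 0, each analyzed in `n_tech` technical replicates.
#' With levels {0,1,10,100} and 2 biological replicates this gives 11
#' samples and 19 LC-MS runs.
#'
#' @param levels heavy-standard fmol/injection levels, default `c(0,1,10,100)`.
#' @param n_tech technical replicates per non-blank sample, default 2.
#' @param n_bio biological replicates, default 2.
#' @param protein_ug cell protein per injection of non-blank samples (µg).
#' @param luciferase_fmol luciferase spike per injection (fmol), all samples.
#' @return data.table of samples: `sample_id`, `bio_rep` (NA for blanks),
#'   `protein_ug`, `luciferase_fmol`, `heavy_std_fmol`, `n_tech_reps`,
#'   `is_blank`.
#' @export
generate_design <- function(levels = c(0, 1, 10, 100), n_tech = 2L,
                            n_bio = 2L, protein_ug = 1, luciferase_fmol = 20) {
  stopifnot(length(levels) >= 1L, n_tech >= 1L, n_bio >= 0L)
  nz <- sort(unique(levels[levels > 0]))
  blanks <- if (length(nz)) data.table::data.table(
    sample_id = sprintf("B0-%d", seq_along(nz)),
    bio_rep = NA_integer_, protein_ug = 0,
    luciferase_fmol = luciferase_fmol, heavy_std_fmol = nz,
    n_tech_reps = 1L, is_blank = TRUE) else NULL
  lv <- sort(unique(levels))
  samples <- if (n_bio >= 1L) data.table::data.table(
    sample_id = sprintf("B%d-%d", rep(seq_len(n_bio), each = length(lv)),
                        rep(seq_along(lv) - 1L, n_bio)),
    bio_rep = rep(seq_len(n_bio), each = length(lv)),
    protein_ug = protein_ug, luciferase_fmol = luciferase_fmol,
    heavy_std_fmol = rep(lv, n_bio),
    n_tech_reps = as.integer(n_tech), is_blank = FALSE) else NULL
  rbind(blanks, samples)
}

#' Simulate transition-level peak areas from a ground truth and a design
#'
#' Forward model, per peptide and LC-MS run:
#' \deqn{A_{light,t} = (f_L \epsilon_L + b f_H) \cdot r_t \cdot s, \qquad
#'       A_{heavy,t} = f_H \epsilon_H \cdot r_t \cdot s}
#' where `f_L` is the endogenous light fmol/injection (true copies/cell
#' times a biological lognormal factor, converted via the protein load and
#' `pg_per_cell`), `f_H` the heavy spike, `b` the bleed-through fraction,
#' `r_t` the per-transition response factor, `s` a shared injection-scale
#' factor (cancels in the ratio), and `eps_L`, `eps_R` label-specific
#' lognormal factors whose ratio has CV exactly `tech_cv`. Blanks carry no
#' endogenous light signal beyond bleed-through (spiked control peptides
#' keep their known light amount everywhere). With all CVs and bleed at 0
#' the measured ratio is exactly `f_L / f_H`.
#'
#' @param truth a [generate_truth()] object.
#' @param design a [generate_design()] table.
#' @param pg_per_cell protein mass per cell (pg), default 230.
#' @param seed RNG seed for the noise draws.
#' @return transition-level data.table with the report columns
#'   (`sample_id`, `tech_rep`, `peptide_key`, `precursor_charge`,
#'   `fragment_ion`, `product_charge`, `label`, `area`, `quantitative`).
#' @export
simulate_transitions <- function(truth, design, pg_per_cell = 230, seed = 1L) {
  stopifnot(inherits(truth, "prm_truth"))
  de <- data.table::as.data.table(design)
  set.seed(seed)
  tech_cv <- truth$tech_cv
  bio_cv <- truth$bio_cv
  # per-label sigma such that eps_L/eps_H has CV = tech_cv
  sig_lab <- .lognormal_cv_sigma(tech_cv) / sqrt(2)

  pep <- merge(truth$peptides, truth$proteins, by = "protein")
  bio_ids <- unique(de$bio_rep[!is.na(de$bio_rep)])
  bio_mult <- if (length(bio_ids)) data.table::data.table(
    protein = rep(truth$proteins$protein, each = length(bio_ids)),
    bio_rep = rep(bio_ids, nrow(truth$proteins)),
    bio_factor = .rlnorm_cv(nrow(truth$proteins) * length(bio_ids), bio_cv))
  else data.table::data.table(protein = character(), bio_rep = integer(),
                              bio_factor = numeric())
  bio_mult[protein %in% truth$proteins[is_spike == TRUE, protein],
           bio_factor := 1]

  runs <- de[rep(seq_len(nrow(de)), de$n_tech_reps)]
  runs[, tech_rep := seq_len(.N), by = sample_id]

  grid <- runs[, {
    p <- data.table::copy(pep)
    p[, `:=`(sample_id = sample_id, tech_rep = tech_rep,
             bio_rep = bio_rep, protein_ug = protein_ug,
             heavy_std_fmol = heavy_std_fmol, is_blank = is_blank)]
    p
  }, by = seq_len(nrow(runs))][, seq_len := NULL]
  grid <- merge(grid, bio_mult, by = c("protein", "bio_rep"), all.x = TRUE)
  grid[is.na(bio_factor), bio_factor := 1]

  # endogenous light fmol per injection
  grid[, light_fmol := 0]
  grid[is_spike == TRUE, light_fmol := spike_fmol]
  grid[is_spike == FALSE & is_blank == FALSE & protein_ug > 0,
       light_fmol := .copies_to_fmol(true_copies_per_cell * bio_factor,
                                     protein_ug, pg_per_cell)]
  grid[, heavy_fmol := heavy_std_fmol]

  # label noise factors per (peptide, run)
  n <- nrow(grid)
  if (tech_cv > 0) {
    grid[, eps_light := stats::rlnorm(n, 0, sig_lab)]
    grid[, eps_heavy := stats::rlnorm(n, 0, sig_lab)]
  } else {
    grid[, `:=`(eps_light = 1, eps_heavy = 1)]
  }
  grid[, inj_scale := .rlnorm_cv(n, min(tech_cv, 0.05))]

  tt <- merge(grid, truth$transitions, by = "peptide_key", allow.cartesian = TRUE)
  light <- tt[, .(sample_id, tech_rep, peptide_key, precursor_charge,
                  fragment_ion, product_charge, label = "light",
                  area = (light_fmol * eps_light +
                          bleed_fraction * heavy_fmol) *
                         response_factor * inj_scale)]
  heavy <- tt[, .(sample_id, tech_rep, peptide_key, precursor_charge,
                  fragment_ion, product_charge, label = "heavy",
                  area = heavy_fmol * eps_heavy * response_factor * inj_scale)]
  out <- rbind(light, heavy)
  out[, quantitative := TRUE]
  out[order(sample_id, tech_rep, peptide_key, fragment_ion, label)]
}

#' Simulate an RNA-seq counts table log-linearly tied to protein abundance
#'
#' For each non-spike protein (treated as one gene) log10(TPM) is derived
#' by inverting `log10(copies) = slope * log10(TPM) + intercept +
#' N(0, scatter)`, and the raw TPM values are then renormalized to sum to
#' 1e6 (as real TPM must). The renormalization by `c` shifts the true
#' intercept to `intercept - slope * log10(c)`, which is recorded in the
#' attribute `rna_intercept_effective`; recovery checks must compare
#' against it. Gene effective lengths are drawn uniformly and counts are
#' produced as `TPM * length * K` with `K` set by the library size
#' (rounded to integers by default; set `round_counts = FALSE` for
#' exact-recovery checks).
#'
#' @param truth a [generate_truth()] object.
#' @param rna_slope,rna_intercept generating line, defaults 1.2 and 3.0
#'   (log10 copies/cell per log10 TPM; a moderate mRNA-protein correlation).
#' @param scatter standard deviation of the log10 residual, default 0.3.
#' @param library_size total read count target, default 2e7.
#' @param length_range effective-length range (nt), default `c(500, 5000)`.
#' @param round_counts round counts to integers (default TRUE).
#' @param seed RNG seed.
#' @return data.table `gene`, `count`, `effective_length`, with attributes
#'   `tpm_true` (named vector of renormalized TPM for the target genes),
#'   `rna_slope`, `rna_intercept`, `rna_intercept_effective`.
#' @export
simulate_rnaseq <- function(truth, rna_slope = 1.2, rna_intercept = 3.0,
                            scatter = 0.3, library_size = 2e7,
                            length_range = c(500, 5000),
                            round_counts = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "prm_truth"), scatter >= 0)
  set.seed(seed)
  pr <- truth$proteins[is_spike == FALSE]
  eps <- stats::rnorm(nrow(pr), 0, scatter)
  log_tpm <- (log10(pr$true_copies_per_cell) - rna_intercept - eps) / rna_slope
  tpm <- 10^log_tpm
  scale <- 1e6 / sum(tpm)
  tpm <- tpm * scale
  eff_intercept <- rna_intercept - rna_slope * log10(scale)
  len <- stats::runif(nrow(pr), length_range[1], length_range[2])
  k <- library_size / sum(tpm * len)
  counts <- tpm * len * k
  if (round_counts) counts <- round(counts)
  out <- data.table::data.table(gene = pr$protein, count = counts,
                                effective_length = len)
  data.table::setattr(out, "tpm_true", stats::setNames(tpm, pr$protein))
  data.table::setattr(out, "rna_slope", rna_slope)
  data.table::setattr(out, "rna_intercept", rna_intercept)
  data.table::setattr(out, "rna_intercept_effective", eff_intercept)
  out[]
}

#' Solve the standards mass model from blank totals
#'
#' Blanks contain only the luciferase spike and the heavy peptide standards,
#' so their total injected mass obeys `total = L + level * p` with `L` the
#' luciferase mass (µg) and `p` the mass of 1 fmol of each standard (µg).
#' Solved by least squares (exact with two distinct levels).
#'
#' @param blank_totals two-column object (`fmol_level`, `total_ug`) with at
#'   least two distinct nonzero levels.
#' @return object of class `standards_mass_model`: list with
#'   `luciferase_mass_ug` and `per_fmol_each_mass_ug`.
#' @examples
#' infer_standards_masses(data.frame(fmol_level = c(10, 100),
#'                                   total_ug = c(0.005598, 0.048189)))
#' @export
infer_standards_masses <- function(blank_totals) {
  bt <- as.data.frame(blank_totals)
  names(bt)[1:2] <- c("fmol_level", "total_ug")
  bt <- bt[bt$fmol_level > 0, , drop = FALSE]
  if (length(unique(bt$fmol_level)) < 2L)
    stop("need blank totals at >=2 distinct nonzero fmol levels")
  fit <- stats::lm(total_ug ~ fmol_level, data = bt)
  structure(list(luciferase_mass_ug = unname(coef(fit)[1]),
                 per_fmol_each_mass_ug = unname(coef(fit)[2])),
            class = "standards_mass_model")
}

#' @export
print.standards_mass_model <- function(x, ...) {
  cat(sprintf("Standards mass model: total = %.6f + level * %.6f ug/injection\n",
              x$luciferase_mass_ug, x$per_fmol_each_mass_ug))
  invisible(x)
}

#' Predict the total injected mass of a sample
#'
#' `protein_ug + L + heavy_std_fmol * p` per injection.
#'
#' @param spec one design row (or a table) with `protein_ug` and
#'   `heavy_std_fmol`.
#' @param model a [infer_standards_masses()] model.
#' @return total µg per injection (vectorized over rows of `spec`).
#' @export
predict_total_mass <- function(spec, model) {
  stopifnot(inherits(model, "standards_mass_model"))
  spec <- as.data.frame(spec)
  spec$protein_ug + model$luciferase_mass_ug +
    spec$heavy_std_fmol * model$per_fmol_each_mass_ug
}
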