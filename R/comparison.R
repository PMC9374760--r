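# Cross-dataset comparison of two absolute-quantitation datasets: per-protein
# copies/cell ratios on the shared proteins, their geometric mean, and the
# consistency check against the measured protein-mass-per-cell ratio.

#' Per-protein abundance ratios between two datasets
#'
#' @param dataset_a,dataset_b named positive vectors of copies/cell keyed
#'   by protein accession.
#' @return list: `ratios` (named A/B ratios on the shared accessions),
#'   `only_a`, `only_b` (accessions not shared).
#' @export
per_protein_ratios <- function(dataset_a, dataset_b) {
  stopifnot(!is.null(names(dataset_a)), !is.null(names(dataset_b)))
  shared <- intersect(names(dataset_a), names(dataset_b))
  if (length(shared) == 0L) stop("no proteins shared between the datasets")
  a <- dataset_a[shared]; b <- dataset_b[shared]
  if (any(a <= 0) || any(b <= 0)) stop("abundances must be positive")
  list(ratios = a / b,
       only_a = setdiff(names(dataset_a), shared),
       only_b = setdiff(names(dataset_b), shared))
}

#' Summarize a two-dataset comparison
#'
#' Reports the geometric mean of the per-protein A/B ratios, the
#' protein-mass-per-cell ratio (the orthogonal bulk measurement the
#' abundance ratio should track), the log10-log10 Pearson correlation of
#' the shared abundances, and the agreement metric
#' `|log(gm_ratio / mass_ratio)|`.
#'
#' @param dataset_a,dataset_b named copies/cell vectors.
#' @param mass_a_pg,mass_b_pg protein mass per cell (pg) of the two cell
#'   types (e.g. 230 for BMDM, 136 for RAW264.7).
#' @return list of class `dataset_comparison`: `ratios`,
#'   `geometric_mean_ratio`, `mass_ratio`, `log_agreement`, `r_loglog`,
#'   `n_shared`, `only_a`, `only_b`.
#' @export
summarize_comparison <- function(dataset_a, dataset_b, mass_a_pg, mass_b_pg) {
  stopifnot(mass_a_pg > 0, mass_b_pg > 0)
  pr <- per_protein_ratios(dataset_a, dataset_b)
  shared <- names(pr$ratios)
  gm <- geometric_mean(pr$ratios)
  mass_ratio <- mass_a_pg / mass_b_pg
  r <- if (length(shared) >= 3L)
    stats::cor(log10(dataset_a[shared]), log10(dataset_b[shared]))
  else NA_real_
  structure(list(ratios = pr$ratios,
                 geometric_mean_ratio = gm,
                 mass_ratio = mass_ratio,
                 log_agreement = abs(log(gm / mass_ratio)),
                 r_loglog = r,
                 n_shared = length(shared),
                 only_a = pr$only_a, only_b = pr$only_b),
            class = "dataset_comparison")
}

#' @export
print.dataset_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Dataset comparison over %d shared proteins:\n",
           "  geometric-mean abundance ratio A/B: %.2f\n",
           "  protein-mass ratio A/B:             %.2f\n",
           "  log-log Pearson r:                  %.3f\n"),
    x$n_shared, x$geometric_mean_ratio, x$mass_ratio, x$r_loglog))
  invisible(x)
}
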