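# Proteome-wide abundance estimation: TPM from counts, the log10-log10
# regression of protein copies/cell on transcript TPM, proteome-wide
# prediction, and symmetric fold-error summaries.

#' Transcripts per million from counts and effective lengths
#'
#' `rate_g = count_g / length_g`; `TPM_g = 1e6 * rate_g / sum(rate)`.
#' TPM values sum to 1e6 by construction.
#'
#' @param counts non-negative read counts.
#' @param effective_lengths positive effective lengths.
#' @return TPM vector (same order, names preserved).
#' @export
compute_tpm <- function(counts, effective_lengths) {
  stopifnot(length(counts) == length(effective_lengths))
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  rate <- counts / effective_lengths
  total <- sum(rate)
  if (total == 0) stop("all counts are zero; TPM undefined")
  1e6 * rate / total
}

#' Fit the log10-log10 protein-vs-transcript regression
#'
#' Ordinary least squares of `log10(copies/cell)` on `log10(TPM)` over
#' genes with both values positive (zeros are excluded and counted).
#'
#' @param tpm_measured TPM values of the measured genes.
#' @param copies_measured matched protein copies/cell.
#' @return object of class `loglog_model`: `slope`, `intercept`, `r`,
#'   `r_squared`, `n_points`, `n_excluded`, and the underlying `lm` fit.
#' @export
fit_loglog <- function(tpm_measured, copies_measured) {
  stopifnot(length(tpm_measured) == length(copies_measured))
  ok <- is.finite(tpm_measured) & is.finite(copies_measured) &
    tpm_measured > 0 & copies_measured > 0
  n_excluded <- sum(!ok)
  x <- log10(tpm_measured[ok])
  y <- log10(copies_measured[ok])
  if (length(x) < 3L) stop("need >=3 positive paired values to fit")
  if (stats::sd(x) == 0) stop("zero variance in log10(TPM)")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, r_squared = r^2,
                 n_points = length(x), n_excluded = n_excluded,
                 fit = fit),
            class = "loglog_model")
}

#' @export
print.loglog_model <- function(x, ...) {
  cat(sprintf(
    "log10(copies/cell) = %.4f * log10(TPM) + %.4f  (r = %.4f, R2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict proteome-wide copies/cell from TPM
#'
#' `copies = 10^(slope * log10(TPM) + intercept)` for every gene with
#' TPM > 0; genes with TPM = 0 are emitted with `NA` (not estimable).
#'
#' @param tpm_all named TPM vector for the whole transcriptome.
#' @param model a [fit_loglog()] model.
#' @return data.table: `gene`, `tpm`, `estimated_copies_per_cell`,
#'   `estimable`.
#' @export
predict_proteome <- function(tpm_all, model) {
  stopifnot(inherits(model, "loglog_model"))
  genes <- names(tpm_all) %||% as.character(seq_along(tpm_all))
  est <- ifelse(tpm_all > 0,
                10^(model$slope * log10(pmax(tpm_all, .Machine$double.xmin)) +
                      model$intercept),
                NA_real_)
  data.table::data.table(gene = genes, tpm = as.numeric(tpm_all),
                         estimated_copies_per_cell = as.numeric(est),
                         estimable = tpm_all > 0)
}

#' Symmetric fold-error summary of modeled vs measured abundances
#'
#' For each pair a ratio `modeled/measured` is formed; ratios below 1 are
#' replaced by their reciprocal, so every stored ratio is >= 1. The mean,
#' geometric mean and median of these ratios summarize the estimation
#' error.
#'
#' @param modeled,measured positive paired abundance vectors.
#' @return list of class `fold_error_summary`: `ratios`, `mean`,
#'   `geometric_mean`, `median`, `n`.
#' @export
fold_error_summary <- function(modeled, measured) {
  stopifnot(length(modeled) == length(measured))
  if (any(!is.finite(modeled)) || any(!is.finite(measured)) ||
      any(modeled <= 0) || any(measured <= 0))
    stop("fold_error_summary requires positive finite pairs")
  ratios <- pmax(modeled / measured, measured / modeled)
  structure(list(ratios = ratios, mean = mean(ratios),
                 geometric_mean = geometric_mean(ratios),
                 median = stats::median(ratios), n = length(ratios)),
            class = "fold_error_summary")
}

#' @export
print.fold_error_summary <- function(x, ...) {
  cat(sprintf(
    "Fold errors over %d pairs: mean %.2f, geometric mean %.2f, median %.2f\n",
    x$n, x$mean, x$geometric_mean, x$median))
  invisible(x)
}

#' Estimate the whole proteome from a counts table and measured proteins
#'
#' Convenience driver: TPM from the counts table, [fit_loglog()] on the
#' genes with measured copies/cell, [predict_proteome()] for every gene,
#' and a [fold_error_summary()] over the measured genes.
#'
#' @param counts_table data.frame with `gene`, `count`, `effective_length`.
#' @param measured named vector of measured copies/cell (names are genes).
#' @return list: `model`, `estimates` (data.table with measured values and
#'   fold errors joined), `fold_errors`.
#' @export
estimate_proteome <- function(counts_table, measured) {
  ct <- data.table::as.data.table(counts_table)
  tpm <- compute_tpm(ct$count, ct$effective_length)
  names(tpm) <- ct$gene
  shared <- intersect(names(tpm), names(measured))
  if (length(shared) < 3L) stop("fewer than 3 genes shared between counts and measurements")
  model <- fit_loglog(tpm[shared], measured[shared])
  est <- predict_proteome(tpm, model)
  est[, measured_copies_per_cell := measured[gene]]
  est[, fold_error := ifelse(
    !is.na(measured_copies_per_cell) & estimable,
    pmax(estimated_copies_per_cell / measured_copies_per_cell,
         measured_copies_per_cell / estimated_copies_per_cell), NA_real_)]
  ok <- est[!is.na(fold_error)]
  fe <- fold_error_summary(ok$estimated_copies_per_cell,
                           ok$measured_copies_per_cell)
  list(model = model, estimates = est, fold_errors = fe)
}
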