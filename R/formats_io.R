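# External tables: Skyline-style transition report CSV (remappable column
# names), sample design TSV, RNA-seq counts TSV (+ optional gene-symbol
# mapping), protein FASTA, and result writers. No science in this file.

#' Default column mapping for the transition report CSV
#'
#' Keys are internal names; values are the column headers expected in the
#' file (Skyline report vocabulary). Override any entry through the
#' `dialect` argument of [read_transition_report()].
#' @return named character vector.
#' @export
default_transition_dialect <- function() {
  c(sample_id = "Replicate Name",
    tech_rep = "Technical Replicate",
    peptide_key = "Peptide Modified Sequence",
    precursor_charge = "Precursor Charge",
    fragment_ion = "Fragment Ion",
    product_charge = "Product Charge",
    label = "Isotope Label Type",
    area = "Area",
    quantitative = "Quantitative")
}

#' Read a transition-level peak-area report
#'
#' Parses a Skyline-style CSV export into the internal transition table.
#' Labels are case-folded to `light`/`heavy`; rows with negative area or
#' unknown label are rejected with a line-numbered warning (never silently
#' dropped: rows in = rows parsed + rows rejected). A missing mapped
#' column is a fatal configuration error. A missing `Technical Replicate`
#' or `Quantitative` column gets defaults (1 / TRUE) since Skyline reports
#' do not always carry them.
#'
#' @param path CSV file.
#' @param dialect named character vector overriding entries of
#'   [default_transition_dialect()].
#' @return transition data.table (`sample_id`, `tech_rep`, `peptide_key`,
#'   `precursor_charge`, `fragment_ion`, `product_charge`, `label`,
#'   `area`, `quantitative`).
#' @export
read_transition_report <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- default_transition_dialect()
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- data.table::fread(path, sep = ",", header = TRUE)
  optional <- c("tech_rep", "quantitative")
  need <- map[setdiff(names(map), optional)]
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols))
    stop("transition report is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- data.table::data.table(
    sample_id = as.character(raw[[map[["sample_id"]]]]),
    tech_rep = if (map[["tech_rep"]] %in% names(raw))
      as.integer(raw[[map[["tech_rep"]]]]) else 1L,
    peptide_key = as.character(raw[[map[["peptide_key"]]]]),
    precursor_charge = as.integer(raw[[map[["precursor_charge"]]]]),
    fragment_ion = as.character(raw[[map[["fragment_ion"]]]]),
    product_charge = as.integer(raw[[map[["product_charge"]]]]),
    label = tolower(trimws(as.character(raw[[map[["label"]]]]))),
    area = as.numeric(raw[[map[["area"]]]]),
    quantitative = if (map[["quantitative"]] %in% names(raw))
      as.logical(raw[[map[["quantitative"]]]]) else TRUE)
  bad_label <- !dt$label %in% c("light", "heavy")
  bad_area <- !is.na(dt$area) & dt$area < 0
  bad <- bad_label | bad_area | is.na(dt$area)
  if (any(bad)) {
    lines <- which(bad) + 1L # header line
    warning(sum(bad), " row(s) rejected (bad label/negative or missing area) ",
            "at file line(s): ",
            paste(utils::head(lines, 10L), collapse = ", "),
            if (sum(bad) > 10L) " ..." else "")
    dt <- dt[!bad]
  }
  if (anyDuplicated(dt[, .(sample_id, tech_rep, peptide_key, precursor_charge,
                           fragment_ion, product_charge, label)]))
    stop("duplicate transition rows within the report")
  dt[]
}

#' Write a transition table back to CSV
#'
#' Inverse of [read_transition_report()]: round-trips all fields.
#' @param transitions transition data.table.
#' @param path output CSV.
#' @param dialect column-name mapping, as in [read_transition_report()].
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(transitions, path, dialect = NULL) {
  map <- default_transition_dialect()
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  out <- data.table::as.data.table(transitions)[, .(
    sample_id, tech_rep, peptide_key, precursor_charge, fragment_ion,
    product_charge, label, area, quantitative)]
  data.table::setnames(out, unname(map[names(out)]))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read the sample design table
#'
#' TSV with columns `sample_id`, `bio_rep`, `protein_ug`,
#' `luciferase_fmol`, `heavy_std_fmol`, `n_tech_reps`. `is_blank` is
#' derived from `protein_ug == 0`; `bio_rep` may be empty/`-` for blanks.
#'
#' @param path TSV file.
#' @return design data.table.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("", "-", "NA"))
  need <- c("sample_id", "bio_rep", "protein_ug", "luciferase_fmol",
            "heavy_std_fmol", "n_tech_reps")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id in design table: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  if (any(raw$protein_ug < 0) || any(raw$heavy_std_fmol < 0) ||
      any(raw$luciferase_fmol < 0))
    stop("negative masses in design table")
  dt <- data.table::data.table(
    sample_id = as.character(raw$sample_id),
    bio_rep = suppressWarnings(as.integer(raw$bio_rep)),
    protein_ug = as.numeric(raw$protein_ug),
    luciferase_fmol = as.numeric(raw$luciferase_fmol),
    heavy_std_fmol = as.numeric(raw$heavy_std_fmol),
    n_tech_reps = as.integer(raw$n_tech_reps))
  dt[, is_blank := protein_ug == 0]
  dt[]
}

#' Write a design table
#' @param design design data.table.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  out <- data.table::as.data.table(design)[, .(
    sample_id, bio_rep, protein_ug, luciferase_fmol, heavy_std_fmol,
    n_tech_reps)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a gene-level RNA-seq counts table
#'
#' TSV with columns `gene`, `count`, `effective_length`. Rows with
#' non-positive length or negative count are rejected with a warning. An
#' optional two-column mapping table (`old`, `new`) renames gene symbols;
#' counts of genes mapped onto an existing symbol are summed (the
#' effective length of the target symbol is kept) and each merge is
#' reported.
#'
#' @param path TSV file.
#' @param mapping optional data.frame with columns `old`, `new`.
#' @return data.table `gene`, `count`, `effective_length`.
#' @export
read_counts_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene", "count", "effective_length")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("counts table is missing column(s): ", paste(miss, collapse = ", "))
  dt <- raw[, .(gene = as.character(gene), count = as.numeric(count),
                effective_length = as.numeric(effective_length))]
  bad <- dt$effective_length <= 0 | dt$count < 0 | is.na(dt$count)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (non-positive length or bad count): ",
            paste(utils::head(dt$gene[bad], 10L), collapse = ", "))
    dt <- dt[!bad]
  }
  if (!is.null(mapping)) {
    mp <- data.table::as.data.table(mapping)
    stopifnot(all(c("old", "new") %in% names(mp)))
    hit <- dt$gene %in% mp$old
    if (any(hit)) {
      renames <- mp[data.table::data.table(old = dt$gene[hit]), on = "old"]
      message("gene symbols updated: ",
              paste(sprintf("%s->%s", renames$old, renames$new), collapse = ", "))
      dt[hit, gene := renames$new]
    }
  }
  if (anyDuplicated(dt$gene)) {
    dt <- dt[, .(count = sum(count),
                 effective_length = effective_length[1L]), by = gene]
  }
  dt[]
}

#' Read a protein FASTA
#'
#' Uses `Biostrings::readAAStringSet()` when available, otherwise a
#' minimal internal reader. Accessions are the first whitespace-delimited
#' token of each header (UniProt `db|ACC|NAME` headers are reduced to
#' `ACC`).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    headers <- names(aa)
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    if (length(idx) == 0L) stop("not a FASTA file: ", path)
    headers <- sub("^>", "", lines[idx])
    ends <- c(idx[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(idx), function(i) {
      paste(lines[(idx[i] + 1L):ends[i]], collapse = "")
    }, character(1))
  }
  acc <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  piped <- grepl("^[a-z]+\\|[^|]+\\|", acc)
  acc[piped] <- vapply(strsplit(acc[piped], "\\|"), `[[`, character(1), 2L)
  stats::setNames(toupper(seqs), acc)
}

#' Write a simple run log header into an output directory
#' @param dir output directory.
#' @param seed RNG seed used.
#' @param params named list of parameters to record.
#' @return path of the log file, invisibly.
#' @keywords internal
.write_run_log <- function(dir, seed, params = list()) {
  lines <- c(sprintf("prmquant %s", as.character(utils::packageVersion("prmquant"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("seed: %d", seed),
             sprintf("%s: %s", names(params),
                     vapply(params, function(p) paste(format(p), collapse = ","),
                            character(1))))
  p <- file.path(dir, "run_log.txt")
  writeLines(lines, p)
  invisible(p)
}
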