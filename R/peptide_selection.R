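# In-silico selection of proteotypic/quantotypic target peptides: tryptic
# digestion (Keil rule), rule-based criterion evaluation with hard and soft
# fails, an I/L-collapsed uniqueness index, and deterministic ranking.

#' Strip bracketed modification annotations from a peptide key
#'
#' Modified sequences use bracketed tokens after the modified residue,
#' e.g. `"M[Ox]"`, `"C[Carbam]"`, `"S[Pho]"`. Stripping every bracketed
#' token yields the base sequence.
#'
#' @param peptide_key character vector of modified-sequence keys.
#' @return base sequences.
#' @examples
#' strip_modifications("TM[Ox]DAGC[Carbam]KPYM[Ox]APER")
#' @export
strip_modifications <- function(peptide_key) {
  gsub("\\[[^]]*\\]", "", peptide_key)
}

#' Fully tryptic in-silico digestion (Keil rule)
#'
#' Cleaves after K or R except when the next residue is P. Peptides tile
#' the parent sequence exactly. Internal KP/RP sites (which trypsin may
#' digest slowly) do not cleave, so peptides containing them are produced
#' and flagged.
#'
#' @param sequence one protein sequence (standard residues; others are
#'   flagged via `nonstandard`).
#' @param missed_cleavages maximum missed cleavages to enumerate
#'   (default 0; candidates must be fully tryptic with none).
#' @return data.table: `sequence`, `start`, `end` (0-based half-open),
#'   `prev_aa`, `next_aa` (`"-"` at termini), `missed_cleavages`,
#'   `internal_kp_rp`, `nonstandard`.
#' @examples
#' digest_tryptic("MKAAARLK")$sequence # "MK" "AAAR" "LK"
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0L) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  # cleavage after position i when aa[i] in {K,R} and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n else NULL)
  bounds <- unique(bounds)
  starts0 <- head(bounds, -1L)
  ends0 <- tail(bounds, -1L)
  pieces <- data.table::data.table(start = starts0, end = ends0)

  out <- list()
  for (mc in 0:missed_cleavages) {
    k <- nrow(pieces) - mc
    if (k < 1L) break
    s <- pieces$start[seq_len(k)]
    e <- pieces$end[seq_len(k) + mc]
    out[[mc + 1L]] <- data.table::data.table(start = s, end = e,
                                             missed_cleavages = mc)
  }
  dt <- data.table::rbindlist(out)
  dt[, sequence := substring(sequence, start + 1L, end)]
  dt[, prev_aa := ifelse(start == 0L, "-", aa[start])]
  dt[, next_aa := ifelse(end == n, "-", aa[pmin(end + 1L, n)])]
  dt[, internal_kp_rp := grepl("[KR]P", sequence)]
  dt[, nonstandard := grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)]
  data.table::setcolorder(dt, c("sequence", "start", "end", "prev_aa",
                                "next_aa", "missed_cleavages"))
  dt[]
}

#' Build an I/L-collapsed peptide uniqueness index over a proteome
#'
#' Isoleucine and leucine are isobaric and behave nearly identically in
#' LC-MS(/MS), so uniqueness is assessed on I/L-collapsed sequences. The
#' index maps each collapsed tryptic peptide (up to `missed_cleavages`) to
#' the set of parent accessions.
#'
#' @param proteome named character vector of protein sequences
#'   (names are accessions), e.g. from [read_fasta()].
#' @param homologue_groups optional list of character vectors of accessions
#'   considered one quantifiable group.
#' @param missed_cleavages enumerate up to this many missed cleavages so
#'   that shared subsequences across digestion registers are caught
#'   (default 2).
#' @return object of class `uniqueness_index` (environment-backed list).
#' @export
build_uniqueness_index <- function(proteome, homologue_groups = list(),
                                   missed_cleavages = 2L) {
  stopifnot(!is.null(names(proteome)), all(nzchar(names(proteome))))
  idx <- new.env(parent = emptyenv())
  for (acc in names(proteome)) {
    peps <- digest_tryptic(proteome[[acc]], missed_cleavages)$sequence
    keys <- unique(chartr("I", "L", peps))
    for (k in keys) assign(k, unique(c(idx[[k]], acc)), envir = idx)
  }
  structure(list(index = idx, homologue_groups = homologue_groups,
                 accessions = names(proteome)),
            class = "uniqueness_index")
}

#' Look up the uniqueness status of a peptide
#'
#' @param index a [build_uniqueness_index()] object.
#' @param peptide peptide sequence (modifications are stripped, I/L
#'   collapsed before lookup).
#' @return list: `status` one of `"unique"`, `"homologue_shared"`,
#'   `"non_unique"`, `"absent"`; `accessions` the parents found.
#' @export
lookup_uniqueness <- function(index, peptide) {
  stopifnot(inherits(index, "uniqueness_index"))
  key <- chartr("I", "L", strip_modifications(peptide))
  acc <- index$index[[key]]
  if (is.null(acc)) return(list(status = "absent", accessions = character()))
  if (length(acc) == 1L) return(list(status = "unique", accessions = acc))
  for (grp in index$homologue_groups) {
    if (all(acc %in% grp))
      return(list(status = "homologue_shared", accessions = acc))
  }
  list(status = "non_unique", accessions = acc)
}

#' Default soft-criterion weights for the candidate score
#'
#' One unit per soft-failed criterion; fully configurable.
#' @return named numeric vector.
#' @export
default_criterion_weights <- function() {
  c(c2_neighboring_sites = 1, c3_multi_copy = 1, c4_length = 1,
    c5_residues_ptm = 1, c6_variant = 1, c7_ortholog = 1,
    c9_isoform = 1, c10_proteotypic = 1)
}

#' Evaluate the target-peptide selection criteria for one digest peptide
#'
#' Hard criteria (any hard fail disqualifies the candidate):
#' * fully tryptic with no missed cleavages and no internal KP/RP site
#'   (internal KP/RP changes cleavage semantics), and
#' * uniqueness to the target protein (I/L-collapsed), with peptides shared
#'   only within a declared homologue group allowed.
#'
#' Soft criteria (each failure adds its weight to the score):
#' neighboring cleavage sites; more than one copy per protein copy
#' (I/L-collapsed); length outside 5-20; oxidation/deamidation-prone
#' residues (C, M, N, Q), N-terminal Gln, protein termini, or an annotated
#' PTM overlap; annotated variant overlap; ortholog incompatibility;
#' poor isoform coverage; weak proteotypic evidence (supplied evidence
#' score, not computed).
#'
#' @param p one row from [digest_tryptic()] (list or single-row data.frame).
#' @param parent_sequence the parent protein sequence.
#' @param index optional [build_uniqueness_index()]; without it uniqueness
#'   passes (single-protein mode).
#' @param annotations optional list with numeric position vectors
#'   `ptm_sites`, `variant_sites` (1-based, in parent coordinates) and
#'   logicals `ortholog_ok`, `isoform_ok`, `evidence_ok` (peptide-level;
#'   missing entries pass).
#' @param weights named weights, see [default_criterion_weights()].
#' @return list of class `filter_report`: `peptide`, `criterion_flags`
#'   (named character: `pass`/`soft_fail`/`hard_fail`), `hard_pass`,
#'   `score`.
#' @export
evaluate_criteria <- function(p, parent_sequence, index = NULL,
                              annotations = list(),
                              weights = default_criterion_weights()) {
  p <- as.list(as.data.frame(p))
  seqn <- p$sequence
  len <- nchar(seqn)
  flags <- c(c1_tryptic = "pass", c2_neighboring_sites = "pass",
             c3_multi_copy = "pass", c4_length = "pass",
             c5_residues_ptm = "pass", c6_variant = "pass",
             c7_ortholog = "pass", c8_unique = "pass",
             c9_isoform = "pass", c10_proteotypic = "pass")

  if (p$missed_cleavages > 0L || isTRUE(p$internal_kp_rp))
    flags["c1_tryptic"] <- "hard_fail"

  # neighboring cleavage sites (e.g. AAK.R.AA): ragged ends digest slowly
  if ((substr(seqn, 1L, 1L) %in% c("K", "R") && p$prev_aa %in% c("K", "R")) ||
      p$next_aa %in% c("K", "R"))
    flags["c2_neighboring_sites"] <- "soft_fail"

  # exactly one copy per protein copy, I/L-collapsed
  collapsed_parent <- chartr("I", "L", parent_sequence)
  collapsed_pep <- chartr("I", "L", seqn)
  n_copies <- length(gregexpr(collapsed_pep, collapsed_parent,
                              fixed = TRUE)[[1]])
  if (n_copies > 1L) flags["c3_multi_copy"] <- "soft_fail"

  if (len < 5L || len > 20L) flags["c4_length"] <- "soft_fail"

  # modification-prone residues, termini, annotated PTMs
  ptm_prone <- grepl("[CMNQ]", seqn) || startsWith(seqn, "Q")
  at_terminus <- p$start == 0L || p$next_aa == "-"
  ptm_overlap <- length(annotations$ptm_sites) &&
    any(annotations$ptm_sites >= p$start + 1L &
        annotations$ptm_sites <= p$end + 1L) # +1: flanking trypsin sites too
  if (ptm_prone || at_terminus || isTRUE(ptm_overlap))
    flags["c5_residues_ptm"] <- "soft_fail"

  if (length(annotations$variant_sites) &&
      any(annotations$variant_sites >= p$start &
          annotations$variant_sites <= p$end + 1L))
    flags["c6_variant"] <- "soft_fail"

  if (isFALSE(annotations$ortholog_ok)) flags["c7_ortholog"] <- "soft_fail"

  if (!is.null(index)) {
    u <- lookup_uniqueness(index, seqn)
    if (u$status == "non_unique") flags["c8_unique"] <- "hard_fail"
  }

  if (isFALSE(annotations$isoform_ok)) flags["c9_isoform"] <- "soft_fail"
  if (isFALSE(annotations$evidence_ok))
    flags["c10_proteotypic"] <- "soft_fail"

  soft <- names(flags)[flags == "soft_fail"]
  score <- sum(weights[soft], na.rm = TRUE)
  structure(list(peptide = p, criterion_flags = flags,
                 hard_pass = !any(flags == "hard_fail"),
                 score = unname(score)),
            class = "filter_report")
}

#' Rank candidate peptides deterministically
#'
#' Hard-pass candidates first, then ascending score; ties broken by length
#' closest to the midpoint of the preferred 5-20 range (12.5), then
#' lexicographically by sequence. Permuting the input never changes the
#' output order.
#'
#' @param reports list of [evaluate_criteria()] reports.
#' @return data.table: `sequence`, `hard_pass`, `score`, `rank`.
#' @export
rank_candidates <- function(reports) {
  if (length(reports) == 0L)
    return(data.table::data.table(sequence = character(),
                                  hard_pass = logical(), score = numeric(),
                                  rank = integer()))
  dt <- data.table::rbindlist(lapply(reports, function(r) {
    data.table::data.table(sequence = r$peptide$sequence,
                           hard_pass = r$hard_pass, score = r$score,
                           len_dev = abs(nchar(r$peptide$sequence) - 12.5))
  }))
  data.table::setorder(dt, -hard_pass, score, len_dev, sequence)
  dt[, rank := .I]
  dt[, len_dev := NULL]
  dt[]
}

#' Select target peptides for every protein in a FASTA
#'
#' Digest, evaluate, and rank candidates per protein against an
#' I/L-collapsed uniqueness index over the whole input proteome.
#'
#' @param proteome named character vector of sequences.
#' @param n_per_protein candidates to keep per protein, default 2.
#' @param annotations optional per-accession list of annotation lists.
#' @param weights soft-criterion weights.
#' @param homologue_groups see [build_uniqueness_index()].
#' @return data.table: `protein`, `sequence`, `hard_pass`, `score`,
#'   `rank`, `selected`.
#' @export
select_peptides <- function(proteome, n_per_protein = 2L,
                            annotations = list(),
                            weights = default_criterion_weights(),
                            homologue_groups = list()) {
  index <- build_uniqueness_index(proteome, homologue_groups)
  res <- lapply(names(proteome), function(acc) {
    dig <- digest_tryptic(proteome[[acc]])
    dig <- dig[nonstandard == FALSE]
    if (nrow(dig) == 0L) return(NULL)
    reports <- lapply(seq_len(nrow(dig)), function(i)
      evaluate_criteria(dig[i], proteome[[acc]], index,
                        annotations[[acc]] %||% list(), weights))
    ranked <- rank_candidates(reports)
    ranked[, protein := acc]
    ranked
  })
  out <- data.table::rbindlist(res)
  out[, selected := hard_pass & rank <= n_per_protein]
  data.table::setcolorder(out, "protein")
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
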