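# Domain types and file I/O: interaction tables (binary or Kd TSV), FASTA
# sequence sets, and the bundled Scrib PDZ validation panel.

#' Window width for a peptide window kind
#'
#' PDZ models consider the five C-terminal residues of a ligand (positions
#' P-4..P0); SH2 models consider the six residues flanking the fixed
#' phosphotyrosine (pY-2, pY-1, pY+1..pY+4 -- the pY itself carries no
#' information and is excluded).
#'
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @return Integer window width (5 or 6).
#' @export
window_width <- function(window_kind) {
  switch(match.arg(window_kind, c("PDZ_CTERM", "SH2_PY")),
         PDZ_CTERM = 5L, SH2_PY = 6L)
}

#' Family of a window kind
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @return `"PDZ"` or `"SH2"`.
#' @export
window_family <- function(window_kind) {
  switch(match.arg(window_kind, c("PDZ_CTERM", "SH2_PY")),
         PDZ_CTERM = "PDZ", SH2_PY = "SH2")
}

#' Window kind used by a domain family
#' @param family `"PDZ"` or `"SH2"`.
#' @return `"PDZ_CTERM"` or `"SH2_PY"`.
#' @export
family_window_kind <- function(family) {
  switch(match.arg(family, c("PDZ", "SH2")),
         PDZ = "PDZ_CTERM", SH2 = "SH2_PY")
}

.check_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("AlphabetError: non-amino-acid characters in ", what, ": ",
         paste(head(seqs[bad], 3), collapse = ", "), call. = FALSE)
  invisible(seqs)
}

#' Reduce a peptide sequence to its model window
#'
#' Peptides longer than the window (e.g. the 10-mers of the Scrib panel) are
#' truncated on ingestion: PDZ keeps the C-terminal 5 residues; SH2 sequences
#' must already be the 6-residue pY-context. The full string is retained by
#' callers for display.
#'
#' @param sequence Amino-acid string (uppercase).
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @return The window-length sequence.
#' @export
peptide_window <- function(sequence, window_kind) {
  w <- window_width(window_kind)
  sequence <- toupper(sequence)
  .check_alphabet(sequence, "peptide")
  n <- nchar(sequence)
  if (any(n < w))
    stop("WindowMismatch: peptide shorter than the ", w, "-residue window",
         call. = FALSE)
  if (window_kind == "SH2_PY" && any(n != w))
    stop("WindowMismatch: SH2 pY-context peptides must have exactly ",
         w, " residues", call. = FALSE)
  substr(sequence, n - w + 1L, n)
}

#' Classify a dissociation constant as bound or unbound
#'
#' A Kd at or below the cutoff classifies as `"BOUND"` (the boundary itself
#' counts as binding), above as `"UNBOUND"`; `NA` stays `"UNTESTED"`.
#'
#' @param kd Numeric Kd values in micromolar; `NA` for untested.
#' @param cutoff_uM Positive cutoff, default 100.
#' @return Character vector of outcomes.
#' @export
classify_kd <- function(kd, cutoff_uM = 100) {
  stopifnot(is.numeric(kd), cutoff_uM > 0)
  if (any(!is.na(kd) & kd <= 0))
    stop("ParseError: Kd values must be positive", call. = FALSE)
  ifelse(is.na(kd), "UNTESTED", ifelse(kd <= cutoff_uM, "BOUND", "UNBOUND"))
}

#' Construct an interaction table
#'
#' The substrate of every specificity metric: a domains x peptides matrix of
#' binding outcomes. Untested cells are first-class -- array panels differ per
#' domain, and imputing them as unbound would corrupt LBS denominators.
#'
#' @param peptides Data frame with columns `sequence` (full peptide string)
#'   and optionally `source_protein`, `position`.
#' @param outcomes Character matrix, `nrow(peptides)` x number of domains,
#'   entries in `BOUND`, `UNBOUND`, `UNTESTED`; column names are domain ids.
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param kd Optional numeric matrix of Kd values (uM) shaped like `outcomes`.
#' @param kd_cutoff_uM Cutoff used to derive outcomes from `kd`, default 100.
#' @return An object of class `interaction_table` with fields `domains`,
#'   `peptides` (with a derived `window` column), `outcomes`, `kd`,
#'   `kd_cutoff_uM`, `window_kind`.
#' @export
interaction_table <- function(peptides, outcomes, window_kind,
                              kd = NULL, kd_cutoff_uM = 100) {
  window_kind <- match.arg(window_kind, c("PDZ_CTERM", "SH2_PY"))
  peptides <- as.data.frame(peptides)
  stopifnot("sequence" %in% names(peptides))
  outcomes <- as.matrix(outcomes)
  if (nrow(outcomes) != nrow(peptides))
    stop("ParseError: outcomes rows must match peptides", call. = FALSE)
  if (is.null(colnames(outcomes)))
    stop("ParseError: outcomes must carry domain ids as column names",
         call. = FALSE)
  if (anyDuplicated(colnames(outcomes)))
    stop("ParseError: duplicate domain ids", call. = FALSE)
  bad <- !outcomes %in% c("BOUND", "UNBOUND", "UNTESTED")
  if (any(bad))
    stop("ParseError: invalid outcome values: ",
         paste(unique(outcomes[bad]), collapse = ", "), call. = FALSE)
  peptides$window <- peptide_window(peptides$sequence, window_kind)
  x <- structure(
    list(domains = colnames(outcomes), peptides = peptides,
         outcomes = outcomes, kd = kd, kd_cutoff_uM = kd_cutoff_uM,
         window_kind = window_kind),
    class = "interaction_table")
  .dompep_log("interaction table: %d domains, %d peptides, %d positives",
              length(x$domains), nrow(peptides), sum(outcomes == "BOUND"))
  x
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf(
    "interaction_table: %d domains x %d peptides (%s), %d BOUND / %d UNBOUND / %d UNTESTED\n",
    length(x$domains), nrow(x$peptides), x$window_kind,
    sum(x$outcomes == "BOUND"), sum(x$outcomes == "UNBOUND"),
    sum(x$outcomes == "UNTESTED")))
  invisible(x)
}

#' Read a domain-peptide interaction table from TSV
#'
#' The TSV schema is: first column = peptide sequence, remaining columns = one
#' per domain (header gives domain ids); `#` lines are comments. For
#' `format = "binary_tsv"` cells are `1`/`0` (bound/unbound) with empty or
#' `NA` cells meaning untested. For `format = "kd_tsv"` cells are Kd values in
#' micromolar, `NB` for tested non-binders, empty/`NA` for untested; outcomes
#' derive from `kd <= kd_cutoff_uM`.
#'
#' @param path Path to the TSV file.
#' @param format `"binary_tsv"` or `"kd_tsv"`.
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param kd_cutoff_uM Kd classification cutoff (uM), default 100.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path, format = c("binary_tsv", "kd_tsv"),
                                   window_kind = "PDZ_CTERM",
                                   kd_cutoff_uM = 100) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("FileMissing: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 2L)
    stop("ParseError: expected a peptide column plus >=1 domain column",
         call. = FALSE)
  peps <- toupper(df[[1L]])
  doms <- names(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  kd <- NULL
  if (format == "binary_tsv") {
    bad <- !is.na(cells) & !cells %in% c("0", "1")
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("ParseError: row '%s', column '%s': expected 0/1, got '%s'",
                   peps[idx[1L]], doms[idx[2L]], cells[bad][1L]),
           call. = FALSE)
    }
    out <- ifelse(is.na(cells), "UNTESTED",
                  ifelse(cells == "1", "BOUND", "UNBOUND"))
  } else {
    kd <- matrix(NA_real_, nrow(cells), ncol(cells), dimnames = dimnames(cells))
    is_nb <- !is.na(cells) & toupper(cells) == "NB"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !is.na(cells) & !is_nb & (is.na(num) | num <= 0)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "ParseError: row '%s', column '%s': expected positive Kd or NB, got '%s'",
        peps[idx[1L]], doms[idx[2L]], cells[bad][1L]), call. = FALSE)
    }
    kd[!is.na(num)] <- num[!is.na(num)]
    out <- classify_kd(kd, kd_cutoff_uM)
    out[is_nb] <- "UNBOUND"
    dim(out) <- dim(cells)
  }
  colnames(out) <- doms
  interaction_table(data.frame(sequence = peps), out, window_kind,
                    kd = kd, kd_cutoff_uM = kd_cutoff_uM)
}

#' Write an interaction table to TSV
#'
#' Inverse of [read_interaction_table()]: Kd tables are written with Kd values
#' (`NB` for tested non-binders), binary tables as 1/0, untested cells empty.
#'
#' @param x An [interaction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "interaction_table"))
  if (!is.null(x$kd)) {
    cells <- matrix(as.character(x$kd), nrow(x$kd), dimnames = dimnames(x$kd))
    cells[is.na(x$kd) & x$outcomes == "UNBOUND"] <- "NB"
    cells[x$outcomes == "UNTESTED"] <- NA
  } else {
    cells <- ifelse(x$outcomes == "UNTESTED", NA,
                    ifelse(x$outcomes == "BOUND", "1", "0"))
  }
  df <- data.frame(peptide = x$peptides$sequence, cells, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read amino-acid sequences from FASTA
#'
#' Order-preserving; sequences are uppercased. Duplicate ids are kept but
#' suffix-deduplicated (`x`, `x_2`, ...) with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FileMissing: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("ParseError: empty FASTA file: ", path,
                             call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids suffix-deduplicated: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
    ids <- make.unique(ids, sep = "_")
    # make.unique yields x, x_1; shift duplicates to x, x_2, ...
    dup <- grepl("_\\d+$", ids) & !grepl("_\\d+$", sub("\\s.*$", "", names(ss)))
    ids[dup] <- vapply(ids[dup], function(s) {
      k <- as.integer(sub("^.*_(\\d+)$", "\\1", s))
      sub("_\\d+$", paste0("_", k + 1L), s)
    }, character(1L))
  }
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Load the bundled Scrib PDZ validation panel
#'
#' A 56-ligand panel of human C-terminal peptides tested against the three
#' Scrib PDZ domains: measured Kd (uM; `NA` = no binding detected), per-domain
#' prediction scores and database-standardized Z scores, plus flags for the
#' four proteins (APC, LPP, VANGL2, ZO2) previously reported as in-vivo Scrib
#' partners.
#'
#' @return A data frame of class `table1_fixture` with columns `protein`,
#'   `cterm`, `kd_pdz1..3` (numeric, `NA` = NB), `score_pdz1..3`,
#'   `z_pdz1..3`, `in_vivo` (logical).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "scrib_pdz_table1.tsv", package = "dompep",
                      mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (d in 1:3) {
    kd <- df[[paste0("kd_pdz", d)]]
    df[[paste0("kd_pdz", d)]] <- suppressWarnings(as.numeric(kd))
  }
  df$in_vivo <- df$in_vivo == 1L
  stopifnot(nrow(df) == 56L)
  class(df) <- c("table1_fixture", class(df))
  df
}

#' Scrib panel domain ids
#' @return `c("PDZ1","PDZ2","PDZ3")`.
#' @keywords internal
table1_domains <- function() paste0("PDZ", 1:3)
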