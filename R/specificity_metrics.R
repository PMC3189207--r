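# Pairwise specificity metrics: ligand-binding similarity (standard and
# minimum-denominator forms), PWM construction and angle-based PWM distance,
# and global-alignment domain sequence identity.

#' Binder-overlap counts for a domain pair
#'
#' Only peptides tested for both domains contribute; untested cells are never
#' treated as unbound.
#'
#' @param table An [interaction_table()].
#' @param domain_i,domain_j Domain ids present in the table.
#' @return A list of class `lbs_counts`: `b_ij` (bound by both), `b_i_nb_j`,
#'   `b_j_nb_i` (bound by one, unbound by the other), `b_i`, `b_j` (total
#'   bound among co-tested peptides), `n_cotested`.
#' @export
lbs_counts <- function(table, domain_i, domain_j) {
  stopifnot(inherits(table, "interaction_table"))
  oi <- table$outcomes[, domain_i]
  oj <- table$outcomes[, domain_j]
  both <- oi != "UNTESTED" & oj != "UNTESTED"
  bi <- both & oi == "BOUND"
  bj <- both & oj == "BOUND"
  structure(list(
    b_ij = sum(bi & bj),
    b_i_nb_j = sum(bi & !bj),
    b_j_nb_i = sum(bj & !bi),
    b_i = sum(bi), b_j = sum(bj),
    n_cotested = sum(both)), class = "lbs_counts")
}

#' Standard ligand-binding similarity
#'
#' The fraction of peptides commonly bound by a domain pair among all peptides
#' bound by either: `b_ij / (b_ij + b_i_nb_j + b_j_nb_i)` -- the Jaccard index
#' of the two binder sets over co-tested peptides. 1 means identical binder
#' sets, 0 disjoint. Suits quantitative, saturating panels (PDZ-style data).
#'
#' @param counts An [lbs_counts()] result (or a list with the same fields).
#' @return LBS in `[0, 1]`.
#' @export
lbs_standard <- function(counts) {
  den <- counts$b_ij + counts$b_i_nb_j + counts$b_j_nb_i
  if (den == 0)
    stop("UndefinedMetric: neither domain bound any co-tested peptide",
         call. = FALSE)
  counts$b_ij / den
}

#' Minimum-denominator ligand-binding similarity
#'
#' `b_ij / min(b_i, b_j)`. Robust to signal-strength differences between
#' array experiments: when one domain's panel detects far fewer binders but
#' all of them are shared (as for the ABL1/ABL2 SH2 pair, 173 vs 40 binders
#' with full nesting), the standard form collapses to 0.23 while this form
#' correctly reports 1.
#'
#' @inheritParams lbs_standard
#' @return LBS in `[0, 1]`; 1 whenever the smaller binder set nests in the
#'   larger.
#' @export
lbs_modified <- function(counts) {
  den <- min(counts$b_i, counts$b_j)
  if (den == 0)
    stop("UndefinedMetric: a domain has zero co-tested binders", call. = FALSE)
  counts$b_ij / den
}

#' Build a position weight matrix from binding peptides
#'
#' Plain per-position residue frequencies over the fixed window -- no
#' pseudocounts by default (a Laplace `alpha` is available but off). Rows are
#' window positions, columns the 20 residues in alphabetical order.
#'
#' @param peptides Character vector of peptide sequences (full length or
#'   already window-length; truncated via [peptide_window()]).
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param alpha Laplace pseudocount added to every cell before normalization;
#'   default 0.
#' @return A `pwm` object: `freq` (w x 20 matrix, rows sum to 1),
#'   `n_peptides`, `window_kind`.
#' @export
build_pwm <- function(peptides, window_kind, alpha = 0) {
  if (length(peptides) == 0L)
    stop("EmptyInputError: no peptides", call. = FALSE)
  win <- peptide_window(peptides, window_kind)
  w <- window_width(window_kind)
  mat <- matrix(0, nrow = w, ncol = 20L,
                dimnames = list(paste0("pos", seq_len(w)), AA_ALPHABET))
  chars <- strsplit(win, "")
  for (p in chars)
    for (i in seq_len(w))
      mat[i, p[[i]]] <- mat[i, p[[i]]] + 1
  mat <- mat + alpha
  freq <- mat / rowSums(mat)
  structure(list(freq = freq, n_peptides = length(win),
                 window_kind = window_kind), class = "pwm")
}

.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Angle-based distance between two PWMs
#'
#' Per window position, the two frequency vectors are rescaled to unit length
#' and the angle between them taken (inverse cosine of the inner product,
#' clipped to `[0, 1]`); frequency vectors are non-negative, so angles lie in
#' `[0, pi/2]` and are normalized by `pi/2`. The default averages the
#' normalized angle over the `w` positions; `method = "flattened"` instead
#' takes one angle over the whole matrix flattened to a single vector (a
#' sensitivity variant). Either way the distance lies in `[0, 1]`: 0 for
#' proportional per-position frequencies, 1 when every position has disjoint
#' residue support.
#'
#' @param a,b `pwm` objects with equal window width.
#' @param method `"column_average"` (default) or `"flattened"`.
#' @return Distance in `[0, 1]`.
#' @export
pwm_distance <- function(a, b, method = c("column_average", "flattened")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (nrow(a$freq) != nrow(b$freq))
    stop("WindowMismatch: PWMs have different window widths", call. = FALSE)
  if (method == "column_average") {
    ua <- .unit_rows(a$freq)
    ub <- .unit_rows(b$freq)
    ip <- pmin(pmax(rowSums(ua * ub), 0), 1)
    mean(acos(ip) / (pi / 2))
  } else {
    va <- as.vector(a$freq); vb <- as.vector(b$freq)
    ip <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    acos(min(max(ip, 0), 1)) / (pi / 2)
  }
}

#' Domain sequence identity from global alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap penalties
#' (open 10, extend 0.1 -- ClustalW2-like defaults), identity counted as
#' identical aligned columns over the full alignment length (gap columns in
#' the denominator). Related domains align nearly gap-free, so the
#' denominator choice barely moves their DSI, while for unrelated sequences
#' it keeps DSI honestly low (cheap gap extension would otherwise let the
#' aligner concentrate matches into few gap-free columns and inflate
#' identity).
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return Percent identity in `[0, 100]`.
#' @export
dsi <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.1) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  .check_alphabet(c(seq_a, seq_b), "domain sequence")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Binding windows of one domain
#'
#' @param table An [interaction_table()].
#' @param domain Domain id.
#' @return Unique window sequences of the peptides the domain binds.
#' @export
binders <- function(table, domain) {
  stopifnot(inherits(table, "interaction_table"))
  unique(table$peptides$window[table$outcomes[, domain] == "BOUND"])
}

#' Pairwise specificity metrics for all domain pairs
#'
#' One record per unordered pair: LBS and PWM distance are only defined when
#' both domains have at least `min_binders` experimentally verified binders
#' (pairs failing that carry `NA`, they are never dropped); DSI is always
#' computed. The LBS variant defaults per family -- standard (union
#' denominator) for PDZ-style quantitative data, minimum-denominator for
#' SH2-style array data -- but is a switch, not hard-coded.
#'
#' @param table An [interaction_table()].
#' @param domain_seqs Named character vector of domain sequences covering all
#'   table domains.
#' @param min_binders Minimum binder count for LBS/PWM distance, default 10.
#' @param lbs_variant `"standard"` or `"min_denominator"`; default by family.
#' @param pwm_method Passed to [pwm_distance()].
#' @return Data frame with columns `domain_i`, `domain_j`, `n_cotested`,
#'   `lbs`, `lbs_variant`, `dsi`, `pwm_distance`.
#' @export
pairwise_metrics_table <- function(table, domain_seqs, min_binders = 10,
                                   lbs_variant = NULL,
                                   pwm_method = "column_average") {
  stopifnot(inherits(table, "interaction_table"))
  doms <- table$domains
  missing_seq <- setdiff(doms, names(domain_seqs))
  if (length(missing_seq))
    stop("MissingSequence: no sequence for ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  if (is.null(lbs_variant))
    lbs_variant <- if (table$window_kind == "PDZ_CTERM") "standard"
                   else "min_denominator"
  lbs_variant <- match.arg(lbs_variant, c("standard", "min_denominator"))
  lbs_fun <- if (lbs_variant == "standard") lbs_standard else lbs_modified

  nb <- vapply(doms, function(d) length(binders(table, d)), integer(1L))
  pwms <- lapply(doms, function(d) {
    if (nb[[d]] >= min_binders)
      build_pwm(binders(table, d), table$window_kind) else NULL
  })
  names(pwms) <- doms

  pairs <- utils::combn(doms, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cnt <- lbs_counts(table, i, j)
    defined <- nb[[i]] >= min_binders && nb[[j]] >= min_binders
    lbs <- if (defined) tryCatch(lbs_fun(cnt), error = function(e) NA_real_)
           else NA_real_
    pd <- if (defined) pwm_distance(pwms[[i]], pwms[[j]], pwm_method)
          else NA_real_
    data.frame(domain_i = i, domain_j = j, n_cotested = cnt$n_cotested,
               lbs = lbs, lbs_variant = lbs_variant,
               dsi = dsi(domain_seqs[[i]], domain_seqs[[j]]),
               pwm_distance = pd)
  })
  out <- do.call(rbind, res)
  .dompep_log("pairwise metrics: %d pairs, %d with defined LBS",
              nrow(out), sum(!is.na(out$lbs)))
  out
}
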