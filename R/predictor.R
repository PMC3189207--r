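# Proteome scanning: window extraction, model scoring with Z-score
# standardization against the scanned database, and stringency calls.

#' Extract candidate binding windows from a proteome
#'
#' PDZ domains bind extreme C-termini, so each protein contributes exactly
#' one window -- its C-terminal 5-mer. SH2 domains bind phosphotyrosine
#' contexts, so each tyrosine with a complete -2..+4 flank contributes one
#' 6-mer (the pY itself excluded); tyrosines whose window would run past a
#' terminus are skipped. Every tyrosine is scanned regardless of
#' phosphorylation state -- a deliberate over-approximation, since the
#' binding data come from synthetic pY-peptide arrays. Proteins shorter than
#' the window yield no window.
#'
#' @param proteome Named character vector of protein sequences.
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @return Data frame with columns `protein`, `window`, `position` (1-based
#'   position of the window anchor: the first window residue for PDZ, the
#'   tyrosine for SH2).
#' @export
extract_windows <- function(proteome, window_kind) {
  window_kind <- match.arg(window_kind, c("PDZ_CTERM", "SH2_PY"))
  stopifnot(!is.null(names(proteome)))
  proteome <- toupper(proteome)
  if (window_kind == "PDZ_CTERM") {
    len <- nchar(proteome)
    keep <- len >= 5L
    if (any(!keep))
      .dompep_log("%d protein(s) shorter than 5 aa skipped", sum(!keep))
    df <- data.frame(protein = names(proteome)[keep],
                     window = substr(proteome[keep], len[keep] - 4L,
                                     len[keep]),
                     position = len[keep] - 4L)
  } else {
    rows <- lapply(seq_along(proteome), function(i) {
      s <- proteome[[i]]
      ys <- gregexpr("Y", s, fixed = TRUE)[[1L]]
      ys <- ys[ys >= 3L & ys + 4L <= nchar(s)]
      if (length(ys) == 0L || ys[1L] == -1L)
        return(NULL)
      data.frame(protein = names(proteome)[i],
                 window = paste0(substr(rep(s, length(ys)), ys - 2L, ys - 1L),
                                 substr(rep(s, length(ys)), ys + 1L, ys + 4L)),
                 position = ys)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(protein = character(), window = character(),
                       position = integer())
  }
  rownames(df) <- NULL
  df
}

#' Scan a proteome with a binding model
#'
#' Every extracted window is scored with the model's linear decision
#' function; scores are standardized to Z scores, `z = (raw - mu) / sigma`,
#' with `mu` and `sigma` taken over all windows scanned in this run (the
#' scanned database is the reference population) unless a stored
#' `score_stats` from a previous large scan is supplied. Records are sorted
#' by raw score descending.
#'
#' @param model A `binding_model`.
#' @param proteome Named character vector of protein sequences.
#' @param score_stats Optional `c(mean, sd)` reference statistics to reuse.
#' @return Data frame of class `dompep_predictions` with columns `protein`,
#'   `window`, `position`, `raw_score`, `z_score`; the attribute
#'   `score_stats` holds the reference `c(mean, sd)` and `model` the model
#'   updated with them.
#' @export
scan_proteome <- function(model, proteome, score_stats = NULL) {
  stopifnot(inherits(model, "binding_model"))
  wins <- extract_windows(proteome, model$window_kind)
  if (nrow(wins) == 0L)
    stop("EmptyProteome: no scannable windows", call. = FALSE)
  wins$raw_score <- score_windows(model, wins$window)
  if (is.null(score_stats))
    score_stats <- c(mean = mean(wins$raw_score), sd = sd(wins$raw_score))
  wins$z_score <- (wins$raw_score - score_stats[[1L]]) / score_stats[[2L]]
  wins <- wins[order(-wins$raw_score, wins$protein), , drop = FALSE]
  rownames(wins) <- NULL
  model$score_stats <- score_stats
  structure(wins, score_stats = score_stats, model = model,
            class = c("dompep_predictions", class(wins)))
}

#' Stringency cutoffs from TPR-anchored averaged ROC curves
#'
#' The three stringency levels are anchored at true-positive rates of 70%,
#' 50% and 30% on the ROC curve averaged over models. Per model, the raw-
#' score threshold achieving a TPR level is the score of the
#' `ceiling(tpr * n_pos)`-th highest-scoring positive; cutoffs are the mean
#' of these thresholds over models. A lower TPR anchor means a higher
#' threshold and fewer, more confident calls, so the tightest anchor (TPR
#' 30%) is labeled `high` stringency and the loosest (TPR 70%) `low`; this
#' keeps the call sets nested (every HIGH call is also a MEDIUM and LOW
#' call). Per-model ROC curves are also pooled by vertical averaging (mean
#' FPR on a fixed TPR grid) and returned as provenance.
#'
#' @param eval_data List (one element per model) of data frames with columns
#'   `score` and `label` (logical).
#' @param tpr_levels Strictly descending TPR targets, default
#'   `c(0.7, 0.5, 0.3)` for high/medium/low.
#' @return A `stringency_cutoffs` object: named numeric thresholds (`high`,
#'   `medium`, `low`), with attributes `per_model` (threshold matrix) and
#'   `avg_roc` (TPR grid with mean FPR).
#' @export
derive_stringency_cutoffs <- function(eval_data,
                                      tpr_levels = c(0.7, 0.5, 0.3)) {
  if (any(diff(tpr_levels) >= 0))
    stop("tpr_levels must be strictly descending", call. = FALSE)
  stopifnot(length(eval_data) >= 1L)
  thr <- vapply(eval_data, function(d) {
    pos <- sort(d$score[d$label], decreasing = TRUE)
    neg <- d$score[!d$label]
    if (length(pos) == 0L || length(neg) == 0L)
      stop("InsufficientLabels: each model needs positives and negatives",
           call. = FALSE)
    pos[pmin(length(pos), ceiling(tpr_levels * length(pos)))]
  }, numeric(length(tpr_levels)))
  thr <- matrix(thr, nrow = length(tpr_levels))
  cuts <- rowMeans(thr)
  # descending TPR anchors give ascending thresholds; the tightest
  # threshold (lowest TPR) is the high-stringency cutoff
  cuts <- rev(cuts)
  thr <- thr[rev(seq_len(nrow(thr))), , drop = FALSE]
  names(cuts) <- if (length(tpr_levels) == 3L) c("high", "medium", "low")
                 else paste0("tpr", rev(tpr_levels))
  grid <- seq(0, 1, by = 0.01)
  fpr <- rowMeans(vapply(eval_data, function(d) {
    r <- aroc(d$score, d$label)
    vapply(grid, function(t) {
      i <- which(r$points$tpr >= t - 1e-12)
      if (length(i)) min(r$points$fpr[i]) else 1
    }, numeric(1L))
  }, numeric(length(grid))))
  structure(cuts, per_model = thr, avg_roc = data.frame(tpr = grid,
                                                        fpr = fpr),
            class = "stringency_cutoffs")
}

#' Assign stringency calls to scanned records
#'
#' Each record gets the tightest stringency level whose raw-score threshold
#' it meets (`HIGH`, then `MEDIUM`, then `LOW`), or `NONE`. Because the
#' thresholds are non-increasing, the call sets nest: every HIGH call is also
#' above the MEDIUM and LOW thresholds.
#'
#' @param records Output of [scan_proteome()] (needs a `raw_score` column).
#' @param cutoffs A [derive_stringency_cutoffs()] result or a named numeric
#'   vector `c(high =, medium =, low =)` with non-increasing values.
#' @return `records` with a `stringency_call` column added.
#' @export
assign_stringency <- function(records, cutoffs) {
  cuts <- as.numeric(cutoffs)[1:3]
  if (is.unsorted(rev(cuts)))
    stop("stringency cutoffs must satisfy high >= medium >= low",
         call. = FALSE)
  s <- records$raw_score
  records$stringency_call <- ifelse(
    s >= cuts[1L], "HIGH",
    ifelse(s >= cuts[2L], "MEDIUM", ifelse(s >= cuts[3L], "LOW", "NONE")))
  records
}

#' Write prediction records to TSV
#' @param records Output of [scan_proteome()] / [assign_stringency()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
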