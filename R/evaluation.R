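# ROC/AROC computation, paired model comparison by Wilcoxon signed-rank
# test, and the bundled Scrib PDZ validation harness.

#' Area under the ROC curve
#'
#' The AROC is computed in the rank (Mann-Whitney) form -- the probability
#' that a random positive outscores a random negative, with tied
#' positive/negative pairs contributing 1/2 -- so it is invariant to any
#' strictly monotone transform of the scores. The full ROC curve (FPR, TPR at
#' every distinct threshold, descending) is returned alongside; ties produce
#' diagonal segments whose trapezoidal area matches the rank form.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) labels, at least one of each class.
#' @return An object of class `roc_result`: `points` (data frame `fpr`,
#'   `tpr`), `aroc`, `n_pos`, `n_neg`.
#' @export
aroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("DegenerateLabels: need at least one positive and one negative",
         call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1L))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1L))
  points <- data.frame(fpr = c(0, fp / n_neg, 1), tpr = c(0, tp / n_pos, 1))
  structure(list(points = points, aroc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AROC %.4f (%d positives, %d negatives)\n",
              x$aroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Trapezoidal area of an ROC curve
#' @param points Data frame with `fpr`, `tpr` columns (monotone).
#' @return Area in `[0, 1]`.
#' @export
roc_trapezoid <- function(points) {
  sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
}

#' Compare two sets of per-domain model AROCs by Wilcoxon signed-rank test
#'
#' Paired, two-sided; zero differences are discarded under the standard
#' signed-rank convention (all-zero pairs degenerate to p = 1 with a
#' warning). The exact null distribution is used for 25 or fewer non-zero
#' untied differences, the normal approximation with continuity correction
#' otherwise.
#'
#' @param aroc_a,aroc_b Paired numeric vectors (same domains, same order),
#'   length >= 6.
#' @return List with `statistic` (signed-rank sum, flips sign when the
#'   arguments are swapped) and `p_value`.
#' @export
compare_models_wilcoxon <- function(aroc_a, aroc_b) {
  if (length(aroc_a) != length(aroc_b))
    stop("LengthMismatch: paired AROC lists differ in length", call. = FALSE)
  stopifnot(length(aroc_a) >= 6L)
  d <- aroc_a - aroc_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; degenerate test, p = 1",
            call. = FALSE)
    return(list(statistic = 0, p_value = 1))
  }
  stat <- sum(sign(d) * rank(abs(d)))
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = stat, p_value = wt$p.value)
}

#' Validate prediction scores on the bundled Scrib PDZ panel
#'
#' Labels each of the 56 panel peptides per Scrib domain as positive when the
#' measured Kd is at or below the cutoff and computes the per-domain AROC of
#' the prediction scores, the positive counts, and two Z-score summaries: the
#' mean Z over every positive interaction and the mean Z over the ten
#' interactions of the four previously known in-vivo Scrib partners (APC,
#' LPP, VANGL2, ZO2; the domains each measurably binds). With
#' `use = "printed_scores"` the panel's own published per-peptide scores are
#' evaluated -- fully deterministic. With `use = "retrained_model"` a named
#' list of `binding_model`s (`PDZ1..3`) is scanned over the 56 C-termini
#' instead (exploratory; Z scores then standardize against the 56-window
#' panel itself).
#'
#' @param fixture A [load_table1_fixture()] data frame.
#' @param use `"printed_scores"` (default) or `"retrained_model"`.
#' @param models Named list of models, required for `"retrained_model"`.
#' @param kd_cutoff_uM Positive/negative Kd cutoff, default 100.
#' @return List with `per_domain` (data frame: domain, n_pos, aroc),
#'   `roc` (list of `roc_result`), `mean_z_positives`,
#'   `mean_z_in_vivo`, `n_in_vivo_interactions`.
#' @export
table1_validation <- function(fixture = load_table1_fixture(),
                              use = c("printed_scores", "retrained_model"),
                              models = NULL, kd_cutoff_uM = 100) {
  use <- match.arg(use)
  doms <- table1_domains()
  kd <- sapply(tolower(doms), function(d) fixture[[paste0("kd_", d)]])
  pos <- !is.na(kd) & kd <= kd_cutoff_uM
  if (use == "printed_scores") {
    sc <- sapply(tolower(doms), function(d) fixture[[paste0("score_", d)]])
    z <- sapply(tolower(doms), function(d) fixture[[paste0("z_", d)]])
  } else {
    stopifnot(!is.null(models), all(doms %in% names(models)))
    prot <- setNames(fixture$cterm, fixture$protein)
    sc <- sapply(doms, function(d) {
      r <- scan_proteome(models[[d]], prot)
      r$raw_score[match(fixture$protein, r$protein)]
    })
    z <- scale(sc)
  }
  roc <- lapply(seq_along(doms), function(i) aroc(sc[, i], pos[, i]))
  names(roc) <- doms
  per_domain <- data.frame(
    domain = doms,
    n_pos = colSums(pos),
    aroc = vapply(roc, `[[`, numeric(1L), "aroc"),
    row.names = NULL)
  iv <- matrix(fixture$in_vivo, nrow(fixture), length(doms))
  list(per_domain = per_domain, roc = roc,
       mean_z_positives = mean(z[pos]),
       mean_z_in_vivo = mean(z[pos & iv]),
       n_in_vivo_interactions = sum(pos & iv))
}
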