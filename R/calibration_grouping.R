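# LBS-calibrated thresholds on DSI and PWM distance, identification of
# specificity-similar domains, and substitute-model lookup for query domains
# without binding data.

#' Construct a threshold rule
#'
#' A rule is a disjunction of conjunctive clauses over the predicates
#' `dsi >= dsi_min` and `pwm_distance < pwm_max`; a domain pair (or group
#' candidate) is admitted if any clause holds.
#'
#' @param family `"PDZ"` or `"SH2"`.
#' @param clauses List of clauses, each a list with optional numeric fields
#'   `dsi_min` and `pwm_max` (at least one present).
#' @param lbs_cutoff The LBS level the thresholds were calibrated to,
#'   default 0.7.
#' @param insufficient Flag set by [calibrate_thresholds()] when no bin
#'   reached the cutoff (empty admissible region).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(family, clauses, lbs_cutoff = 0.7,
                           insufficient = FALSE) {
  family <- match.arg(family, c("PDZ", "SH2"))
  if (!insufficient && length(clauses) == 0L)
    stop("threshold_rule: clauses must be non-empty", call. = FALSE)
  for (cl in clauses) {
    if (is.null(cl$dsi_min) && is.null(cl$pwm_max))
      stop("threshold_rule: a clause needs dsi_min and/or pwm_max",
           call. = FALSE)
    stopifnot(all(is.finite(unlist(cl))))
  }
  structure(list(family = family, clauses = clauses,
                 lbs_cutoff = lbs_cutoff, insufficient = insufficient),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  fmt <- vapply(x$clauses, function(cl) {
    parts <- c(
      if (!is.null(cl$dsi_min)) sprintf("DSI >= %g%%", cl$dsi_min),
      if (!is.null(cl$pwm_max)) sprintf("PWM distance < %g", cl$pwm_max))
    paste(parts, collapse = " & ")
  }, character(1L))
  cat(sprintf("threshold_rule (%s, LBS cutoff %g)%s:\n", x$family,
              x$lbs_cutoff,
              if (x$insufficient) " [INSUFFICIENT DATA]" else ""))
  if (length(fmt)) cat(paste0("  ", fmt, collapse = "\n"), "\n")
  invisible(x)
}

#' Published default threshold rules
#'
#' The per-family rules established on the large PDZ and SH2 array panels:
#' PDZ pairs are specificity-similar when DSI >= 50% or PWM distance < 0.3;
#' SH2 pairs when DSI >= 60%, or PWM distance < 0.1, or DSI >= 40% together
#' with PWM distance < 0.3. These let users without array data of their own
#' run the published behavior.
#'
#' @param family `"PDZ"` or `"SH2"`.
#' @return A [threshold_rule()].
#' @export
default_threshold_rule <- function(family) {
  family <- match.arg(family, c("PDZ", "SH2"))
  if (family == "PDZ")
    threshold_rule("PDZ", list(list(dsi_min = 50), list(pwm_max = 0.3)))
  else
    threshold_rule("SH2", list(list(dsi_min = 60), list(pwm_max = 0.1),
                               list(dsi_min = 40, pwm_max = 0.3)))
}

#' Evaluate a rule against a pair's metrics
#'
#' @param rule A [threshold_rule()].
#' @param dsi DSI percentage.
#' @param pwm_distance PWM distance or `NA` when undefined.
#' @return Integer indices of the satisfied clauses (empty if none).
#' @export
rule_admits <- function(rule, dsi, pwm_distance = NA_real_) {
  stopifnot(inherits(rule, "threshold_rule"))
  ok <- vapply(rule$clauses, function(cl) {
    d_ok <- is.null(cl$dsi_min) || (!is.na(dsi) && dsi >= cl$dsi_min)
    p_ok <- is.null(cl$pwm_max) ||
      (!is.na(pwm_distance) && pwm_distance < cl$pwm_max)
    d_ok && p_ok
  }, logical(1L))
  which(ok)
}

#' Calibrate DSI and PWM-distance thresholds against LBS
#'
#' Pairs with defined LBS are binned by DSI (default band edges 0, 30, 40,
#' 50, 60, 100) and by PWM distance (default width-0.1 bins on `[0, 1]`), and
#' per-bin mean LBS is computed. The DSI threshold is the lowest band edge
#' from which that band and every higher band has mean LBS at or above
#' `lbs_cutoff`; the PWM threshold is the highest distance edge below which
#' every bin's mean LBS reaches the cutoff. A compound clause
#' (`dsi >= band & pwm < edge`) is emitted for an intermediate DSI band that
#' reaches the cutoff only jointly with a PWM-distance band -- the situation
#' observed for SH2 pairs at DSI 40-59% with PWM distance < 0.3. When no bin
#' anywhere reaches the cutoff, the rule is returned with no clauses and the
#' `insufficient` flag set.
#'
#' @param metrics Output of [pairwise_metrics_table()].
#' @param lbs_cutoff LBS level defining "similar specificity", default 0.7.
#' @param family `"PDZ"` or `"SH2"` (recorded in the rule).
#' @param dsi_edges,pwm_edges Bin edges.
#' @param min_pairs Minimum pairs for a bin's mean to count, default 1.
#' @return A [threshold_rule()] whose `bins` attribute holds the per-bin
#'   mean/SD/count table used for calibration.
#' @export
calibrate_thresholds <- function(metrics, lbs_cutoff = 0.7,
                                 family = c("PDZ", "SH2"),
                                 dsi_edges = c(0, 30, 40, 50, 60, 100),
                                 pwm_edges = seq(0, 1, by = 0.1),
                                 min_pairs = 1L) {
  family <- match.arg(family)
  m <- metrics[!is.na(metrics$lbs), , drop = FALSE]
  if (nrow(m) == 0L)
    return(threshold_rule(family, list(), lbs_cutoff, insufficient = TRUE))

  bin_stats <- function(x, edges) {
    bin <- cut(x, edges, right = FALSE, include.lowest = TRUE)
    data.frame(
      lower = edges[-length(edges)], upper = edges[-1L],
      mean_lbs = as.numeric(tapply(m$lbs, bin, mean)[levels(bin)]),
      sd_lbs = as.numeric(tapply(m$lbs, bin, sd)[levels(bin)]),
      n = as.integer(table(bin)[levels(bin)]))
  }
  dsi_tab <- bin_stats(m$dsi, dsi_edges)
  pwm_tab <- bin_stats(m$pwm_distance, pwm_edges)
  # a bin qualifies when populated and its mean LBS reaches the cutoff;
  # empty bins are neutral (they neither qualify nor veto a threshold)
  qual_dsi <- !is.na(dsi_tab$mean_lbs) & dsi_tab$n >= min_pairs &
    dsi_tab$mean_lbs >= lbs_cutoff
  block_dsi <- !is.na(dsi_tab$mean_lbs) & dsi_tab$n >= min_pairs &
    dsi_tab$mean_lbs < lbs_cutoff
  qual_pwm <- !is.na(pwm_tab$mean_lbs) & pwm_tab$n >= min_pairs &
    pwm_tab$mean_lbs >= lbs_cutoff
  block_pwm <- !is.na(pwm_tab$mean_lbs) & pwm_tab$n >= min_pairs &
    pwm_tab$mean_lbs < lbs_cutoff

  clauses <- list()
  # DSI threshold: lowest qualifying band edge with no blocking band above
  dsi_min <- NA_real_
  clear_above <- rev(cumprod(rev(!block_dsi))) == 1
  cand_dsi <- which(qual_dsi & clear_above)
  if (length(cand_dsi)) {
    dsi_min <- dsi_tab$lower[min(cand_dsi)]
    clauses <- c(clauses, list(list(dsi_min = dsi_min)))
  }
  # PWM threshold: widest distance prefix containing a qualifying bin and
  # no blocking bin
  pwm_max <- NA_real_
  clear_below <- cumprod(!block_pwm) == 1
  cand_pwm <- which(qual_pwm & clear_below)
  if (length(cand_pwm)) {
    pwm_max <- pwm_tab$upper[max(cand_pwm)]
    clauses <- c(clauses, list(list(pwm_max = pwm_max)))
  }
  # compound clauses for intermediate DSI bands reaching the cutoff only
  # jointly with a PWM-distance prefix wider than the global PWM threshold
  inter <- which(!qual_dsi & dsi_tab$lower > dsi_edges[1L] &
                   (is.na(dsi_min) | dsi_tab$lower < dsi_min))
  for (b in inter) {
    sel <- m$dsi >= dsi_tab$lower[b] &
      (is.na(dsi_min) | m$dsi < dsi_min) & !is.na(m$pwm_distance)
    if (!any(sel)) next
    pw <- bin_stats_subset(m[sel, , drop = FALSE], pwm_edges, min_pairs,
                           lbs_cutoff)
    if (is.na(pw)) next
    if (is.na(pwm_max) || pw > pwm_max)
      clauses <- c(clauses,
                   list(list(dsi_min = dsi_tab$lower[b], pwm_max = pw)))
  }
  # prune clauses subsumed by a strictly-wider clause
  if (length(clauses) > 1L) {
    lo <- vapply(clauses, function(cl)
      if (is.null(cl$dsi_min)) -Inf else cl$dsi_min, numeric(1L))
    hi <- vapply(clauses, function(cl)
      if (is.null(cl$pwm_max)) Inf else cl$pwm_max, numeric(1L))
    keep <- vapply(seq_along(clauses), function(i) {
      !any(lo <= lo[i] & hi >= hi[i] &
             (lo < lo[i] | hi > hi[i]))
    }, logical(1L))
    clauses <- clauses[keep]
  }
  rule <- threshold_rule(family, clauses, lbs_cutoff,
                         insufficient = length(clauses) == 0L)
  attr(rule, "bins") <- list(dsi = dsi_tab, pwm = pwm_tab)
  rule
}

# widest PWM-distance prefix edge within a subset of pairs: the upper edge
# of the furthest qualifying bin with no blocking bin at or below it (empty
# bins are neutral); NA when no bin qualifies
bin_stats_subset <- function(m, pwm_edges, min_pairs, lbs_cutoff) {
  bin <- cut(m$pwm_distance, pwm_edges, right = FALSE, include.lowest = TRUE)
  mu <- tapply(m$lbs, bin, mean)[levels(bin)]
  n <- as.integer(table(bin)[levels(bin)])
  qual <- !is.na(mu) & n >= min_pairs & mu >= lbs_cutoff
  block <- !is.na(mu) & n >= min_pairs & mu < lbs_cutoff
  cand <- which(qual & cumprod(!block) == 1)
  if (!length(cand)) return(NA_real_)
  pwm_edges[-1L][max(cand)]
}

#' Identify the specificity-similar domains of a query
#'
#' A family member is admitted if its DSI to the query satisfies a DSI clause
#' of the rule; additionally, when both the query and the member have at
#' least `min_binders` experimentally verified binders, PWM-distance clauses
#' can admit it. Members are ordered by PWM distance ascending (undefined
#' last), ties broken by DSI descending, then by id -- PWM distance is the
#' more direct specificity measure, and this order drives the iterative
#' pooling in [build_dompep_model()].
#'
#' @param query Query domain id (present in `domain_seqs`).
#' @param domain_seqs Named character vector of domain sequences (query and
#'   candidate members).
#' @param table An [interaction_table()] supplying binding data, or `NULL`
#'   for sequence-only admission.
#' @param rule A [threshold_rule()].
#' @param min_binders Minimum binders for PWM-distance eligibility.
#' @return A `similarity_group`: `query`, `members` (ordered ids) and
#'   `evidence` (data frame of member, dsi, pwm_distance, clauses).
#' @export
find_similar_domains <- function(query, domain_seqs, table = NULL,
                                 rule = default_threshold_rule("PDZ"),
                                 min_binders = 10) {
  if (!query %in% names(domain_seqs))
    stop("MissingSequence: query ", query, call. = FALSE)
  cand <- setdiff(names(domain_seqs), query)
  nb <- if (!is.null(table)) {
    vapply(intersect(c(query, cand), table$domains),
           function(d) length(binders(table, d)), integer(1L))
  } else integer(0)
  q_pwm <- if (!is.null(table) && query %in% names(nb) &&
               nb[[query]] >= min_binders)
    build_pwm(binders(table, query), table$window_kind) else NULL

  ev <- lapply(cand, function(d) {
    ds <- dsi(domain_seqs[[query]], domain_seqs[[d]])
    pd <- NA_real_
    if (!is.null(q_pwm) && d %in% names(nb) && nb[[d]] >= min_binders)
      pd <- pwm_distance(q_pwm, build_pwm(binders(table, d),
                                          table$window_kind))
    cl <- rule_admits(rule, ds, pd)
    data.frame(member = d, dsi = ds, pwm_distance = pd,
               clauses = I(list(cl)), admitted = length(cl) > 0L)
  })
  ev <- do.call(rbind, ev)
  adm <- ev[ev$admitted, , drop = FALSE]
  ord <- order(is.na(adm$pwm_distance), adm$pwm_distance, -adm$dsi,
               adm$member)
  adm <- adm[ord, , drop = FALSE]
  structure(list(query = query, members = adm$member,
                 evidence = adm[, c("member", "dsi", "pwm_distance",
                                    "clauses")]),
            class = "similarity_group")
}

#' @export
print.similarity_group <- function(x, ...) {
  cat(sprintf("similarity_group: query %s, %d member(s)\n", x$query,
              length(x$members)))
  if (length(x$members)) print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Rank substitute models for an unmodeled query domain
#'
#' For a query without its own binding model, candidate models are ranked by
#' DSI of the query sequence to each model's domain sequence; candidates at
#' or above `min_dsi` are kept, sorted by DSI descending and truncated to
#' `top_k`. The `recommended` flag follows the per-family guidance that a
#' substitute is trustworthy for PDZ at DSI >= 50% and SH2 at DSI >= 60%.
#'
#' @param query_sequence Amino-acid string of the query domain.
#' @param model_store List of [binding_model] objects (each carries the
#'   domain sequence it was built for).
#' @param min_dsi Minimum DSI to list a candidate, default 40.
#' @param top_k Maximum candidates returned, default 10.
#' @return Data frame with columns `model`, `family`, `dsi`, `recommended`
#'   (possibly 0 rows).
#' @export
substitute_model_lookup <- function(query_sequence, model_store,
                                    min_dsi = 40, top_k = 10) {
  stopifnot(length(model_store) > 0L)
  rows <- lapply(model_store, function(m) {
    data.frame(model = m$domain, family = m$family,
               dsi = dsi(query_sequence, m$domain_sequence))
  })
  df <- do.call(rbind, rows)
  df <- df[df$dsi >= min_dsi, , drop = FALSE]
  df <- df[order(-df$dsi, df$model), , drop = FALSE]
  df <- head(df, top_k)
  df$recommended <- df$dsi >= ifelse(df$family == "PDZ", 50, 60)
  rownames(df) <- NULL
  df
}
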