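# Orthogonal peptide encoding, negative-set sampling, linear-SVM training,
# leave-one-out scoring, and model selection over iteratively pooled
# specificity-similar domain groups.

#' Orthogonal (one-hot) encoding of a peptide window
#'
#' Each window position maps to a 20-slot 0/1 block in fixed alphabetical
#' residue order, giving 20*w dimensions: 100 for PDZ 5-mers, 120 for SH2
#' pY-context 6-mers. The encoding is injective on window sequences.
#'
#' @param window Window-length peptide sequence (see [peptide_window()]).
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @return Binary numeric vector of length `20 * window_width(window_kind)`.
#' @export
encode_peptide <- function(window, window_kind) {
  w <- window_width(window_kind)
  if (nchar(window) != w)
    stop("WindowMismatch: expected a ", w, "-residue window", call. = FALSE)
  .check_alphabet(window, "peptide")
  idx <- match(strsplit(window, "")[[1L]], AA_ALPHABET)
  v <- numeric(20L * w)
  v[(seq_len(w) - 1L) * 20L + idx] <- 1
  v
}

# rows = peptides, cols = 20*w encoding dimensions
encode_matrix <- function(windows, window_kind) {
  t(vapply(windows, encode_peptide, numeric(20L * window_width(window_kind)),
           window_kind = window_kind, USE.NAMES = FALSE))
}

#' Sample negative training windows from a background proteome
#'
#' Binders of other family domains cannot be presumed negative for a query
#' (low-identity pairs still share ligands), so negatives are drawn from a
#' background proteome instead: for PDZ, the 5-residue C-termini of sampled
#' proteins; for SH2, 6-residue pY-context windows around tyrosines. Sampling
#' is without replacement over distinct windows, windows in `exclude` (known
#' positives of the candidate pool) are skipped, and the draw is fully
#' determined by `seed`.
#'
#' @param background Named character vector of protein sequences.
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param n Number of negatives required.
#' @param exclude Window sequences that must not appear among negatives.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct windows.
#' @export
sample_negatives <- function(background, window_kind, n,
                             exclude = character(), seed = 20110) {
  wins <- extract_windows(background, window_kind)$window
  pool <- setdiff(unique(wins), exclude)
  if (length(pool) < n)
    stop("InsufficientBackground: ", length(pool), " candidate windows < ",
         n, call. = FALSE)
  set.seed(seed)
  sample(pool, n)
}

#' Train a linear SVM binding model
#'
#' Fits a soft-margin linear-kernel SVM on orthogonally encoded peptides and
#' stores the explicit linear decision function (weights and bias), so
#' scoring reduces to a dot product. Deterministic given the training set
#' and `C`.
#'
#' @param positives,negatives Character vectors of window sequences.
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param C Soft-margin cost, default 1.
#' @param domain Domain id recorded on the model.
#' @param domain_sequence Optional amino-acid sequence of the domain (used by
#'   [substitute_model_lookup()]).
#' @param training_domains Ids whose binders were pooled as positives.
#' @param seed Seed recorded on the model (negative sampling provenance).
#' @return A `binding_model`: `weights`, `bias`, `window_kind`, `family`,
#'   `domain`, `training_domains`, `n_pos`, `n_neg`, `C`, `loocv`,
#'   `score_stats`, `seed`.
#' @export
train_svm <- function(positives, negatives, window_kind, C = 1.0,
                      domain = NA_character_, domain_sequence = NULL,
                      training_domains = domain, seed = NA_integer_) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("DegenerateTraining: need both positive and negative peptides",
         call. = FALSE)
  x <- rbind(encode_matrix(positives, window_kind),
             encode_matrix(negatives, window_kind))
  y <- factor(rep(c("pos", "neg"), c(length(positives), length(negatives))),
              levels = c("pos", "neg"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function by the first label it encounters;
  # flip so positives score high
  if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
  structure(list(weights = w, bias = b, window_kind = window_kind,
                 family = window_family(window_kind),
                 domain = domain, domain_sequence = domain_sequence,
                 training_domains = training_domains,
                 n_pos = length(positives), n_neg = length(negatives),
                 C = C, loocv = NA_real_, score_stats = NULL, seed = seed),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf(
    "binding_model: %s (%s), %d pos / %d neg, pooled domains: %s%s\n",
    x$domain, x$family, x$n_pos, x$n_neg,
    paste(x$training_domains, collapse = ","),
    if (is.na(x$loocv)) "" else sprintf(", LOOCV %.3f", x$loocv)))
  invisible(x)
}

#' Score peptide windows with a binding model
#'
#' @param model A `binding_model`.
#' @param windows Character vector of window sequences.
#' @return Numeric decision values (higher = more likely to bind).
#' @export
score_windows <- function(model, windows) {
  stopifnot(inherits(model, "binding_model"))
  drop(encode_matrix(windows, model$window_kind) %*% model$weights) +
    model$bias
}

#' Leave-one-out cross-validation score of a training set
#'
#' Each labeled peptide is held out in turn, the SVM is refit on the rest,
#' and the held-out decision value is recorded; the score is the AROC of
#' those held-out values against the labels. AROC is used rather than raw
#' classification accuracy because accuracy is degenerate at the 5:1 class
#' imbalance of these training sets (the all-negative classifier already
#' scores 0.83); `measure = "accuracy"` is available for comparison.
#'
#' @param positives,negatives Character vectors of window sequences
#'   (`length(positives) >= 3`).
#' @param window_kind `"PDZ_CTERM"` or `"SH2_PY"`.
#' @param C Soft-margin cost.
#' @param measure `"aroc"` (default) or `"accuracy"`.
#' @return Score in `[0, 1]`.
#' @export
loocv_score <- function(positives, negatives, window_kind, C = 1.0,
                        measure = c("aroc", "accuracy")) {
  measure <- match.arg(measure)
  if (length(positives) < 3L)
    stop("TooFewPositives: need >= 3 positive peptides", call. = FALSE)
  if (length(negatives) < 1L)
    stop("DegenerateTraining: need negative peptides", call. = FALSE)
  x <- rbind(encode_matrix(positives, window_kind),
             encode_matrix(negatives, window_kind))
  y <- rep(c(TRUE, FALSE), c(length(positives), length(negatives)))
  n <- nrow(x)
  held <- numeric(n)
  for (i in seq_len(n)) {
    yi <- factor(ifelse(y[-i], "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(x[-i, , drop = FALSE], yi, kernel = "linear",
                      cost = C, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV); b <- -fit$rho
    if (fit$labels[1L] != 1L) { w <- -w; b <- -b }
    held[i] <- sum(x[i, ] * w) + b
  }
  if (measure == "aroc") aroc(held, y)$aroc
  else mean((held > 0) == y)
}

#' Build the final binding model for a query domain
#'
#' Candidate models are trained on nested positive pools following the
#' similarity group's member order: the query alone, then the query plus the
#' first member, plus the second, and so on; each pool's positives are the
#' union of member binders, and negatives are resampled per pool at
#' `neg_ratio`:1 from the background with a seed derived from `seed`
#' (negatives are screened against the current pool's positives only). Each
#' candidate is scored by [loocv_score()] and the best is retained; ties go
#' to the candidate with fewer pooled domains, so the selected model is never
#' strictly worse than the query-only model.
#'
#' @param query Query domain id (must have >= 3 binders in `table`).
#' @param group A `similarity_group` from [find_similar_domains()] (or
#'   `NULL` for query-only training).
#' @param table An [interaction_table()].
#' @param background Named character vector of background protein sequences.
#' @param neg_ratio Negatives per positive, default 5.
#' @param C Soft-margin cost, default 1.
#' @param seed Base seed for negative sampling, default 20110.
#' @param domain_sequence Optional query domain sequence to record.
#' @return A `binding_model` with `loocv` set; the attribute `candidates`
#'   holds the per-pool LOOCV scores.
#' @export
build_dompep_model <- function(query, group, table, background,
                               neg_ratio = 5, C = 1.0, seed = 20110,
                               domain_sequence = NULL) {
  stopifnot(inherits(table, "interaction_table"))
  q_pos <- binders(table, query)
  if (length(q_pos) < 3L)
    stop("TooFewPositives: query has ", length(q_pos),
         " binders (< 3)", call. = FALSE)
  members <- if (is.null(group)) character() else
    intersect(group$members, table$domains)
  pools <- lapply(0:length(members), function(k) {
    doms <- c(query, head(members, k))
    list(domains = doms,
         positives = unique(unlist(lapply(doms, binders, table = table))))
  })
  cand <- lapply(seq_along(pools), function(k) {
    p <- pools[[k]]
    negs <- sample_negatives(background, table$window_kind,
                             round(neg_ratio * length(p$positives)),
                             exclude = p$positives, seed = seed + k)
    sc <- loocv_score(p$positives, negs, table$window_kind, C = C)
    list(pool = p, negatives = negs, loocv = sc)
  })
  scores <- vapply(cand, `[[`, numeric(1L), "loocv")
  best <- which.max(scores)  # first max: ties favor fewer pooled domains
  .dompep_log("model selection for %s: LOOCV %s -> pool of %d domain(s)",
              query, paste(sprintf("%.3f", scores), collapse = "/"),
              length(cand[[best]]$pool$domains))
  model <- train_svm(cand[[best]]$pool$positives, cand[[best]]$negatives,
                     table$window_kind, C = C, domain = query,
                     domain_sequence = domain_sequence,
                     training_domains = cand[[best]]$pool$domains,
                     seed = seed)
  model$loocv <- scores[best]
  attr(model, "candidates") <- data.frame(
    n_domains = vapply(cand, function(cc) length(cc$pool$domains),
                       integer(1L)),
    n_pos = vapply(cand, function(cc) length(cc$pool$positives),
                   integer(1L)),
    loocv = scores)
  model
}

#' Serialize a binding model to JSON
#'
#' @param model A `binding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  obj <- unclass(model)
  obj$schema <- "dompep-model/1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a binding model from JSON
#' @param path Path written by [write_binding_model()].
#' @return A `binding_model`.
#' @export
read_binding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "dompep-model/1"))
    stop("ParseError: not a dompep model file: ", path, call. = FALSE)
  obj$schema <- NULL
  obj$weights <- as.numeric(obj$weights)
  obj$score_stats <- if (length(obj$score_stats))
    as.numeric(obj$score_stats) else NULL
  structure(obj, class = "binding_model")
}
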