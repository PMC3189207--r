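# Seeded synthetic data: domain families with planted specificity groups,
# domain-peptide arrays with known ground truth, and background proteomes.
# Structure, not biological realism, is the goal: these fixtures exist so
# that metric calibration, grouping and model building can be tested for
# recovery of planted signal without any external download.

# Background amino-acid frequencies (Robinson-Robinson style composition
# table), order = AA_ALPHABET.
AA_BACKGROUND_FREQ <- local({
  f <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0397,
         G = 0.0738, H = 0.0219, I = 0.0514, K = 0.0572, L = 0.0901,
         M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
         S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0133, Y = 0.0321)
  f / sum(f)
})

.sample_aa <- function(n, freq = AA_BACKGROUND_FREQ) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = freq)
}

#' Specification of a synthetic domain family
#'
#' Defaults emulate the structure (not the scale) of the published array
#' panels: a PDZ-style family of 8 domains in 2 specificity groups, 40
#' binders per domain among a 220-peptide array, and a 2,000-protein
#' background proteome for negative sampling.
#'
#' @param family `"PDZ"` or `"SH2"`.
#' @param n_domains,n_groups Family size and number of planted specificity
#'   groups (`n_groups <= n_domains`).
#' @param binders_per_domain Peptides bound per domain (before label noise).
#' @param n_array_peptides Array size; half the peptides are drawn from the
#'   planted group PWMs, half from background composition.
#' @param concentration Dirichlet-style sharpness of the planted PWMs'
#'   residue preferences (larger = sharper motifs).
#' @param identity_within,identity_between Target pairwise sequence identity
#'   (fractions) within and between groups; domain sequences are evolved
#'   from per-group ancestors by seeded point mutations whose rates are set
#'   by expected-identity calibration (identity ~ fraction unmutated), so
#'   realized DSI lands within a few points of the target.
#' @param domain_length Length of the synthetic domain sequences.
#' @param label_noise Per-cell outcome flip rate, default 0.02 -- array
#'   screens carry a small false-positive/negative rate, and recovery tests
#'   should tolerate it.
#' @param background_size Number of background proteins.
#' @param background_length_range Protein length range, default 80-300.
#' @param seed Integer seed; every downstream draw is determined by it.
#' @return A validated `synthetic_family_spec` list.
#' @export
synthetic_family_spec <- function(family = "PDZ", n_domains = 8,
                                  n_groups = 2, binders_per_domain = 40,
                                  n_array_peptides = 220,
                                  concentration = 10,
                                  identity_within = 0.70,
                                  identity_between = 0.30,
                                  domain_length = 90,
                                  label_noise = 0.02,
                                  background_size = 2000,
                                  background_length_range = c(80, 300),
                                  seed = 1) {
  family <- match.arg(family, c("PDZ", "SH2"))
  if (n_groups > n_domains)
    stop("SpecError: n_groups must not exceed n_domains", call. = FALSE)
  if (identity_within <= identity_between)
    stop("SpecError: identity_within must exceed identity_between",
         call. = FALSE)
  stopifnot(n_domains > 0, binders_per_domain > 0, n_array_peptides > 0,
            background_size >= 0, label_noise >= 0, label_noise < 0.5,
            concentration > 0)
  structure(as.list(environment()), class = "synthetic_family_spec")
}

.mutate_seq <- function(chars, rate) {
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit],
                   function(a) sample(setdiff(AA_ALPHABET, a), 1L),
                   character(1L))
    chars[hit] <- repl
  }
  chars
}

# sharp position-specific residue preferences for one group: gamma draws
# with a boosted shape on `n_pref` randomly preferred residues per position
.planted_pwm <- function(w, concentration, n_pref = 2L) {
  freq <- matrix(0, w, 20L, dimnames = list(paste0("pos", seq_len(w)),
                                            AA_ALPHABET))
  for (i in seq_len(w)) {
    alpha <- rep(0.05, 20L)
    alpha[sample.int(20L, n_pref)] <- concentration
    g <- rgamma(20L, shape = alpha)
    freq[i, ] <- g / sum(g)
  }
  freq
}

.sample_from_pwm <- function(n, freq) {
  w <- nrow(freq)
  apply(vapply(seq_len(w),
               function(i) sample(AA_ALPHABET, n, TRUE, prob = freq[i, ]),
               character(n)), 1L, paste, collapse = "")
}

#' Generate a background proteome
#'
#' Uniform-composition proteins with natural amino-acid frequencies (the
#' bundled Robinson-Robinson style table); lengths uniform over
#' `length_range`; fully seed-deterministic.
#'
#' @param n Number of proteins (0 allowed).
#' @param length_range Integer length range, default `c(80, 300)`.
#' @param seed Integer seed.
#' @return Named character vector (`bg00001`, ...).
#' @export
generate_background <- function(n, length_range = c(80, 300), seed = 1) {
  set.seed(seed)
  if (n == 0L) return(setNames(character(), character()))
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seqs <- vapply(lens, function(l) paste(.sample_aa(l), collapse = ""),
                 character(1L))
  setNames(seqs, sprintf("bg%05d", seq_len(n)))
}

#' Generate a synthetic domain family with planted specificity groups
#'
#' Domain sequences are evolved from per-group ancestors (themselves mutated
#' copies of a common root) by seeded point mutations calibrated to the
#' spec's identity targets. Array peptides are drawn half from the planted
#' group PWMs and half from background composition; a domain binds the
#' `binders_per_domain` peptides with the highest log-likelihood under its
#' group's PWM (relative to background, plus a small per-domain jitter so
#' same-group domains overlap strongly without being identical), after which
#' each outcome cell is flipped with probability `label_noise`.
#'
#' @param spec A [synthetic_family_spec()].
#' @return List: `domain_seqs` (named character), `table` (an
#'   [interaction_table()]), `background` (named character),
#'   `groups` (named integer vector: planted group of each domain),
#'   `planted_pwms` (list of w x 20 frequency matrices).
#' @export
generate_family <- function(spec = synthetic_family_spec()) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  set.seed(spec$seed)
  window_kind <- family_window_kind(spec$family)
  w <- window_width(window_kind)

  # domain sequences: root -> group ancestors -> domains; a pair of
  # sequences independently mutated at rate r keeps ~(1-r)^2 of its sites,
  # so rates are set from the square roots of the identity targets
  r_w <- 1 - sqrt(spec$identity_within)
  r_b <- 1 - sqrt(spec$identity_between / spec$identity_within)
  root <- .sample_aa(spec$domain_length)
  ancestors <- lapply(seq_len(spec$n_groups),
                      function(g) .mutate_seq(root, r_b))
  groups <- sort(rep_len(seq_len(spec$n_groups), spec$n_domains))
  ids <- sprintf("D%02d", seq_len(spec$n_domains))
  domain_seqs <- setNames(vapply(seq_len(spec$n_domains), function(i) {
    paste(.mutate_seq(ancestors[[groups[i]]], r_w), collapse = "")
  }, character(1L)), ids)
  names(groups) <- ids

  # planted per-group motifs and the array peptide panel
  pwms <- lapply(seq_len(spec$n_groups),
                 function(g) .planted_pwm(w, spec$concentration))
  n_planted <- spec$n_array_peptides %/% 2L
  per_group <- rep_len(n_planted %/% spec$n_groups, spec$n_groups)
  planted <- unlist(lapply(seq_len(spec$n_groups),
                           function(g) .sample_from_pwm(per_group[g],
                                                        pwms[[g]])))
  random <- .sample_from_pwm(spec$n_array_peptides - length(planted),
                             matrix(rep(AA_BACKGROUND_FREQ, each = w), w,
                                    dimnames = list(NULL, AA_ALPHABET)))
  peptides <- unique(c(planted, random))

  # outcomes: per-domain top-k log-likelihood ratio, jittered, then noised
  ll <- vapply(seq_len(spec$n_groups), function(g) {
    vapply(strsplit(peptides, ""), function(p)
      sum(log(pmax(pwms[[g]][cbind(seq_len(w), match(p, AA_ALPHABET))],
                   1e-6) / AA_BACKGROUND_FREQ[p])), numeric(1L))
  }, numeric(length(peptides)))
  k <- min(spec$binders_per_domain, length(peptides))
  outcomes <- vapply(seq_len(spec$n_domains), function(i) {
    jit <- ll[, groups[i]] + rnorm(length(peptides), 0, 0.5)
    out <- rep("UNBOUND", length(peptides))
    out[order(jit, decreasing = TRUE)[seq_len(k)]] <- "BOUND"
    flip <- runif(length(peptides)) < spec$label_noise
    out[flip] <- ifelse(out[flip] == "BOUND", "UNBOUND", "BOUND")
    out
  }, character(length(peptides)))
  colnames(outcomes) <- ids

  background <- generate_background(spec$background_size,
                                    spec$background_length_range,
                                    seed = spec$seed + 1L)
  list(domain_seqs = domain_seqs,
       table = interaction_table(data.frame(sequence = peptides), outcomes,
                                 window_kind),
       background = background, groups = groups, planted_pwms = pwms)
}
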