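# Shared fixtures and test-only utilities.

# md5 of the bundled Scrib panel TSV, frozen after row-by-row verification
TABLE1_MD5 <- "63c63994da28f57c5bfbd3a25f6baff1"

# inverse of encode_peptide, implemented only here so encoding tests have an
# independent round-trip check
decode_peptide <- function(v, window_kind) {
  w <- window_width(window_kind)
  stopifnot(length(v) == 20L * w)
  paste(vapply(seq_len(w), function(i) {
    block <- v[((i - 1L) * 20L + 1L):(i * 20L)]
    dompep:::AA_ALPHABET[which(block == 1)]
  }, character(1L)), collapse = "")
}

# random window sequences under background composition
random_windows <- function(n, w) {
  vapply(seq_len(n), function(i)
    paste(sample(dompep:::AA_ALPHABET, w, replace = TRUE,
                 prob = dompep:::AA_BACKGROUND_FREQ), collapse = ""),
    character(1L))
}

# a tiny 3-domain binary interaction table: D1 and D2 have identical binder
# sets (12 peptides each), D3 binds a disjoint dozen
tiny_planted_table <- function() {
  set.seed(42)
  shared <- do.call(paste0, expand.grid(c("E", "S", "T"), "T",
                                        c("D", "E"), c("V", "L"), "V"))
  other <- unique(random_windows(40, 5))
  other <- setdiff(other, shared)[1:12]
  peps <- c(shared, other)
  out <- matrix("UNBOUND", length(peps), 3,
                dimnames = list(NULL, c("D1", "D2", "D3")))
  out[seq_along(shared), c("D1", "D2")] <- "BOUND"
  out[length(shared) + seq_along(other), "D3"] <- "BOUND"
  interaction_table(data.frame(sequence = peps), out, "PDZ_CTERM")
}

# deterministic metrics table with planted PDZ-style calibration structure:
# same-group pairs sit at DSI 50-75 / PWM 0.10-0.25 with high LBS, cross
# pairs at DSI 10-45 / PWM 0.45-0.90 with low LBS
planted_metrics <- function(n_same = 40, n_cross = 60, seed = 1) {
  set.seed(seed)
  same <- data.frame(
    domain_i = sprintf("s%02da", seq_len(n_same)),
    domain_j = sprintf("s%02db", seq_len(n_same)),
    n_cotested = 100L,
    lbs = pmin(1, 0.85 + rnorm(n_same, 0, 0.04)),
    lbs_variant = "standard",
    dsi = runif(n_same, 50, 75),
    pwm_distance = runif(n_same, 0.10, 0.25))
  cross <- data.frame(
    domain_i = sprintf("c%02da", seq_len(n_cross)),
    domain_j = sprintf("c%02db", seq_len(n_cross)),
    n_cotested = 100L,
    lbs = pmax(0, 0.35 + rnorm(n_cross, 0, 0.08)),
    lbs_variant = "standard",
    dsi = runif(n_cross, 10, 45),
    pwm_distance = runif(n_cross, 0.45, 0.90))
  rbind(same, cross)
}

# mutate an amino-acid sequence at a fixed number of positions
mutate_at <- function(seq, k, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(ch), k)
  ch[idx] <- vapply(ch[idx], function(a)
    sample(setdiff(dompep:::AA_ALPHABET, a), 1), character(1))
  paste(ch, collapse = "")
}
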