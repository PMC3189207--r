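test_that("orthogonal encoding places one hot bit per 20-slot position block", {
  v <- encode_peptide("AAAAA", "PDZ_CTERM")
  expect_length(v, 100)
  expect_equal(which(v == 1), c(1, 21, 41, 61, 81))  # A is residue index 1
  v2 <- encode_peptide("YYYYYY", "SH2_PY")
  expect_length(v2, 120)
  expect_equal(sum(v2), 6)
  expect_equal(which(v2 == 1), seq(20, 120, by = 20))  # Y is residue 20
  expect_error(encode_peptide("AAAA", "PDZ_CTERM"), "WindowMismatch")
  expect_error(encode_peptide("AAAXZ", "PDZ_CTERM"), "AlphabetError")
})

test_that("encoding is injective and round-trips through the test decoder", {
  set.seed(14)
  wins <- unique(random_windows(1200, 5))[1:1000]
  mat <- t(vapply(wins, encode_peptide, numeric(100),
                  window_kind = "PDZ_CTERM"))
  expect_equal(nrow(unique(mat)), 1000L)
  for (w in wins[1:25])
    expect_equal(decode_peptide(encode_peptide(w, "PDZ_CTERM"),
                                "PDZ_CTERM"), w)
})

test_that("negative sampling honors exclusion, count and determinism", {
  bg <- generate_background(400, seed = 6)
  excl <- extract_windows(bg, "PDZ_CTERM")$window[1:20]
  negs <- sample_negatives(bg, "PDZ_CTERM", 10, exclude = excl, seed = 1)
  expect_length(negs, 10)
  expect_length(unique(negs), 10)
  expect_length(intersect(negs, excl), 0)
  expect_identical(sample_negatives(bg, "PDZ_CTERM", 10, excl, seed = 1),
                   negs)
  expect_false(identical(sample_negatives(bg, "PDZ_CTERM", 10, excl, 2),
                         negs))
  # the 5:1 ratio for a 30-positive domain
  expect_length(sample_negatives(bg, "PDZ_CTERM", 5 * 30, seed = 3), 150)
  expect_error(sample_negatives(bg[1:3], "PDZ_CTERM", 10),
               "InsufficientBackground")
})

test_that("a linear SVM separates a separable toy set and stores its geometry", {
  set.seed(15)
  pos <- paste0(sample(c("E", "S", "T"), 30, TRUE), "T",
                sample(c("D", "E"), 30, TRUE), "V",
                sample(c("V", "L"), 30, TRUE))
  neg <- setdiff(unique(random_windows(200, 5)), pos)[1:100]
  m <- train_svm(unique(pos), neg, "PDZ_CTERM", domain = "toy")
  expect_s3_class(m, "binding_model")
  expect_length(m$weights, 100)
  sp <- score_windows(m, unique(pos))
  sn <- score_windows(m, neg)
  expect_true(min(sp) > max(sn))            # every positive above every negative
  expect_equal(mean(c(sp > 0, sn < 0)), 1)  # training accuracy 1
  expect_error(train_svm(character(), neg, "PDZ_CTERM"),
               "DegenerateTraining")
})

test_that("LOOCV returns 1 on separable data and chance on shuffled labels", {
  set.seed(16)
  pos <- unique(paste0(sample(c("E", "S", "T", "Q"), 20, TRUE), "TDV",
                       sample(c("V", "L"), 20, TRUE)))
  neg <- setdiff(unique(random_windows(80, 5)), pos)[1:40]
  expect_equal(loocv_score(pos, neg, "PDZ_CTERM"), 1)
  expect_error(loocv_score(pos[1:2], neg, "PDZ_CTERM"), "TooFewPositives")
  # permutation null: shuffle which windows are called positive
  all_w <- c(pos, neg)
  null_scores <- vapply(1:20, function(s) {
    set.seed(100 + s)
    lab <- sample(seq_along(all_w)) <= 8
    loocv_score(all_w[which(lab)], all_w[which(!lab)], "PDZ_CTERM")
  }, numeric(1))
  expect_equal(mean(null_scores), 0.5, tolerance = 0.2)
})

test_that("pooling specificity-similar positives does not hurt LOOCV on a shared motif", {
  improved <- vapply(1:20, function(s) {
    set.seed(200 + s)
    motif <- function(n) paste0(sample(c("E", "S", "T", "Q", "N"), n, TRUE),
                                sample(c("T", "S"), n, TRUE),
                                sample(c("D", "E"), n, TRUE),
                                sample(c("V", "L"), n, TRUE), "V")
    q_pos <- unique(motif(30))[1:4]
    nb_pos <- setdiff(unique(motif(200)), q_pos)[1:30]
    negs <- setdiff(unique(random_windows(400, 5)),
                    c(q_pos, nb_pos))
    solo <- loocv_score(q_pos, negs[1:20], "PDZ_CTERM")
    pooled <- loocv_score(c(q_pos, nb_pos), negs[1:170], "PDZ_CTERM")
    pooled - solo
  }, numeric(1))
  expect_gte(mean(improved >= 0), 0.9)
  expect_gt(mean(improved), 0)
})

test_that("model selection over nested pools never falls below the query-only model", {
  fam <- generate_family(synthetic_family_spec(seed = 31))
  g <- find_similar_domains("D01", fam$domain_seqs, fam$table,
                            default_threshold_rule("PDZ"))
  m <- build_dompep_model("D01", g, fam$table, fam$background, seed = 77)
  cand <- attr(m, "candidates")
  expect_gte(m$loocv, cand$loocv[1])     # candidate 1 is the query alone
  expect_equal(m$loocv, max(cand$loocv))
  expect_equal(cand$n_domains[1], 1L)
  # empty group: trains on the query peptides only
  m0 <- build_dompep_model("D01", NULL, fam$table, fam$background, seed = 77)
  expect_equal(m0$training_domains, "D01")
  expect_equal(attr(m0, "candidates")$n_domains, 1L)
  # fewer than three positives is an error
  tab <- fam$table
  tab$outcomes[, "D02"] <- "UNBOUND"
  tab$outcomes[1:2, "D02"] <- "BOUND"
  expect_error(build_dompep_model("D02", NULL, tab, fam$background),
               "TooFewPositives")
})

test_that("the full training pipeline is bit-reproducible under a fixed seed", {
  run <- function() {
    fam <- generate_family(synthetic_family_spec(seed = 12))
    rule <- default_threshold_rule("PDZ")
    g <- find_similar_domains("D05", fam$domain_seqs, fam$table, rule)
    build_dompep_model("D05", g, fam$table, fam$background, seed = 55)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  expect_identical(m1$loocv, m2$loocv)
  expect_identical(attr(m1, "candidates"), attr(m2, "candidates"))
})

test_that("per-domain models recover planted specificity in held-out AROC", {
  ok <- vapply(1:20, function(s) {
    fam <- generate_family(synthetic_family_spec(seed = 3000 + s))
    arocs <- vapply(names(fam$domain_seqs), function(d) {
      pos <- binders(fam$table, d)
      negs <- sample_negatives(fam$background, "PDZ_CTERM",
                               5 * length(pos), exclude = pos,
                               seed = s)
      m <- train_svm(pos, negs, "PDZ_CTERM", domain = d)
      # held-out: fresh peptides from the planted group PWM vs background
      set.seed(s)
      g <- fam$groups[d]
      hp <- dompep:::.sample_from_pwm(100, fam$planted_pwms[[g]])
      hn <- random_windows(300, 5)
      aroc(score_windows(m, c(hp, hn)),
           rep(c(TRUE, FALSE), c(100, 300)))$aroc
    }, numeric(1))
    all(arocs >= 0.9)
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("binding models serialize to JSON and back", {
  set.seed(17)
  m <- train_svm(c("AETDV", "SETDV", "TETDV"), random_windows(15, 5),
                 "PDZ_CTERM", domain = "d1", domain_sequence = "MKVLAT",
                 seed = 9L)
  p <- tempfile(fileext = ".json")
  write_binding_model(m, p)
  m2 <- read_binding_model(p)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$domain, "d1")
  expect_equal(score_windows(m2, "AETDV"), score_windows(m, "AETDV"))
  expect_error(read_binding_model(system.file("extdata",
                                              "scrib_pdz_table1.tsv",
                                              package = "dompep")))
})
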