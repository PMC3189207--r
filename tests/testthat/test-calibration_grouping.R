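test_that("calibration on planted PDZ-style metrics recovers the published rule shape", {
  m <- planted_metrics()
  rule <- calibrate_thresholds(m, lbs_cutoff = 0.7, family = "PDZ",
                               min_pairs = 3)
  expect_s3_class(rule, "threshold_rule")
  expect_false(rule$insufficient)
  dsi_cl <- Filter(function(cl) !is.null(cl$dsi_min) && is.null(cl$pwm_max),
                   rule$clauses)
  pwm_cl <- Filter(function(cl) is.null(cl$dsi_min) && !is.null(cl$pwm_max),
                   rule$clauses)
  expect_length(dsi_cl, 1)
  expect_length(pwm_cl, 1)
  expect_equal(dsi_cl[[1]]$dsi_min, 50)
  expect_equal(pwm_cl[[1]]$pwm_max, 0.3)
})

test_that("degenerate calibration with uniformly high LBS loosens to the outermost bins", {
  set.seed(2)
  m <- planted_metrics()
  m$lbs <- 1  # every pair fully overlapping
  rule <- calibrate_thresholds(m, family = "PDZ", min_pairs = 1)
  dsi_min <- min(unlist(lapply(rule$clauses, `[[`, "dsi_min")))
  pwm_max <- max(unlist(lapply(rule$clauses, `[[`, "pwm_max")))
  expect_equal(dsi_min, 0)
  expect_equal(pwm_max, 0.9)  # loosest populated distance edge
})

test_that("LBS-shuffled metrics yield an insufficient-data rule", {
  m <- planted_metrics()
  for (s in 1:20) {
    set.seed(s)
    m$lbs <- sample(m$lbs)  # break the LBS/DSI and LBS/PWM relationships
    rule <- calibrate_thresholds(m, family = "PDZ", min_pairs = 3)
    expect_true(rule$insufficient)
    expect_length(rule$clauses, 0)
  }
})

test_that("raising the LBS cutoff never loosens a threshold", {
  m <- planted_metrics()
  r1 <- calibrate_thresholds(m, lbs_cutoff = 0.7, family = "PDZ",
                             min_pairs = 3)
  r2 <- calibrate_thresholds(m, lbs_cutoff = 0.8, family = "PDZ",
                             min_pairs = 3)
  bound <- function(r, f, worst) {
    v <- unlist(lapply(r$clauses, `[[`, f))
    if (length(v)) v else worst
  }
  expect_gte(min(bound(r2, "dsi_min", Inf)), min(bound(r1, "dsi_min", Inf)))
  expect_lte(max(bound(r2, "pwm_max", -Inf)), max(bound(r1, "pwm_max", -Inf)))
})

test_that("compound clauses appear when a DSI band qualifies only jointly with PWM", {
  # SH2-like structure: DSI>=60 always high LBS; DSI 40-59 high LBS only at
  # small PWM distance; below 40 never
  set.seed(9)
  mk <- function(n, dsi_rng, pwm_rng, lbs_mu) data.frame(
    domain_i = paste0("a", seq_len(n)), domain_j = paste0("b", seq_len(n)),
    n_cotested = 100L, lbs = pmin(1, pmax(0, lbs_mu + rnorm(n, 0, 0.03))),
    lbs_variant = "min_denominator",
    dsi = runif(n, dsi_rng[1], dsi_rng[2]),
    pwm_distance = runif(n, pwm_rng[1], pwm_rng[2]))
  m <- rbind(mk(30, c(60, 90), c(0.02, 0.09), 0.92),
             mk(30, c(40, 59), c(0.10, 0.29), 0.80),
             mk(30, c(40, 59), c(0.35, 0.80), 0.40),
             mk(30, c(5, 39), c(0.10, 0.30), 0.30),
             mk(40, c(5, 39), c(0.30, 0.90), 0.25))
  rule <- calibrate_thresholds(m, family = "SH2", min_pairs = 3)
  comp <- Filter(function(cl) !is.null(cl$dsi_min) && !is.null(cl$pwm_max),
                 rule$clauses)
  expect_length(comp, 1)
  expect_equal(comp[[1]]$dsi_min, 40)
  expect_equal(comp[[1]]$pwm_max, 0.3)
  expect_equal(Filter(function(cl) !is.null(cl$dsi_min) &&
                        is.null(cl$pwm_max), rule$clauses)[[1]]$dsi_min, 60)
  expect_equal(Filter(function(cl) is.null(cl$dsi_min) &&
                        !is.null(cl$pwm_max), rule$clauses)[[1]]$pwm_max, 0.1)
})

test_that("shipped default rules encode the published per-family clauses", {
  pdz <- default_threshold_rule("PDZ")
  expect_length(rule_admits(pdz, dsi = 55, NA), 1)
  expect_length(rule_admits(pdz, dsi = 20, 0.16), 1)  # PWM clause only
  expect_length(rule_admits(pdz, dsi = 20, 0.4), 0)
  sh2 <- default_threshold_rule("SH2")
  expect_true(length(rule_admits(sh2, 65, NA)) > 0)
  expect_true(length(rule_admits(sh2, 20, 0.05)) > 0)
  expect_true(length(rule_admits(sh2, 45, 0.2)) > 0)   # compound clause
  expect_length(rule_admits(sh2, 45, 0.35), 0)
  expect_length(rule_admits(sh2, 30, 0.2), 0)
})

test_that("similarity grouping admits by DSI, by PWM distance, or not at all", {
  tab <- tiny_planted_table()
  base <- paste(rep(c("MKVLATGGSP"), 6), collapse = "")  # length 60
  seqs <- c(Q = base,
            # ~80% identical family member, no binding data needed
            HI = mutate_at(base, 12, seed = 1),
            # unrelated sequence but identical binder set to the query
            LO = paste(sample(strsplit(base, "")[[1]]), collapse = ""))
  # Q and LO share all binders (copy D1/D2 planted identity), HI has none
  colnames(tab$outcomes) <- c("Q", "LO", "HI")
  tab$domains <- colnames(tab$outcomes)
  rule <- default_threshold_rule("PDZ")
  g <- find_similar_domains("Q", seqs, tab, rule)
  expect_s3_class(g, "similarity_group")
  expect_true(all(c("HI", "LO") %in% g$members))
  ev <- g$evidence
  # the low-identity member is admitted by the PWM clause only
  lo <- ev[ev$member == "LO", ]
  expect_lt(lo$dsi, 50)
  expect_lt(lo$pwm_distance, 0.3)
  expect_equal(lo$clauses[[1]], 2L)
  # the high-identity member is admitted by the DSI clause
  expect_true(1L %in% ev$clauses[[which(ev$member == "HI")]])
  # members with PWM evidence order before PWM-undefined ones
  expect_equal(g$members[1], "LO")
  # no member passes any clause -> empty group
  g0 <- find_similar_domains("Q", c(Q = base, ZZ = seqs[["LO"]]), NULL, rule)
  expect_length(g0$members, 0)
  expect_error(find_similar_domains("nope", seqs, tab, rule),
               "MissingSequence")
})

test_that("similarity-group evidence re-evaluates true against stored metrics", {
  fam <- generate_family(synthetic_family_spec(seed = 3))
  rule <- default_threshold_rule("PDZ")
  for (q in names(fam$domain_seqs)[1:3]) {
    g <- find_similar_domains(q, fam$domain_seqs, fam$table, rule)
    for (i in seq_along(g$members)) {
      ev <- g$evidence[i, ]
      expect_equal(sort(rule_admits(rule, ev$dsi, ev$pwm_distance)),
                   sort(ev$clauses[[1]]))
    }
  }
})

test_that("grouping recovers planted specificity groups across seeds", {
  rule <- default_threshold_rule("PDZ")
  hits <- misses <- cross <- 0
  for (s in 1:20) {
    fam <- generate_family(synthetic_family_spec(seed = 1000 + s))
    for (q in names(fam$domain_seqs)) {
      g <- find_similar_domains(q, fam$domain_seqs, fam$table, rule)
      mates <- setdiff(names(fam$groups)[fam$groups == fam$groups[q]], q)
      hits <- hits + length(intersect(g$members, mates))
      misses <- misses + length(setdiff(mates, g$members))
      cross <- cross + length(setdiff(g$members, mates))
    }
  }
  expect_gte(hits / (hits + misses), 0.90)
  expect_lt(cross / (hits + cross), 0.05)
})

test_that("substitute-model lookup ranks by DSI and flags sub-recommended hits", {
  base <- paste(rep("MKVLATGGSP", 9), collapse = "")  # length 90
  mk_model <- function(id, seq) {
    m <- train_svm(c("AETDV", "SETDV", "TETDV"), random_windows(15, 5),
                   "PDZ_CTERM", domain = id, domain_sequence = seq)
    m
  }
  set.seed(4)
  store <- c(
    list(mk_model("exact", base), mk_model("far", mutate_at(base, 55, 2))),
    lapply(1:12, function(i) mk_model(paste0("mid", i),
                                      mutate_at(base, 28, seed = 10 + i))))
  res <- substitute_model_lookup(base, store)
  expect_equal(res$model[1], "exact")
  expect_equal(res$dsi[1], 100)
  expect_true(res$recommended[1])
  expect_lte(nrow(res), 10)          # top-k truncation with 13 candidates
  expect_true(all(diff(res$dsi) <= 0))
  expect_true(all(res$dsi >= 40))
  # a hit in the 40-50 band is listed but flagged below the PDZ guidance
  mid <- res[res$dsi < 50, ]
  if (nrow(mid)) expect_false(any(mid$recommended))
})
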