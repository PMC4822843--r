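test_that("profile construction follows the match-column and pseudocount rules", {
  ## single sequence, near-zero pseudocount: deterministic emissions
  m <- build_profile(c(s = "AAA"), pseudocount = 1e-9)
  expect_identical(m$length, 3L)
  expect_true(all(m$match_em[, "A"] > 1 - 1e-6))
  expect_silent(validate_profile(m))
  ## all-gap-majority column is an insert region, not a match state
  m2 <- build_profile(c(a = "A-A", b = "A-A"))
  expect_identical(m2$length, 2L)
  expect_identical(m2$match_columns, c(1L, 3L))
  ## boundary: a column with exactly 50% residues is a match state
  m3 <- build_profile(c(a = "AA", b = "A-"), match_fraction = 0.5)
  expect_identical(m3$length, 2L)
  ## zero match columns errors
  expect_error(build_profile(c(a = "--", b = "--")), "zero match columns")
})

test_that("forward scores equal the exhaustive path-sum oracle on toy models", {
  for (s in 1:12) {
    set.seed(s)
    L <- sample(1:3, 1)
    model <- random_toy_model(L, s)
    n <- sample(1:4, 1)
    seq <- random_bg_seq(n, 4000 + s)
    expect_equal(forward_score(model, seq), oracle_forward_bits(model, seq),
                 tolerance = 1e-9)
  }
  ## empty sequence has no emitting path
  expect_identical(forward_score(random_toy_model(2, 1), ""), -Inf)
})

test_that("a training consensus outscores all its single-point mutants", {
  cons <- "WCHKMFDNQY"
  m <- build_profile(setNames(cons, "c"), pseudocount = 0.1)
  s0 <- forward_score(m, cons)
  cc <- strsplit(cons, "")[[1]]
  for (i in seq_along(cc)) {
    for (r in setdiff(c("A", "G", "S"), cc[i])) {
      mut <- cc; mut[i] <- r
      expect_lt(forward_score(m, paste(mut, collapse = "")), s0)
    }
  }
})

test_that("Gumbel calibration closed forms and parameter recovery hold", {
  ## P-value at the location parameter is 1 - exp(-1)
  expect_equal(gumbel_pvalue(10, 10, 0.7), 1 - exp(-1))
  ## E-value monotone decreasing in score
  m <- calibrate(build_profile(setNames(random_bg_seq(60, 1), "s")),
                 n_random = 200, random_length = 80, rng_seed = 4)
  ev <- vapply(seq(0, 40, 5), function(s) model_evalue(m, s), numeric(1))
  expect_true(all(diff(ev) < 0))
  ## ML fit recovers known parameters within 5% at n = 5000
  set.seed(42)
  u <- runif(5000)
  x <- 10 - log(-log(u)) / 0.7
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$mu - 10) / 10, 0.05)
  expect_lt(abs(fit$lambda - 0.7) / 0.7, 0.05)
  ## degenerate variance errors
  expect_error(fit_gumbel(rep(1, 300)), "degenerate")
  expect_error(calibrate(build_profile(c(s = "AAA")), n_random = 10),
               "n_random")
})

test_that("calibrated P-values are roughly uniform on background sequences", {
  cons <- generate_family_consensus(family_spec("f", "single", 80), 9)
  mem <- vapply(1:10, function(i) sample_family_member(cons, 0.2, i), "")
  names(mem) <- paste0("m", 1:10)
  model <- calibrate(build_profile(progressive_align(mem)),
                     n_random = 300, random_length = 100, rng_seed = 7)
  pv <- vapply(1:200, function(i) {
    s <- forward_score(model, random_bg_seq(100, 9000 + i))
    gumbel_pvalue(s, model$mu, model$lambda_g)
  }, numeric(1))
  expect_gt(median(pv), 0.3)
  expect_lt(median(pv), 0.7)
  ## family members are detected far below the background score range
  e_mem <- model_evalue(model, forward_score(model, sample_family_member(cons, 0.2, 99)))
  expect_lt(e_mem, 1e-6)
})

test_that("scanning reports envelopes for single and tandem domains", {
  cons <- generate_family_consensus(family_spec("f", "single", 90), 21)
  mem <- vapply(1:12, function(i) sample_family_member(cons, 0.25, 300 + i), "")
  names(mem) <- paste0("m", 1:12)
  model <- calibrate(build_profile(progressive_align(mem)),
                     n_random = 300, random_length = 150, rng_seed = 5)
  loop <- function(n, seed) {
    set.seed(seed)
    comp <- cachescan::aa_composition("loop")
    paste0(sample(names(comp), n, TRUE, comp), collapse = "")
  }
  dom1 <- sample_family_member(cons, 0.25, 501)
  dom2 <- sample_family_member(cons, 0.25, 502)
  tandem <- paste0(loop(20, 1), dom1, loop(15, 2), dom2, loop(20, 3))
  plain <- paste0(loop(20, 4), dom1, loop(20, 5))
  seqs <- c(tandem = tandem, plain = plain, decoy = random_bg_seq(200, 88))
  hits <- scan_sequences(list(model), seqs)
  expect_true(all(hits$seq_evalue < 1e-3 & hits$dom_evalue < 1e-3))
  ## the tandem protein yields two non-overlapping envelopes
  th <- hits[hits$protein_id == "tandem", ]
  expect_identical(nrow(th), 2L)
  expect_lt(th$end[1], th$start[2])
  ## envelopes land on the planted domains within a modest margin
  expect_lt(abs(th$start[1] - 21), 12)
  expect_identical(nrow(hits[hits$protein_id == "plain", ]), 1L)
  ## uncalibrated models are refused
  expect_error(scan_sequences(list(build_profile(c(s = "AAAA"))), seqs),
               "not calibrated")
})
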