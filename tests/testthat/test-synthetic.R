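test_that("family consensus respects length bounds, determinism and double-domain metadata", {
  spec <- family_spec("fam1", "single", 140, divergence = 0.25)
  cons <- generate_family_consensus(spec, 7)
  expect_gte(nchar(cons), 126)
  expect_lte(nchar(cons), 154)
  expect_identical(as.character(cons),
                   as.character(generate_family_consensus(spec, 7)))
  expect_false(identical(as.character(cons),
                         as.character(generate_family_consensus(spec, 8))))

  dspec <- family_spec("fam2", "double", 271, divergence = 0.25)
  dcons <- generate_family_consensus(dspec, 3)
  b <- attr(dcons, "subdomain_boundary")
  expect_true(is.numeric(b) && b > 1 && b <= nchar(dcons))
})

test_that("family and architecture specs validate their invariants", {
  expect_error(family_spec("x", "single", 20), "domain_length")
  expect_error(family_spec("x", "single", 140, divergence = 1.2), "divergence")
  expect_error(architecture_spec(fraction_sensor_bearing = 0.8,
                                 fraction_intracellular_decoys = 0.4),
               "fractions")
  expect_error(architecture_spec(tm_length = 10), "tm_length")
})

test_that("sampled members match the divergence statistically", {
  cons <- generate_family_consensus(family_spec("f", "single", 100), 1)
  ## zero-rate limit
  expect_identical(sample_family_member(cons, 0, 5, indel_rate = 0),
                   as.character(cons))
  ## determinism
  expect_identical(sample_family_member(cons, 0.3, 5),
                   sample_family_member(cons, 0.3, 5))
  expect_error(sample_family_member(cons, 1.5, 1), "divergence")
  expect_error(sample_family_member("", 0.3, 1), "non-empty")
  ## Monte-Carlo identity: substitution-only members, positional identity
  cc <- strsplit(cons, "")[[1]]
  ids <- vapply(seq_len(1000), function(i) {
    m <- sample_family_member(cons, 0.3, 10000 + i, indel_rate = 0)
    mean(strsplit(m, "")[[1]] == cc)
  }, numeric(1))
  expect_gt(mean(ids), 0.65)
  expect_lt(mean(ids), 0.75)
  ## binomial mean within 3 standard errors of 1 - divergence
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - 0.7), 3 * se + 1e-3)
})

test_that("generated proteomes honour class counts, truth bijection and determinism", {
  fams <- default_family_set(10, 0.25)
  arch <- architecture_spec(n_proteins = 200, fraction_sensor_bearing = 0.5,
                            fraction_intracellular_decoys = 0.2)
  pr <- generate_proteome(arch, fams, n_taxa = 5, rng_seed = 3)
  expect_identical(sum(pr$truth$class == "sensor"), 100L)
  ## truth/FASTA bijection
  expect_identical(nrow(pr$truth), length(pr$sequences))
  expect_setequal(pr$truth$protein_id, names(pr$sequences))
  ## region coordinates inside bounds; sensor regions at least 50 long
  expect_true(all(pr$truth$region_end <= nchar(pr$sequences[pr$truth$protein_id])))
  sens <- pr$truth[pr$truth$class == "sensor", ]
  expect_true(all(sens$region_end - sens$region_start + 1 >= 50))
  ## sensor regions flanked by hydrophobic TM segments in the sequence
  tm1 <- substring(pr$sequences[sens$protein_id], sens$region_start - 21,
                   sens$region_start - 1)
  expect_true(all(strsplit(paste(tm1, collapse = ""), "")[[1]] %in%
                    c("A", "F", "I", "L", "M", "V", "W")))
  ## determinism
  pr2 <- generate_proteome(arch, fams, n_taxa = 5, rng_seed = 3)
  expect_identical(pr$sequences, pr2$sequences)
  expect_identical(pr$truth, pr2$truth)
  ## at least one family placed per superfamily and presence recorded
  expect_true(all(rowSums(pr$params$presence) >= 1))
})

test_that("superfamily ancestry relates single families and fusion halves", {
  fams <- default_family_set(10, 0.25)
  cg <- build_family_consensi(fams, 11)
  ## within-superfamily singles score clearly higher than cross-superfamily
  within <- local_align(cg$consensus[["sA1"]], cg$consensus[["sA2"]])$bits
  across <- local_align(cg$consensus[["sA1"]], cg$consensus[["sB1"]])$bits
  expect_gt(within, across + 10)
  ## doubles record boundary and their N/C sources
  expect_false(is.na(cg$boundary[["dA1"]]))
  expect_identical(unname(cg$sources[["dA1"]]["N"]), "sA1")
  expect_identical(unname(cg$sources[["dA1"]]["C"]), "sA2")
  b <- cg$boundary[["dA1"]]
  nhalf <- substr(cg$consensus[["dA1"]], 1, b - 1)
  src <- cg$consensus[["sA1"]]
  expect_gt(local_align(nhalf, src)$identity, 0.4)
})
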