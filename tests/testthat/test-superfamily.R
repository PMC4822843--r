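pp_row <- function(a, b, evalue, prob) {
  data.frame(model_a = a, model_b = b, score = 10, evalue = evalue,
             prob = prob, a_start = 1, a_end = 10, b_start = 1, b_end = 10,
             coverage_a = 1, coverage_b = 1)
}

test_that("family graph tiers follow the reciprocal threshold rules", {
  hits <- rbind(
    pp_row("F1", "F2", 1e-5, 99), pp_row("F2", "F1", 1e-6, 98),
    pp_row("F1", "F3", 1e-4, 95), pp_row("F3", "F1", 0.5, 93),
    pp_row("F2", "F3", 0.9, 40), pp_row("F3", "F2", 0.8, 35))
  g <- build_family_graph(hits)
  e12 <- g$edges[g$edges$a == "F1" & g$edges$b == "F2", ]
  ## reciprocal 1e-5/1e-6: thick, hence also thin
  expect_true(e12$thick && e12$thin)
  ## asymmetric E (1e-4 vs 0.5) but both probabilities > 90: dotted only
  e13 <- g$edges[g$edges$a == "F1" & g$edges$b == "F3", ]
  expect_false(e13$thick || e13$thin)
  expect_true(e13$dotted)
  ## no qualifying pair between F2 and F3
  expect_false(any(g$edges$a == "F2" & g$edges$b == "F3"))
  ## threshold nesting is structural
  expect_true(all(!g$edges$thick | g$edges$thin))
})

test_that("the clan cascade applies its three rules in order", {
  hits <- rbind(
    ## X: thick reciprocal edge to seeded S1
    pp_row("X", "S1", 1e-5, 99), pp_row("S1", "X", 1e-5, 99),
    ## Y: best labelled hit is S1 (prob 92) vs S2 (prob 40): closest
    pp_row("Y", "S1", 0.05, 92), pp_row("S1", "Y", 0.05, 91),
    pp_row("Y", "S2", 0.5, 40), pp_row("S2", "Y", 0.5, 41),
    ## V, Z: thick edges to the two seeds
    pp_row("V", "S1", 1e-5, 85), pp_row("S1", "V", 1e-5, 85),
    pp_row("Z", "S2", 1e-5, 85), pp_row("S2", "Z", 1e-5, 85),
    ## W (orphan): ties V and Z at prob 80 (rule 2 cannot pick a unique
    ## clan) but forms a mutual best hit with V
    pp_row("W", "V", 0.3, 80), pp_row("W", "Z", 0.3, 80),
    pp_row("V", "W", 0.2, 99), pp_row("Z", "W", 0.5, 70))
  g <- build_family_graph(hits)
  res <- assign_clans(g, c(S1 = "CacheLike", S2 = "PASLike"), hits)
  r <- setNames(res$clan_id, res$model_id)
  rule <- setNames(res$rule, res$model_id)
  expect_identical(unname(r["X"]), "CacheLike")
  expect_identical(unname(rule["X"]), "threshold")
  expect_identical(unname(r["Y"]), "CacheLike")
  expect_identical(unname(rule["Y"]), "closest-superfamily")
  expect_identical(unname(r["V"]), "CacheLike")
  expect_identical(unname(r["Z"]), "PASLike")
  ## the orphan joins its mutual best hit's clan
  expect_identical(unname(r["W"]), "CacheLike")
  expect_identical(unname(rule["W"]), "mutual-best-hit")
})

test_that("conflicting thick edges flag a model as ambiguous", {
  hits <- rbind(
    pp_row("M", "S1", 1e-5, 99), pp_row("S1", "M", 1e-5, 99),
    pp_row("M", "S2", 1e-6, 99), pp_row("S2", "M", 1e-6, 99))
  g <- build_family_graph(hits)
  res <- assign_clans(g, c(S1 = "A", S2 = "B"), hits)
  m <- res[res$model_id == "M", ]
  expect_identical(m$rule, "ambiguous")
  expect_true(is.na(m$clan_id))
})

test_that("UPGMA reproduces the hand-computed 3-leaf tree and stays ultrametric", {
  sim <- matrix(c(100, 98, 96,
                  98, 100, 96,
                  96, 96, 100), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ## distances: d(A,B) = 2, d(A,C) = d(B,C) = 4
  res <- upgma_dendrogram(sim)
  tree <- res$tree
  depths <- ape::node.depth.edgelength(tree)
  tips <- depths[seq_len(3)]
  ## ultrametric: equal root-to-leaf depths; cherry at height 1, root at 2
  expect_equal(unname(tips), rep(2, 3) - 0)
  expect_equal(sort(unique(round(ape::branching.times(tree), 9))), c(1, 2))
  ## cophenetic distances equal the UPGMA merge heights
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_error(upgma_dendrogram(matrix(1, 2, 3)), "square")
})

test_that("UPGMA equals a naive agglomeration oracle on random matrices", {
  for (trial in 1:8) {
    set.seed(trial)
    n <- sample(4:10, 1)
    sim <- matrix(runif(n * n, 0, 100), n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 100
    dimnames(sim) <- list(letters[1:n], letters[1:n])
    res <- upgma_dendrogram(sim)
    d <- 100 - sim; diag(d) <- 0
    coph <- oracle_upgma_cophenetic(d)
    expect_equal(ape::cophenetic.phylo(res$tree)[letters[1:n], letters[1:n]],
                 coph, tolerance = 1e-8)
  }
})

test_that("heat-map clustering groups block-diagonal superfamilies", {
  blocks <- rep(c("P", "Q", "R"), each = 3)
  n <- length(blocks)
  sim <- matrix(5, n, n)
  sim[outer(blocks, blocks, "==")] <- 85
  diag(sim) <- 100
  ids <- paste0(blocks, 1:n)
  dimnames(sim) <- list(ids, ids)
  hm <- family_heatmap(sim, prob_floor = 20)
  ord_blocks <- blocks[match(hm$order, ids)]
  expect_identical(length(rle(ord_blocks)$lengths), 3L)
  ## permuting input rows yields the same grouping
  set.seed(2)
  perm <- sample(n)
  hm2 <- family_heatmap(sim[perm, perm], prob_floor = 20)
  ord2 <- blocks[match(hm2$order, ids)]
  expect_identical(length(rle(ord2)$lengths), 3L)
  ## floor above the maximum: all-zero matrix, flat order
  hm3 <- family_heatmap(sim, prob_floor = 200)
  expect_true(all(hm3$matrix == 0))
  expect_identical(hm3$order, ids)
})

test_that("fusion subdomains best-match their source single families", {
  ## three single families; a double family fused from f3 (N) and f2 (C)
  fams <- list(
    family_spec("f1", "single", 110, divergence = 0.25, superfamily_id = "SF"),
    family_spec("f2", "single", 110, divergence = 0.25, superfamily_id = "SF"),
    family_spec("f3", "single", 110, divergence = 0.25, superfamily_id = "SF"))
  cg <- build_family_consensi(fams, 77, superfamily_divergence = 0.5)
  fuse_n <- sample_family_member(cg$consensus[["f3"]], 0.2, 881, indel_rate = 0)
  fuse_c <- sample_family_member(cg$consensus[["f2"]], 0.2, 882, indel_rate = 0)
  dcons <- paste0(fuse_n, fuse_c)
  mk <- function(cons, base, n = 12) {
    s <- vapply(seq_len(n), function(i) sample_family_member(cons, 0.25, base + i), "")
    names(s) <- paste0("m", base + seq_len(n)); s
  }
  singles <- lapply(c(f1 = "f1", f2 = "f2", f3 = "f3"), function(f)
    build_profile(progressive_align(mk(cg$consensus[[f]], match(f, names(cg$consensus)) * 1000)),
                  model_id = f))
  dbl <- build_profile(progressive_align(mk(dcons, 9000)), model_id = "dbl")
  ## split at the match state nearest the fusion boundary
  split <- which.min(abs(dbl$match_columns - (nchar(fuse_n) + 1)))
  hits <- subdomain_compare(list(dbl = dbl), singles,
                            split_points = c(dbl = split), rng_seed = 3)
  nh <- hits[hits$model_a == "dbl_N", ]
  ch <- hits[hits$model_a == "dbl_C", ]
  expect_identical(nh$model_b[which.max(nh$prob)], "f3")
  expect_identical(ch$model_b[which.max(ch$prob)], "f2")
  ## invalid split points error
  expect_error(subdomain_compare(list(dbl = dbl), singles,
                                 split_points = c(dbl = 0)), "split point")
})
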