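test_that("local alignment matches hand-computed toy cases", {
  ## identical sequences
  al <- local_align("ACDEFGH", "ACDEFGH")
  expect_equal(al$identity, 1.0)
  expect_equal(al$query_coverage, 1.0)
  ## "ACD" vs "AD" under BLOSUM62 gaps (11,1): aligning A-CD as A--D costs
  ## 4 + 6 - 12 = -2, so the optimum is the single D-D match scoring 6
  al2 <- local_align("ACD", "AD")
  expect_equal(al2$score, 6)
  ## optimality bound: cross-score cannot exceed self-score
  x <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  y <- "GGGGSGGGGSPPPPPNNNNTTTTQQQQHHHH"
  expect_lte(local_align(x, y)$score, local_align(x, x)$score)
  expect_error(local_align("", "AA"), "non-empty")
})

test_that("the Karlin-Altschul E-value obeys its closed form", {
  ## bits 0 with m = n = 1
  expect_equal(evalue(0, 1, 1), 1)
  ## linear in database size
  expect_equal(evalue(30, 100, 2e6), 2 * evalue(30, 100, 1e6))
  ## direct arithmetic: E(50 bits, m=100, n=1e6) = 1e8 * 2^-50
  expect_equal(evalue(50, 100, 1e6), 100 * 1e6 * 2^-50)
  expect_equal(evalue(50, 100, 1e6), 8.8818e-08, tolerance = 1e-4)
  ## monotone decreasing in score
  expect_true(all(diff(evalue(seq(10, 60, 5), 100, 1e6)) < 0))
})

test_that("greedy redundancy reduction follows the CD-HIT-style rules", {
  set.seed(7)
  base <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), 100, TRUE)
  mk <- function(x) paste(x, collapse = "")
  ## two identical sequences -> one retained
  r <- reduce_redundancy(c(s1 = mk(base), s2 = mk(base)))
  expect_identical(r$retained, "s1")
  expect_identical(unname(r$assignment["s2"]), "s1")
  ## two dissimilar sequences -> both retained
  set.seed(1)
  other <- mk(sample(names(cachescan::aa_composition("loop")), 100, TRUE))
  r2 <- reduce_redundancy(c(a = mk(base), b = other))
  expect_setequal(r2$retained, c("a", "b"))
  ## chain A~B ~95%, A~C 88% with |A| >= |B| >= |C|: greedy keeps {A, C}
  A <- mk(c(base, "W", "W", "W", "W"))
  subs <- function(x, pos) {
    for (p in pos) x[p] <- setdiff(c("G", "P", "W"), x[p])[1]
    x
  }
  B <- mk(subs(base, seq(10, 90, 20)))
  C <- mk(subs(base, c(seq(10, 90, 20), seq(15, 45, 5))))
  ab <- local_align(A, B); ac <- local_align(A, C)
  expect_gte(ab$matches / 100, 0.90)
  expect_lt(ac$matches / 100, 0.90)
  seqs <- c(A = A, B = B, C = C)
  r3 <- reduce_redundancy(seqs)
  expect_identical(r3$retained, c("A", "C"))
  expect_identical(unname(r3$assignment["B"]), "A")
  ## retained set contains no redundant pair (exhaustive re-alignment)
  for (i in r3$retained) for (j in r3$retained) if (i < j) {
    al <- local_align(seqs[[i]], seqs[[j]])
    expect_lt(al$matches / min(nchar(seqs[[i]]), nchar(seqs[[j]])), 0.90)
  }
})

test_that("graph edges require reciprocal E-value and coverage", {
  hits <- data.frame(
    query_id   = c("a", "b", "a", "c", "b", "c"),
    subject_id = c("b", "a", "c", "a", "c", "b"),
    bits = 100,
    evalue = c(1e-12, 1e-12, 1e-12, 1e-12, 1e-5, 1e-12),
    query_coverage = c(0.99, 0.80, 0.99, 0.99, 0.99, 0.99),
    identity = 0.9)
  g <- build_graph(hits, nodes = c("a", "b", "c", "d"))
  ## a-b fails (coverage 0.80 one way), b-c fails (E 1e-5 one way),
  ## a-c passes both ways
  expect_identical(nrow(g$edges), 1L)
  expect_setequal(c(g$edges$a, g$edges$b), c("a", "c"))
  ## isolated node d forms a singleton component
  comp <- graph_components(g, min_size = 2)
  expect_identical(sort(lengths(comp$clusters), decreasing = TRUE)[[1]], 2L)
  expect_true(any(lengths(comp$clusters) == 1))
  ## union of components is the node set
  expect_setequal(unlist(comp$clusters), c("a", "b", "c", "d"))
})

test_that("components match a transitive-closure oracle on random graphs", {
  for (trial in 1:10) {
    set.seed(trial)
    n <- sample(20:60, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(10:80, 1)
    edges <- unique(data.frame(a = sample(nodes, m, TRUE),
                               b = sample(nodes, m, TRUE)))
    edges <- edges[edges$a != edges$b, ]
    hits <- rbind(
      data.frame(query_id = edges$a, subject_id = edges$b, bits = 100,
                 evalue = 1e-20, query_coverage = 0.99, identity = 1),
      data.frame(query_id = edges$b, subject_id = edges$a, bits = 100,
                 evalue = 1e-20, query_coverage = 0.99, identity = 1))
    g <- build_graph(hits, nodes = nodes)
    comp <- graph_components(g, min_size = 1)
    oc <- oracle_components(nodes, edges)
    canon <- function(cl) sort(vapply(cl, function(x)
      paste(sort(x), collapse = ","), ""))
    expect_identical(unname(canon(comp$clusters)), unname(canon(oc)))
  }
})

test_that("cluster filtering honours minimum size and labels", {
  hits <- data.frame(
    query_id   = c(rep("a", 2), rep("b", 2), rep("c", 2), "d", "e"),
    subject_id = c("b", "c", "a", "c", "a", "b", "e", "d"),
    bits = 100, evalue = 1e-20, query_coverage = 0.99, identity = 1)
  g <- build_graph(hits, nodes = letters[1:6])
  comp <- graph_components(g, min_size = 3, labeled_ids = "a")
  tab <- comp$table
  expect_identical(tab$retained, tab$size >= 3 & tab$has_labeled_member)
  expect_identical(sum(tab$retained), 1L)
})
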