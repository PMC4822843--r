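test_that("length distributions summarise hits and flag outliers", {
  hits <- data.frame(
    protein_id = sprintf("p%d", 1:6), model_id = c(rep("S", 4), rep("D", 2)),
    start = c(10, 10, 10, 10, 5, 5),
    end = c(149, 139, 160, 330, 275, 160),
    bits = 50, seq_evalue = 1e-5, dom_evalue = 1e-5)
  res <- length_distribution(hits, c(S = "single", D = "double"))
  ## length arithmetic: (10, 149) -> 140
  expect_identical(res$hits$length[1], 140L)
  ## the 321-long "single" hit and the 156-long "double" hit are outliers
  expect_setequal(res$outliers$protein_id, c("p4", "p6"))
  s <- res$summary[res$summary$model_id == "S", ]
  expect_identical(s$n, 4L)
  ## all-identical lengths give zero IQR
  res2 <- length_distribution(hits[c(1, 1, 1), ], c(S = "single"))
  expect_identical(res2$summary$iqr, 0)
})

test_that("coverage records and bins conserve totals", {
  regions <- data.frame(protein_id = c("p1", "p2", "p3"),
                        region_id = c("p1/1-100", "p2/1-80", "p3/1-50"),
                        start = 1L, end = c(100L, 80L, 50L),
                        length = c(100L, 80L, 50L), tm_pair = 1L,
                        sequence = "X")
  hits <- data.frame(protein_id = c("p1", "p2", "p4"),
                     model_id = "m",
                     start = c(11, 1, 1), end = c(80, 80, 50),
                     bits = 50, seq_evalue = 1e-5, dom_evalue = 1e-5)
  res <- coverage_table(hits, regions)
  ## 70/100 -> bin [70,80)
  expect_equal(res$records$coverage[1], 0.70)
  expect_identical(res$records$bin[1], 7)
  ## exact span -> coverage 1, top (closed) bin
  expect_equal(res$records$coverage[2], 1.0)
  expect_identical(res$records$bin[2], 9)
  ## hit with no enclosing region counted separately
  expect_identical(res$n_unassigned, 1L)
  ## percentages conserve mass
  expect_equal(sum(res$freq$percent), 100, tolerance = 1e-9)
})

test_that("abundance ranking counts one best model per region", {
  hits <- data.frame(
    protein_id = c("r1", "r1", "r2", "r3", "r3"),
    model_id = c("A", "B", "A", "B", "C"),
    start = 1, end = 100,
    bits = c(80, 60, 70, 50, 50),
    seq_evalue = 1e-6,
    dom_evalue = c(1e-8, 1e-6, 1e-8, 1e-6, 1e-7))
  res <- abundance_ranking(hits, c(A = "SF1", B = "SF1", C = "SF2"))
  pf <- setNames(res$per_family$count, res$per_family$model_id)
  ## r1 -> A (higher bits); r3 -> C (tie on bits, lower E-value)
  expect_identical(unname(pf["A"]), 2L)
  expect_identical(unname(pf["C"]), 1L)
  expect_false("B" %in% names(pf[pf > 0]))
  ## totals bounded by the number of regions
  expect_lte(sum(res$per_family$count), 3L)
  ## superfamily aggregation and ordering
  expect_identical(res$per_superfamily$superfamily[1], "SF1")
  ## input order invariance
  res2 <- abundance_ranking(hits[sample(nrow(hits)), ],
                            c(A = "SF1", B = "SF1", C = "SF2"))
  expect_identical(res$per_family, res2$per_family)
})

test_that("phyletic presence follows the any-strain rule and protein floor", {
  taxa <- data.frame(
    protein_id = sprintf("p%02d", 1:40),
    taxon_id = c(rep("spA_s1", 10), rep("spA_s2", 10), rep("spB_s1", 12),
                 rep("spC_s1", 8)),
    species_id = c(rep("spA", 20), rep("spB", 12), rep("spC", 8)))
  hits <- data.frame(protein_id = c("p05", "p25"), model_id = "fam1",
                     start = 1, end = 50)
  res <- phyletic_matrix(hits, taxa, min_proteins = 9)
  ## spA present via strain 1 only; spC excluded (8 <= 9, strict floor)
  expect_identical(rownames(res$matrix), c("spA", "spB"))
  expect_identical(res$matrix["spA", "fam1"], 1L)
  expect_identical(res$matrix["spB", "fam1"], 1L)
  expect_identical(res$excluded, "spC")
  ## floor is strict: a species with exactly min_proteins is excluded
  res2 <- phyletic_matrix(hits, taxa, min_proteins = 12)
  expect_false("spB" %in% rownames(res2$matrix))
  ## presence is monotone when adding a strain with a hit
  taxa3 <- rbind(taxa, data.frame(protein_id = "p99", taxon_id = "spC_s2",
                                  species_id = "spC"))
  hits3 <- rbind(hits, data.frame(protein_id = "p99", model_id = "fam1",
                                  start = 1, end = 50))
  res3 <- phyletic_matrix(hits3, taxa3, min_proteins = 8)
  expect_identical(res3$matrix["spC", "fam1"], 1L)
  ## clade aggregation by any-descendant presence
  taxa$clade <- ifelse(taxa$species_id == "spB", "cladeX", "cladeY")
  res4 <- phyletic_matrix(hits, taxa, min_proteins = 9)
  expect_identical(sort(res4$clades$clade), c("cladeX", "cladeY"))
  expect_true(all(res4$clades$fam1 == 1L))
})
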