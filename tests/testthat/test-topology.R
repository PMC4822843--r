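test_that("hydropathy prediction handles degenerate and obvious inputs", {
  ## all-glycine: hydropathy below threshold everywhere
  gly <- paste(rep("G", 100), collapse = "")
  ann <- predict_topology(gly, "g")
  expect_identical(ann$label, "inside")
  expect_identical(nrow(ann), 1L)
  ## window longer than the sequence: single loop segment
  short <- predict_topology("ACDEFG", "s", window = 19)
  expect_identical(short$label, "inside")
  expect_identical(short$end, 6L)
  ## a strongly hydrophobic stretch becomes a membrane segment
  seq <- paste0(paste(rep("E", 30), collapse = ""),
                paste(rep("L", 21), collapse = ""),
                paste(rep("K", 30), collapse = ""))
  ann <- predict_topology(seq, "p")
  expect_true("membrane" %in% ann$label)
  m <- ann[ann$label == "membrane", ]
  ## overlap with the true helix (31..51) has Jaccard >= 0.5
  inter <- max(0, min(m$end, 51) - max(m$start, 31) + 1)
  uni <- max(m$end, 51) - min(m$start, 31) + 1
  expect_gte(inter / uni, 0.5)
  ## segments tile the sequence
  expect_identical(ann$start[1], 1L)
  expect_identical(ann$end[nrow(ann)], nchar(seq))
  expect_true(all(ann$start[-1] == head(ann$end, -1) + 1))
})

test_that("region extraction applies flanking and strict length rules exactly", {
  mkann <- function(out_end) data.frame(
    protein_id = "p",
    label = c("inside", "membrane", "outside", "membrane", "inside"),
    start = c(1L, 11L, 31L, out_end + 1L, out_end + 21L),
    end = c(10L, 30L, out_end, out_end + 20L, 200L))
  seq200 <- paste(rep("A", 200), collapse = "")
  ## outside 31..100, length 70: returned
  r <- extract_regions(mkann(100L), seq200)
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 31L)
  expect_identical(r$end, 100L)
  expect_identical(r$length, 70L)
  expect_identical(r$region_id, "p/31-100")
  ## "longer than 50": length 50 rejected, 51 kept
  expect_identical(nrow(extract_regions(mkann(80L), seq200)), 0L)
  expect_identical(nrow(extract_regions(mkann(81L), seq200)), 1L)
  ## N-terminal outside segment before the first TM is not flanked
  ann <- data.frame(protein_id = "p",
                    label = c("outside", "membrane", "inside"),
                    start = c(1L, 101L, 122L), end = c(100L, 121L, 200L))
  expect_identical(nrow(extract_regions(ann, seq200)), 0L)
  ## idempotent and order-preserving on a two-region protein
  ann2 <- data.frame(protein_id = "p",
                     label = c("inside", "membrane", "outside", "membrane",
                               "inside", "membrane", "outside", "membrane",
                               "inside"),
                     start = c(1, 11, 32, 100, 121, 141, 162, 240, 261),
                     end = c(10, 31, 99, 120, 140, 161, 239, 260, 300))
  seq300 <- paste(rep("A", 300), collapse = "")
  r2 <- extract_regions(ann2, seq300)
  expect_identical(r2$start, c(32, 162))
  expect_identical(extract_regions(ann2, seq300), r2)
})

test_that("planted regions are recovered with small boundary error", {
  fams <- default_family_set(8, 0.25)
  arch <- architecture_spec(n_proteins = 80, fraction_sensor_bearing = 0.6,
                            fraction_intracellular_decoys = 0.15)
  pr <- generate_proteome(arch, fams, n_taxa = 4, rng_seed = 11)
  topo <- predict_topology_all(pr$sequences)
  reg <- extract_regions_all(topo, pr$sequences)
  rec <- planted_region_recall(reg, pr$truth, tol = 5)
  expect_gte(rec$recall, 0.95)
  expect_lte(rec$mean_start_error, 5)
  expect_lte(rec$mean_end_error, 5)
})

test_that("sensor-context filter requires an output hit outside the region", {
  regions <- data.frame(protein_id = c("p1", "p2", "p3"),
                        region_id = c("p1/10-100", "p2/10-100", "p3/10-100"),
                        start = 10L, end = 100L, length = 91L, tm_pair = 1L,
                        sequence = "X")
  hits <- data.frame(protein_id = c("p1", "p3"),
                     start = c(150L, 20L), end = c(200L, 90L))
  kept <- filter_sensor_context(regions, hits)
  ## p1: hit at C-terminus -> kept; p2: no hits -> dropped;
  ## p3: only hit overlaps the region itself -> dropped
  expect_identical(kept$protein_id, "p1")
})

test_that("localization is classified by majority overlap", {
  ann <- rbind(
    data.frame(protein_id = "p1",
               label = c("inside", "membrane", "outside", "membrane", "inside"),
               start = c(1, 21, 42, 152, 173), end = c(20, 41, 151, 172, 300)),
    data.frame(protein_id = "p2", label = "inside", start = 1, end = 300))
  hits <- data.frame(protein_id = c("p1", "p2", "p1", "nope"),
                     model_id = c("m", "m", "m", "m"),
                     start = c(50, 50, 160, 1), end = c(140, 140, 250, 50))
  res <- classify_localization(hits, ann)
  expect_identical(res$hits$localization,
                   c("extracellular", "intracellular", "intracellular",
                     "unknown"))
  ## per-family fraction: 8 extracellular + 2 intracellular -> 0.8
  hits2 <- data.frame(protein_id = c(rep("p1", 8), rep("p2", 2)),
                      model_id = "fam",
                      start = c(rep(50, 8), rep(50, 2)),
                      end = c(rep(140, 8), rep(140, 2)))
  res2 <- classify_localization(hits2, ann)
  expect_equal(res2$summary$frac_extracellular, 0.8)
})
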