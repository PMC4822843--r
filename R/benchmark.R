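#' Recall of planted regions by the topology stage
#'
#' Fraction of planted sensor regions recovered by region extraction with
#' both boundaries within `tol` residues, plus the boundary-error summary.
#'
#' @param regions extracted region table
#' @param truth generator truth table
#' @param tol per-boundary tolerance in residues (default 5)
#' @return list: recall, mean_start_error, mean_end_error, n_truth
#' @export
planted_region_recall <- function(regions, truth, tol = 5) {
  tr <- truth[truth$class == "sensor", , drop = FALSE]
  hitlist <- merge(tr, regions, by = "protein_id")
  ok <- abs(hitlist$start - hitlist$region_start) <= tol &
    abs(hitlist$end - hitlist$region_end) <= tol
  rec <- length(unique(hitlist$protein_id[ok])) / nrow(tr)
  list(recall = rec,
       mean_start_error = mean(abs(hitlist$start - hitlist$region_start)),
       mean_end_error = mean(abs(hitlist$end - hitlist$region_end)),
       n_truth = nrow(tr))
}

#' Adjusted Rand index between clusters and planted families
#'
#' Compares the connected-component labels of sensor-derived regions with
#' the planted family labels from the truth table.
#'
#' @param membership named vector region_id -> cluster id (from
#'   [graph_components()])
#' @param regions region table (maps region ids to proteins)
#' @param truth generator truth table
#' @return adjusted Rand index
#' @export
clustering_ari <- function(membership, regions, truth) {
  prot_of <- setNames(regions$protein_id, regions$region_id)
  fam_of <- setNames(truth$family_id, truth$protein_id)
  fams <- fam_of[prot_of[names(membership)]]
  keep <- !is.na(fams)
  mclust::adjustedRandIndex(membership[keep], fams[keep])
}

#' Held-out detection benchmark for planted families
#'
#' For each planted family, the true member regions (cut from the truth
#' coordinates) are split at random into a training and a held-out half; a
#' profile HMM is built and calibrated from the training half, and all
#' held-out members plus all decoy regions (sensor-less proteins' random
#' extracellular regions) are scanned.  Reports the held-out detection
#' rate at the E-value threshold and the decoy false-hit rate.
#'
#' @param proteome output of [generate_proteome()]
#' @param rng_seed seed controlling the split and calibrations
#' @param evalue_max detection threshold (default 1e-3)
#' @param calibration_n,calibration_length calibration settings
#' @return list: detection_rate, false_hit_rate, n_heldout, n_decoys,
#'   models
#' @export
detection_benchmark <- function(proteome, rng_seed = 1, evalue_max = 1e-3,
                                calibration_n = 400, calibration_length = 150) {
  truth <- proteome$truth
  seqs <- proteome$sequences
  region_seq <- function(rows)
    setNames(substring(seqs[rows$protein_id], rows$region_start,
                       rows$region_end), rows$protein_id)
  sensors <- truth[truth$class == "sensor", , drop = FALSE]
  decoys <- truth[truth$class == "sensorless", , drop = FALSE]
  fams <- sort(unique(sensors$family_id))
  models <- list(); test_sets <- list()
  for (fi in seq_along(fams)) {
    rows <- sensors[sensors$family_id == fams[fi], , drop = FALSE]
    n <- nrow(rows)
    idx <- with_seed(derive_seed(rng_seed, fi), sample(n, floor(n / 2)))
    train <- region_seq(rows[idx, , drop = FALSE])
    test <- region_seq(rows[-idx, , drop = FALSE])
    msa <- progressive_align(train)
    m <- build_profile(msa, model_id = fams[fi])
    m <- calibrate(m, n_random = calibration_n,
                   random_length = calibration_length,
                   rng_seed = derive_seed(rng_seed, 100L + fi))
    models[[fams[fi]]] <- m
    test_sets[[fams[fi]]] <- test
  }
  n_targets <- sum(lengths(test_sets)) + nrow(decoys)
  detected <- 0L; total <- 0L
  for (f in fams) {
    m <- models[[f]]
    for (s in test_sets[[f]]) {
      total <- total + 1L
      e <- model_evalue(m, forward_score(m, s), n_targets)
      if (e < evalue_max) detected <- detected + 1L
    }
  }
  decoy_seqs <- region_seq(decoys)
  false_hits <- 0L
  for (s in decoy_seqs) {
    es <- vapply(models, function(m)
      model_evalue(m, forward_score(m, s), n_targets), numeric(1))
    if (any(es < evalue_max)) false_hits <- false_hits + 1L
  }
  list(detection_rate = detected / total,
       false_hit_rate = false_hits / length(decoy_seqs),
       n_heldout = total, n_decoys = length(decoy_seqs), models = models)
}
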