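#' Per-family domain-length distributions with outlier flags
#'
#' Hit lengths are `end - start + 1`.  Each family is summarised by median
#' and quartiles; hits falling outside the reference band for their kind
#' (centres 140 for single and 271 for double domains — the mean lengths of
#' known structures — with configurable half-widths) are flagged as
#' outliers, the typical signature of partial sequences or partial matches.
#'
#' @param hits domain-hit table with start/end columns
#' @param family_kind named character vector model_id -> "single"/"double"
#' @param centers reference band centres (single, double)
#' @param half_widths reference band half-widths (single, double)
#' @return list: `summary` (per family), `outliers` (flagged hits)
#' @export
length_distribution <- function(hits,
                                family_kind,
                                centers = c(single = 140, double = 271),
                                half_widths = c(single = 50, double = 90)) {
  hits$length <- as.integer(hits$end - hits$start + 1)
  fams <- sort(unique(hits$model_id))
  summ <- do.call(rbind, lapply(fams, function(f) {
    x <- hits$length[hits$model_id == f]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(model_id = f, kind = unname(family_kind[f]), n = length(x),
               q1 = q[1], median = q[2], q3 = q[3], iqr = q[3] - q[1])
  }))
  kind <- family_kind[hits$model_id]
  lo <- centers[kind] - half_widths[kind]
  hi <- centers[kind] + half_widths[kind]
  hits$outlier <- !is.na(kind) & (hits$length < lo | hits$length > hi)
  list(summary = summ, outliers = hits[hits$outlier, , drop = FALSE],
       hits = hits)
}

#' Model coverage of extracellular regions
#'
#' For every hit lying in a region of the same protein, coverage is the
#' hit length (clamped to the region) divided by the region length; the
#' binned frequency table uses 10-percentage-point bins with the top bin
#' closed (coverage 1 falls in [90,100]).  Hits with no enclosing region
#' are excluded and counted in `n_unassigned`.
#'
#' @param hits domain-hit table (protein coordinates)
#' @param regions region table from [extract_regions_all()]
#' @return list: `records` (region_id, model_id, domain_length,
#'   region_length, coverage, bin), `freq` (bin, n, percent), `n_unassigned`
#' @export
coverage_table <- function(hits, regions) {
  recs <- list(); unassigned <- 0L
  for (i in seq_len(nrow(hits))) {
    r <- regions[regions$protein_id == hits$protein_id[i] &
                   regions$start <= hits$end[i] &
                   regions$end >= hits$start[i], , drop = FALSE]
    if (!nrow(r)) { unassigned <- unassigned + 1L; next }
    r <- r[1, ]
    s <- max(hits$start[i], r$start); e <- min(hits$end[i], r$end)
    cov <- (e - s + 1) / r$length
    bin <- min(floor(100 * cov / 10), 9)
    recs[[length(recs) + 1L]] <- data.frame(
      region_id = r$region_id, model_id = hits$model_id[i],
      domain_length = e - s + 1L, region_length = r$length,
      coverage = cov, bin = bin)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(region_id = character(0), model_id = character(0),
               domain_length = integer(0), region_length = integer(0),
               coverage = numeric(0), bin = integer(0))
  bins <- 0:9
  n <- vapply(bins, function(b) sum(records$bin == b), integer(1))
  freq <- data.frame(
    bin = sprintf("[%d,%d%s", bins * 10, (bins + 1) * 10,
                  ifelse(bins == 9, "]", ")")),
    n = n,
    percent = if (nrow(records)) 100 * n / nrow(records) else rep(0, 10))
  list(records = records, freq = freq, n_unassigned = unassigned)
}

#' Reduce a domain-hit table to the best hit per region
#'
#' Keeps, for every scanned region (protein id of the hit), the single
#' best-scoring hit: highest bit score, ties broken by lower domain
#' E-value and then model id.  This is the counting unit used for the
#' coverage and abundance census, where sensitive models legitimately
#' cross-detect related families but each region should be attributed
#' once.
#'
#' @param hits domain-hit table
#' @return one-row-per-region subset, in the original column layout
#' @export
best_hits_per_region <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$protein_id, -hits$bits, hits$dom_evalue, hits$model_id)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$protein_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Abundance ranking of sensor families
#'
#' Counts regions per family on the non-redundant region universe: each
#' region is counted once for its best-scoring model (ties broken by lower
#' E-value, then model id), then counts are aggregated per superfamily and
#' sorted in decreasing order.  Set `count_all = TRUE` to count every hit
#' instead.
#'
#' @param hits domain-hit table on region sequences (protein_id = region
#'   id)
#' @param family_map named character vector model_id -> superfamily id
#' @param count_all count all hits rather than one model per region
#' @return list: `per_family`, `per_superfamily` (both sorted descending)
#' @export
abundance_ranking <- function(hits, family_map, count_all = FALSE) {
  if (nrow(hits)) {
    counted <- if (count_all) hits else best_hits_per_region(hits)
    tab <- table(counted$model_id)
    per_family <- data.frame(model_id = names(tab), count = as.integer(tab))
  } else {
    per_family <- data.frame(model_id = character(0), count = integer(0))
  }
  per_family$superfamily <- unname(family_map[per_family$model_id])
  per_family <- per_family[order(-per_family$count, per_family$model_id), ]
  rownames(per_family) <- NULL
  agg <- stats::aggregate(count ~ superfamily, data = per_family, FUN = sum)
  agg <- agg[order(-agg$count, agg$superfamily), ]
  rownames(agg) <- NULL
  list(per_family = per_family, per_superfamily = agg)
}

#' Phyletic presence/absence matrix
#'
#' Species-level presence: a family is present in a species when any of
#' its strains has at least one hit; species whose total protein count does
#' not exceed `min_proteins` are excluded (guarding against incomplete
#' genomes).  Optional clade labels aggregate presence upward by
#' any-descendant presence.
#'
#' @param hits domain-hit table with protein_id
#' @param taxa data.frame: protein_id, taxon_id (strain), species_id, and
#'   optionally clade
#' @param min_proteins exclusion floor (default 1000; strict "more than")
#' @return list: `matrix` (species x family 0/1 data.frame),
#'   `protein_counts`, `excluded` species, `clades` (aggregated, when
#'   clade labels are present)
#' @export
phyletic_matrix <- function(hits, taxa, min_proteins = 1000) {
  taxa$species_id[is.na(taxa$species_id)] <- "unclassified"
  counts <- table(taxa$species_id)
  keep <- names(counts)[as.integer(counts) > min_proteins]
  excluded <- setdiff(names(counts), keep)
  fams <- sort(unique(hits$model_id))
  sp_of <- setNames(taxa$species_id, taxa$protein_id)
  hits$species <- unname(sp_of[hits$protein_id])
  m <- matrix(0L, nrow = length(keep), ncol = length(fams),
              dimnames = list(sort(keep), fams))
  for (f in fams) {
    sp <- unique(hits$species[hits$model_id == f])
    sp <- intersect(sp, rownames(m))
    m[sp, f] <- 1L
  }
  out <- list(matrix = as.data.frame(m),
              protein_counts = as.data.frame(counts,
                                             stringsAsFactors = FALSE),
              excluded = excluded)
  if ("clade" %in% names(taxa)) {
    clade_of <- unique(taxa[, c("species_id", "clade")])
    cl <- setNames(clade_of$clade, clade_of$species_id)[rownames(m)]
    agg <- stats::aggregate(m, by = list(clade = cl),
                            FUN = function(x) as.integer(any(x > 0)))
    out$clades <- agg
  }
  out
}
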