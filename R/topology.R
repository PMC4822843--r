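#' Predict membrane topology by sliding-window hydropathy
#'
#' A lightweight stand-in for dedicated transmembrane predictors: the mean
#' Kyte-Doolittle hydropathy is computed in a sliding window; maximal runs of
#' at least `min_tm_run` window centres above `threshold` become membrane
#' segments (spanning the centres of the contributing windows),
#' and the remaining stretches are labelled inside/outside by alternation
#' from the stated N-terminal orientation.  Precomputed annotations from real
#' predictors can be supplied instead via [read_topology_tsv()].
#'
#' @param sequence character scalar (one protein)
#' @param protein_id id recorded in the annotation
#' @param window sliding window width in residues (default 19)
#' @param threshold mean-hydropathy cutoff (default 1.6)
#' @param min_tm_run minimum run of above-threshold window centres
#' @param merge_gap membrane segments separated by at most this many
#'   residues are bridged into one helix (real inter-helix loops are much
#'   longer; short dips below threshold inside one helix are noise)
#' @param n_terminus orientation of the N-terminal loop, "in" or "out"
#' @return data.frame with columns protein_id, label
#'   (inside/membrane/outside), start, end — segments tile the sequence
#' @export
predict_topology <- function(sequence, protein_id = "protein",
                             window = 19, threshold = 1.6,
                             min_tm_run = 1, merge_gap = 6,
                             n_terminus = c("in", "out")) {
  n_terminus <- match.arg(n_terminus)
  first_label <- if (n_terminus == "in") "inside" else "outside"
  L <- nchar(sequence)
  whole <- data.frame(protein_id = protein_id, label = first_label,
                      start = 1L, end = L)
  if (L < window) return(whole)

  kd <- unname(KD_HYDROPATHY[str_to_chars(sequence)])
  kd[is.na(kd)] <- 0
  ## mean over windows; win[i] covers residues i .. i+window-1
  cs <- c(0, cumsum(kd))
  nw <- L - window + 1L
  wmean <- (cs[(window + 1):(L + 1)] - cs[1:nw]) / window
  hot <- wmean > threshold
  if (!any(hot)) return(whole)

  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_tm_run)
  if (!length(keep)) return(whole)
  ## windows are indexed by start; a run of hot windows becomes a membrane
  ## segment spanning the window centres, which tracks helix boundaries
  ## much more closely than the union of whole windows
  h <- as.integer(window - 1) %/% 2L
  tm <- data.frame(start = as.integer(starts[keep] + h),
                   end = as.integer(ends[keep] + h))
  ## merge overlapping or near-adjacent membrane segments
  merged <- tm[1, , drop = FALSE]
  if (nrow(tm) > 1) for (i in 2:nrow(tm)) {
    if (tm$start[i] <= merged$end[nrow(merged)] + 1L + merge_gap)
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], tm$end[i])
    else merged <- rbind(merged, tm[i, ])
  }

  labs <- c("inside", "outside")
  cur <- if (n_terminus == "in") 1L else 2L
  segs <- list()
  pos <- 1L
  for (i in seq_len(nrow(merged))) {
    if (merged$start[i] > pos) {
      segs[[length(segs) + 1L]] <- data.frame(label = labs[cur],
                                              start = pos,
                                              end = merged$start[i] - 1L)
    }
    segs[[length(segs) + 1L]] <- data.frame(label = "membrane",
                                            start = merged$start[i],
                                            end = merged$end[i])
    cur <- 3L - cur
    pos <- merged$end[i] + 1L
  }
  if (pos <= L)
    segs[[length(segs) + 1L]] <- data.frame(label = labs[cur], start = pos, end = L)
  out <- do.call(rbind, segs)
  out$protein_id <- protein_id
  out[, c("protein_id", "label", "start", "end")]
}

#' Predict topology for a whole proteome
#'
#' @param sequences named character vector
#' @param ... passed to [predict_topology()]
#' @return row-bound annotation data.frame
#' @export
predict_topology_all <- function(sequences, ...) {
  do.call(rbind, lapply(names(sequences), function(id)
    predict_topology(sequences[[id]], id, ...)))
}

#' Extract candidate extracellular regions
#'
#' Returns every outside-labelled segment lying strictly between two
#' membrane segments whose length exceeds `min_length` (the "longer than
#' 50 residues" filter: length 50 is rejected, 51 kept), in N-to-C order.
#'
#' @param annotation data.frame as produced by [predict_topology()] (one
#'   protein)
#' @param sequence the protein sequence
#' @param min_length regions must be strictly longer than this (default 50)
#' @return data.frame with columns protein_id, region_id, start, end,
#'   length, tm_pair, sequence; zero rows when nothing qualifies
#' @export
extract_regions <- function(annotation, sequence, min_length = 50) {
  stopifnot(all(c("protein_id", "label", "start", "end") %in% names(annotation)))
  ann <- annotation[order(annotation$start), ]
  if (max(ann$end) != nchar(sequence))
    stop("annotation does not tile the sequence")
  empty <- data.frame(protein_id = character(0), region_id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), tm_pair = integer(0),
                      sequence = character(0))
  idx <- which(ann$label == "outside")
  if (!length(idx)) return(empty)
  out <- lapply(idx, function(i) {
    if (i == 1L || i == nrow(ann)) return(NULL)
    if (ann$label[i - 1] != "membrane" || ann$label[i + 1] != "membrane")
      return(NULL)
    len <- ann$end[i] - ann$start[i] + 1L
    if (len <= min_length) return(NULL)
    data.frame(protein_id = ann$protein_id[i],
               start = ann$start[i], end = ann$end[i], length = len,
               tm_pair = sum(ann$label[seq_len(i)] == "membrane"))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out$region_id <- sprintf("%s/%d-%d", out$protein_id, out$start, out$end)
  out$sequence <- substring(sequence, out$start, out$end)
  out[, c("protein_id", "region_id", "start", "end", "length", "tm_pair",
          "sequence")]
}

#' Extract regions for a whole proteome
#' @param annotations row-bound annotations for many proteins
#' @param sequences named character vector
#' @param min_length see [extract_regions()]
#' @return row-bound region data.frame
#' @export
extract_regions_all <- function(annotations, sequences, min_length = 50) {
  res <- lapply(intersect(unique(annotations$protein_id), names(sequences)),
                function(id)
                  extract_regions(annotations[annotations$protein_id == id, ],
                                  sequences[[id]], min_length))
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out))
    return(extract_regions(data.frame(protein_id = "x", label = "inside",
                                      start = 1L, end = 1L), "A", min_length))
  rownames(out) <- NULL
  out
}

#' Keep regions whose protein is a signal transducer
#'
#' A region survives only if its parent protein has at least one
#' output-domain hit located entirely outside the region's coordinates —
#' the analogue of restricting the sequence universe to proteins with a
#' recognised cytoplasmic output signalling domain.
#'
#' @param regions region data.frame from [extract_regions_all()]
#' @param output_hits data.frame with columns protein_id, start, end (hits
#'   of output-domain models)
#' @return filtered region data.frame
#' @export
filter_sensor_context <- function(regions, output_hits) {
  if (!nrow(regions)) return(regions)
  keep <- vapply(seq_len(nrow(regions)), function(i) {
    h <- output_hits[output_hits$protein_id == regions$protein_id[i], , drop = FALSE]
    if (!nrow(h)) return(FALSE)
    any(h$end < regions$start[i] | h$start > regions$end[i])
  }, logical(1))
  regions[keep, , drop = FALSE]
}

#' Classify domain hits as extracellular or intracellular
#'
#' Each hit is labelled by majority overlap of its envelope with outside
#' vs inside topology segments: extracellular when more than half of the
#' envelope lies in outside segments, intracellular when more than half
#' lies inside (a TM-less protein is entirely inside under the N-in
#' convention), otherwise mixed.  Hits on proteins without any annotation
#' are labelled unknown and counted separately.
#'
#' @param hits data.frame with protein_id, model_id, start, end
#' @param annotations row-bound topology annotations
#' @return list with `hits` (input plus `localization` column) and
#'   `summary` (per model: counts per label and extracellular fraction)
#' @export
classify_localization <- function(hits, annotations) {
  loc <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ann <- annotations[annotations$protein_id == hits$protein_id[i], , drop = FALSE]
    if (!nrow(ann)) { loc[i] <- "unknown"; next }
    s <- hits$start[i]; e <- hits$end[i]
    ov <- function(lbl) {
      a <- ann[ann$label == lbl, , drop = FALSE]
      if (!nrow(a)) return(0L)
      sum(pmax(0L, pmin(e, a$end) - pmax(s, a$start) + 1L))
    }
    len <- e - s + 1L
    fo <- ov("outside") / len; fi <- ov("inside") / len
    loc[i] <- if (fo > 0.5) "extracellular" else if (fi > 0.5) "intracellular" else "mixed"
  }
  hits$localization <- loc
  tab <- table(factor(hits$model_id),
               factor(loc, levels = c("extracellular", "intracellular",
                                      "mixed", "unknown")))
  summary <- data.frame(model_id = rownames(tab),
                        n_extracellular = as.integer(tab[, "extracellular"]),
                        n_intracellular = as.integer(tab[, "intracellular"]),
                        n_mixed = as.integer(tab[, "mixed"]),
                        n_unknown = as.integer(tab[, "unknown"]))
  known <- summary$n_extracellular + summary$n_intracellular + summary$n_mixed
  summary$frac_extracellular <- ifelse(known > 0,
                                       summary$n_extracellular / known, NA_real_)
  rownames(summary) <- NULL
  list(hits = hits, summary = summary)
}

#' Parse a truth-table topology string into an annotation data.frame
#' @param topology string like "inside:1-10;membrane:11-31;..."
#' @param protein_id id to attach
#' @return annotation data.frame
#' @export
parse_topology_string <- function(topology, protein_id = "protein") {
  parts <- strsplit(topology, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([a-z]+):(\\d+)-(\\d+)$", parts))
  do.call(rbind, lapply(m, function(x)
    data.frame(protein_id = protein_id, label = x[2],
               start = as.integer(x[3]), end = as.integer(x[4]))))
}
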