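#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (via
#' Biostrings).  The raw score is placed on a bit scale with the standard
#' Karlin-Altschul constants so that E-value thresholds are meaningful.
#'
#' @param a,b amino-acid sequences (character scalars)
#' @param gap_open,gap_extend affine gap penalties (default 11, 1)
#' @param substitution_matrix matrix name (default "BLOSUM62")
#' @return list with raw score, bits, identity (matches / alignment
#'   columns), query_coverage, subject_coverage, and aligned spans
#' @export
local_align <- function(a, b, gap_open = 11, gap_extend = 1,
                        substitution_matrix = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  cols <- nchar(as.character(p))
  qspan <- c(Biostrings::start(p), Biostrings::end(p))
  sspan <- c(Biostrings::start(s), Biostrings::end(s))
  list(score = Biostrings::score(aln),
       bits = bit_score(Biostrings::score(aln)),
       identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
       matches = Biostrings::nmatch(aln),
       query_coverage = (qspan[2] - qspan[1] + 1) / nchar(a),
       subject_coverage = (sspan[2] - sspan[1] + 1) / nchar(b),
       query_span = qspan, subject_span = sspan)
}

#' Raw-to-bit score conversion (Karlin-Altschul)
#' @param score raw alignment score
#' @param lambda,K statistical constants (BLOSUM62 defaults)
#' @return bit score
#' @export
bit_score <- function(score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * score - log(K)) / log(2)
}

#' E-value from a bit score
#'
#' `E = m * n * 2^-bits`, with `m` the query length and `n` the total
#' residue count of the searched database; monotone decreasing in the score.
#'
#' @param bits bit score
#' @param query_length residues in the query
#' @param database_residue_count total residues searched
#' @return expected number of chance hits at this score
#' @export
evalue <- function(bits, query_length, database_residue_count) {
  stopifnot(query_length > 0, database_residue_count > 0)
  query_length * database_residue_count * 2^(-bits)
}

#' All-against-all pairwise comparison
#'
#' Exact Smith-Waterman for every unordered pair; both directional hits are
#' emitted (score/identity are symmetric, coverage is per direction).
#' E-values use the total residue count of the sequence set as the database
#' size.
#'
#' @param sequences named character vector
#' @param gap_open,gap_extend affine gap penalties
#' @return data.frame: query_id, subject_id, bits, evalue, query_coverage,
#'   identity
#' @export
align_all <- function(sequences, gap_open = 11, gap_extend = 1) {
  ids <- names(sequences)
  n <- length(sequences)
  dbres <- sum(nchar(sequences))
  subj <- Biostrings::AAStringSet(sequences)
  data62 <- "BLOSUM62"
  res <- vector("list", n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj[js], subject = Biostrings::AAString(sequences[[i]]),
      type = "local", substitutionMatrix = data62,
      gapOpening = gap_open, gapExtension = gap_extend)
    ## here "pattern" = the j sequences, "subject" = sequence i
    p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
    cols <- nchar(as.character(p))
    nm <- Biostrings::nmatch(aln)
    bits <- bit_score(Biostrings::score(aln))
    cov_j <- (Biostrings::end(p) - Biostrings::start(p) + 1) / nchar(sequences[js])
    cov_i <- (Biostrings::end(s) - Biostrings::start(s) + 1) / nchar(sequences[[i]])
    idn <- ifelse(cols > 0, nm / cols, 0)
    e_i <- evalue(bits, nchar(sequences[[i]]), dbres)
    e_j <- evalue(bits, nchar(sequences[js]), dbres)
    res[[i]] <- data.frame(
      query_id = c(rep(ids[i], length(js)), ids[js]),
      subject_id = c(ids[js], rep(ids[i], length(js))),
      bits = c(bits, bits), evalue = c(e_i, e_j),
      query_coverage = c(cov_i, cov_j), identity = c(idn, idn),
      matches = c(nm, nm))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## distinct k-mer set of a sequence
kmer_set <- function(x, k = 4) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

#' Greedy redundancy reduction at an identity threshold
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by
#' decreasing length (ties broken lexicographically by id); each sequence
#' joins the first retained sequence to which its identity — alignment
#' matches divided by the length of the shorter sequence — reaches the
#' threshold, otherwise it founds a new retained sequence.  A shared-k-mer
#' prefilter skips pairs that cannot reach the threshold; the decision
#' itself is always made by exact alignment.
#'
#' @param sequences named character vector
#' @param identity_threshold default 0.90
#' @return list with `retained` (ids), `assignment` (named map member ->
#'   retained id)
#' @export
reduce_redundancy <- function(sequences, identity_threshold = 0.90) {
  ids <- names(sequences)
  ord <- order(-nchar(sequences), ids)
  ids <- ids[ord]
  retained <- character(0)
  kmers <- list()
  assignment <- setNames(character(length(ids)), ids)
  for (id in ids) {
    seq_i <- sequences[[id]]
    km_i <- kmer_set(seq_i)
    placed <- FALSE
    for (r in retained) {
      ls <- min(nchar(seq_i), nchar(sequences[[r]]))
      ## identity >= t needs >= t*ls matches, i.e. <= (1-t)*ls errors; each
      ## error can destroy at most 4 distinct 4-mer types of the shorter
      ## sequence, so shared types must be >= |K_short| - 4*(1-t)*ls
      k_short <- min(length(km_i), length(kmers[[r]]))
      need <- k_short - 4 * (1 - identity_threshold) * ls
      if (length(intersect(km_i, kmers[[r]])) < max(0, need)) next
      al <- local_align(seq_i, sequences[[r]])
      if (al$matches / ls >= identity_threshold) {
        assignment[id] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      retained <- c(retained, id)
      kmers[[id]] <- km_i
      assignment[id] <- id
    }
  }
  list(retained = retained, assignment = assignment)
}

#' Build the reciprocal similarity graph
#'
#' An undirected edge joins two sequences iff both directional hits have
#' E-value strictly below `evalue_max` and query coverage strictly above
#' `coverage_min` — the reciprocity rule used to define clusters.
#'
#' @param hits hit table from [align_all()] (self-hits ignored)
#' @param nodes node universe (defaults to ids present in hits)
#' @param evalue_max default 1e-10
#' @param coverage_min default 0.95
#' @return object of class `similarity_graph`: list(nodes, edges data.frame
#'   with per-direction provenance columns)
#' @export
build_graph <- function(hits, nodes = NULL, evalue_max = 1e-10,
                        coverage_min = 0.95) {
  if (is.null(nodes))
    nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  h <- hits[hits$query_id != hits$subject_id &
              hits$evalue < evalue_max &
              hits$query_coverage > coverage_min, , drop = FALSE]
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  rev_key <- paste(h$subject_id, h$query_id, sep = "\r")
  recip <- rev_key %in% key
  h <- h[recip & h$query_id < h$subject_id, , drop = FALSE]
  edges <- data.frame(a = h$query_id, b = h$subject_id,
                      evalue_ab = h$evalue, coverage_ab = h$query_coverage)
  if (nrow(edges)) {
    back <- hits[match(paste(edges$b, edges$a, sep = "\r"),
                       paste(hits$query_id, hits$subject_id, sep = "\r")), ]
    edges$evalue_ba <- back$evalue
    edges$coverage_ba <- back$query_coverage
  } else {
    edges$evalue_ba <- numeric(0); edges$coverage_ba <- numeric(0)
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(evalue_max = evalue_max,
                                   coverage_min = coverage_min)),
            class = "similarity_graph")
}

#' Connected components of a similarity graph
#'
#' Each maximal connected component is one cluster; the filtered view keeps
#' clusters with at least `min_size` members that (when labels are given)
#' contain at least one labelled member — the rule used to choose clusters
#' for model building.
#'
#' @param graph a `similarity_graph`
#' @param min_size minimum cluster size for the filtered view (default 10)
#' @param labeled_ids optional character vector of ids carrying a prior
#'   annotation
#' @return list: `membership` (named cluster id per node), `clusters`
#'   (list of member vectors), `table` (cluster_id, size,
#'   has_labeled_member, retained), `filtered` (cluster ids passing)
#' @export
graph_components <- function(graph, min_size = 10, labeled_ids = NULL) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)
  memb <- comp$membership[graph$nodes]
  ## stable cluster ids: by decreasing size then smallest member id
  sizes <- table(memb)
  first_id <- tapply(names(memb), memb, min)
  ord <- order(-as.integer(sizes[names(first_id)]), first_id)
  relabel <- setNames(seq_along(ord), names(first_id)[ord])
  cl <- sprintf("C%03d", relabel[as.character(memb)])
  names(cl) <- graph$nodes
  clusters <- split(graph$nodes, cl)
  tab <- data.frame(cluster_id = names(clusters),
                    size = lengths(clusters))
  tab$has_labeled_member <- if (is.null(labeled_ids)) NA else
    vapply(clusters, function(m) any(m %in% labeled_ids), logical(1))
  tab$retained <- tab$size >= min_size &
    (if (is.null(labeled_ids)) TRUE else tab$has_labeled_member)
  tab <- tab[order(tab$cluster_id), ]
  rownames(tab) <- NULL
  list(membership = cl, clusters = clusters, table = tab,
       filtered = tab$cluster_id[tab$retained])
}
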