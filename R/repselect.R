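#' Build represented sets from a hit table
#'
#' Every query represents the set of subjects whose hit from that query
#' passes the E-value and coverage thresholds, plus itself.  Sets that are
#' identical to or subsets of another query's set are discarded (for
#' identical sets the lexicographically smallest representative id is
#' kept), removing redundant candidates before selection.
#'
#' @param hits hit table (query_id, subject_id, evalue, query_coverage)
#' @param universe character vector of all ids needing coverage
#' @param evalue_max,coverage_min qualification thresholds
#' @return named list of member vectors, one per surviving representative
#' @export
build_represented_sets <- function(hits, universe,
                                   evalue_max = 1e-10, coverage_min = 0.95) {
  h <- hits[hits$query_id %in% universe & hits$subject_id %in% universe &
              hits$evalue < evalue_max & hits$query_coverage > coverage_min, ,
            drop = FALSE]
  sets <- lapply(setNames(universe, universe), function(q)
    sort(unique(c(q, h$subject_id[h$query_id == q]))))
  keep <- rep(TRUE, length(sets))
  ids <- names(sets)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || !keep[i]) next
      si <- sets[[i]]; sj <- sets[[j]]
      if (length(si) < length(sj) && all(si %in% sj)) { keep[i] <- FALSE; break }
      if (length(si) == length(sj) && all(si %in% sj) && ids[j] < ids[i]) {
        keep[i] <- FALSE; break
      }
    }
  }
  sets[keep]
}

#' Greedy maximum-coverage selection of representatives
#'
#' The first representative is the query with the largest represented set;
#' thereafter, each step picks the set that yields the largest working set
#' (i.e. largest gain of not-yet-covered members), until the working set
#' equals the universe.  Ties are broken by larger raw set size, then by
#' lexicographic representative id; zero-gain candidates are skipped.
#'
#' @param sets named list of member vectors (from
#'   [build_represented_sets()])
#' @param universe ids that must end up covered; defaults to the union of
#'   the sets
#' @return list: `representatives` (ordered ids), `gain` (new members added
#'   at each step), `working_set`
#' @export
select_representatives <- function(sets, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  uncovered_check <- setdiff(universe, unlist(sets))
  if (length(uncovered_check))
    stop("sets do not cover the universe; uncovered: ",
         paste(uncovered_check, collapse = ", "))
  ids <- names(sets)
  covered <- character(0)
  reps <- character(0); gains <- integer(0)
  remaining <- rep(TRUE, length(sets))
  while (length(covered) < length(universe)) {
    gain <- vapply(seq_along(sets), function(i)
      if (remaining[i]) length(setdiff(sets[[i]], covered)) else -1L,
      integer(1))
    best <- which(gain == max(gain))
    if (max(gain) <= 0L) stop("no positive-gain candidate left")
    if (length(best) > 1) {
      sz <- lengths(sets[best])
      best <- best[sz == max(sz)]
      if (length(best) > 1) best <- best[order(ids[best])][1]
    }
    reps <- c(reps, ids[best])
    gains <- c(gains, gain[best])
    covered <- union(covered, sets[[best]])
    remaining[best] <- FALSE
  }
  list(representatives = reps, gain = gains, working_set = sort(covered))
}

#' Representative selection within each cluster
#'
#' Runs [build_represented_sets()] + [select_representatives()]
#' independently inside every cluster, restricting hits to within-cluster
#' pairs.
#'
#' @param clusters list of member-id vectors (e.g.
#'   `graph_components(...)$clusters`)
#' @param hits full hit table
#' @param evalue_max,coverage_min representation thresholds
#' @return data.frame: cluster_id, rank, representative_id, gain
#' @export
representatives_for_clusters <- function(clusters, hits,
                                         evalue_max = 1e-10,
                                         coverage_min = 0.95) {
  out <- lapply(names(clusters), function(cid) {
    members <- clusters[[cid]]
    sets <- build_represented_sets(hits, members, evalue_max, coverage_min)
    sel <- select_representatives(sets, universe = members)
    data.frame(cluster_id = cid, rank = seq_along(sel$representatives),
               representative_id = sel$representatives, gain = sel$gain)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
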