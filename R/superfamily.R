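#' Build the tiered family-relationship graph
#'
#' Reciprocal profile-profile hits are classified into three independent
#' tiers mirroring common clan-definition thresholds: thick (both
#' directions E < `e_thick`), thin (both E < `e_thin`) and dotted (both
#' probability scores > `prob_dotted`).  Thick edges are by construction a
#' subset of thin edges.
#'
#' @param hits profile-profile hit table from [pp_compare_all()]
#' @param e_thick,e_thin,prob_dotted tier thresholds (defaults 1e-3, 1e-1,
#'   90)
#' @return object of class `family_graph`: list(nodes, edges with logical
#'   tier columns and both directional hit values)
#' @export
build_family_graph <- function(hits, e_thick = 1e-3, e_thin = 1e-1,
                               prob_dotted = 90) {
  nodes <- sort(unique(c(hits$model_a, hits$model_b)))
  h <- hits[hits$model_a < hits$model_b, , drop = FALSE]
  key <- paste(hits$model_a, hits$model_b, sep = "\r")
  back <- hits[match(paste(h$model_b, h$model_a, sep = "\r"), key), ]
  edges <- data.frame(a = h$model_a, b = h$model_b,
                      evalue_ab = h$evalue, evalue_ba = back$evalue,
                      prob_ab = h$prob, prob_ba = back$prob)
  edges$thick <- edges$evalue_ab < e_thick & edges$evalue_ba < e_thick
  edges$thin <- edges$evalue_ab < e_thin & edges$evalue_ba < e_thin
  edges$dotted <- edges$prob_ab > prob_dotted & edges$prob_ba > prob_dotted
  edges <- edges[edges$thick | edges$thin | edges$dotted, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(e_thick = e_thick, e_thin = e_thin,
                                   prob_dotted = prob_dotted)),
            class = "family_graph")
}

#' Assign families to superfamilies (clans)
#'
#' Starting from seed clan labels, unassigned models are labelled by a rule
#' cascade iterated to a fixed point: (1) a thick reciprocal edge to a clan
#' member assigns that clan ("threshold"); a model with thick edges into
#' two different clans is flagged ambiguous and left unassigned; (2)
#' otherwise, if the model's best hit (highest probability among hits to
#' clan-labelled models) belongs to a unique clan, that clan is assigned
#' ("closest-superfamily"); (3) otherwise, a mutual best hit with an
#' assigned model inherits its clan ("mutual-best-hit").
#'
#' @param graph a `family_graph`
#' @param seed_clans named character vector model_id -> clan_id
#' @param hits the full directional profile-profile hit table
#' @param prob_min probability floor for rule 2: only hits above this
#'   score count as potentially homologous when picking the closest
#'   superfamily (default 70)
#' @return data.frame: model_id, clan_id (NA when unassigned), rule
#'   (seed | threshold | closest-superfamily | mutual-best-hit |
#'   ambiguous | unassigned), support (model id backing the decision)
#' @export
assign_clans <- function(graph, seed_clans, hits, prob_min = 70) {
  nodes <- graph$nodes
  clan <- setNames(rep(NA_character_, length(nodes)), nodes)
  rule <- setNames(rep("unassigned", length(nodes)), nodes)
  supp <- setNames(rep(NA_character_, length(nodes)), nodes)
  clan[names(seed_clans)] <- seed_clans
  rule[names(seed_clans)] <- "seed"

  ## directional best hit (by probability) for the mutual-best rule
  best_hit <- vapply(nodes, function(m) {
    h <- hits[hits$model_a == m, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h$model_b[order(-h$prob, h$model_b)][1]
  }, character(1))

  thick <- graph$edges[graph$edges$thick, c("a", "b"), drop = FALSE]
  ## synchronous update: each iteration assigns from the previous
  ## iteration's state, so the result is independent of node order
  for (iter in seq_len(length(nodes) + 1L)) {
    prev <- clan
    changed <- FALSE
    for (m in nodes) {
      if (!is.na(clan[m]) || rule[m] == "ambiguous") next
      ## rule 1: thick reciprocal edge to an assigned model
      nb <- c(thick$b[thick$a == m], thick$a[thick$b == m])
      nb_clans <- unique(stats::na.omit(prev[nb]))
      if (length(nb_clans) == 1L) {
        hit_nb <- nb[!is.na(prev[nb])][1]
        clan[m] <- nb_clans; rule[m] <- "threshold"; supp[m] <- hit_nb
        changed <- TRUE; next
      }
      if (length(nb_clans) > 1L) {
        rule[m] <- "ambiguous"; changed <- TRUE; next
      }
      ## rule 2: closest superfamily by best labelled hit above the
      ## homology probability floor
      h <- hits[hits$model_a == m & hits$prob > prob_min &
                  hits$model_b %in% nodes[!is.na(prev)], ,
                drop = FALSE]
      if (nrow(h)) {
        h <- h[order(-h$prob, h$model_b), ]
        top <- h$prob[1]
        top_clans <- unique(prev[h$model_b[h$prob == top]])
        if (length(top_clans) == 1L) {
          clan[m] <- top_clans; rule[m] <- "closest-superfamily"
          supp[m] <- h$model_b[1]
          changed <- TRUE; next
        }
      }
      ## rule 3: mutual best hit with an assigned model
      b <- best_hit[m]
      if (!is.na(b) && !is.na(prev[b]) && identical(unname(best_hit[b]), m)) {
        clan[m] <- prev[b]; rule[m] <- "mutual-best-hit"; supp[m] <- b
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  data.frame(model_id = nodes, clan_id = unname(clan[nodes]),
             rule = unname(rule[nodes]), support = unname(supp[nodes]))
}

#' UPGMA dendrogram from a probability-score similarity matrix
#'
#' Distances are `100 - probability`; an asymmetric input is symmetrised by
#' the arithmetic mean (recorded in the result).  Agglomeration is standard
#' UPGMA (average linkage), yielding an ultrametric tree.
#'
#' @param similarity square numeric matrix with dimnames (probability
#'   scores on the 0-100 scale)
#' @return list: `tree` (ape phylo), `newick`, `hclust`, `symmetrized`
#' @export
upgma_dendrogram <- function(similarity) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity))
    stop("similarity must be a square matrix")
  sym <- !isTRUE(all.equal(similarity, t(similarity)))
  m <- (similarity + t(similarity)) / 2
  d <- 100 - m
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  list(tree = tree, newick = ape::write.tree(tree), hclust = hc,
       symmetrized = sym)
}

#' Compare subdomain halves of double-domain models with single-domain
#' models
#'
#' Each double-domain model is split at a supplied match-state index into
#' an N-half and a C-half (by slicing the underlying alignment at the
#' corresponding column and rebuilding profiles), and all halves are
#' compared against the single-domain models.
#'
#' @param double_models named list of `profile_hmm` with stored alignments
#' @param single_models named list of `profile_hmm`
#' @param split_points named integer vector: match-state index at which the
#'   C-half starts, per double model
#' @param rng_seed seed for shuffle calibration
#' @param ... passed to [profile_profile_compare()]
#' @return profile-profile hit table of halves (ids suffixed "_N"/"_C")
#'   versus single models
#' @export
subdomain_compare <- function(double_models, single_models, split_points,
                              rng_seed = 1, ...) {
  halves <- list()
  for (nm in names(double_models)) {
    m <- double_models[[nm]]
    sp <- split_points[[nm]]
    if (is.null(sp) || is.na(sp) || sp <= 1 || sp > m$length)
      stop("split point for '", nm, "' outside model length")
    col <- m$match_columns[sp]
    aln <- m$alignment
    aln_n <- substring(aln, 1, col - 1)
    aln_c <- substring(aln, col, nchar(aln[1]))
    names(aln_n) <- names(aln); names(aln_c) <- names(aln)
    halves[[paste0(nm, "_N")]] <- build_profile(aln_n,
                                                model_id = paste0(nm, "_N"))
    halves[[paste0(nm, "_C")]] <- build_profile(aln_c,
                                                model_id = paste0(nm, "_C"))
  }
  out <- list()
  k <- 0L
  for (h in names(halves)) for (s in names(single_models)) {
    k <- k + 1L
    out[[k]] <- profile_profile_compare(
      halves[[h]], single_models[[s]],
      rng_seed = derive_seed(rng_seed, k), ...)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ward-clustered heat-map ordering of a family similarity matrix
#'
#' Probability scores below `prob_floor` are set to 0, rows are clustered
#' hierarchically with Ward linkage on Euclidean distances, and the leaf
#' order is returned for heat-map display.
#'
#' @param similarity square numeric matrix with dimnames
#' @param prob_floor threshold below which scores are zeroed (default 20)
#' @return list: `matrix` (floored), `order` (leaf ids), `hclust`
#' @export
family_heatmap <- function(similarity, prob_floor = 20) {
  m <- similarity
  m[m < prob_floor] <- 0
  if (all(m == 0)) {
    ord <- rownames(m)
    return(list(matrix = m, order = ord, hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  list(matrix = m, order = rownames(m)[hc$order], hclust = hc)
}
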