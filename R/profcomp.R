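## column-pair co-emission score matrix between two models (natural log):
## S[k,l] = log( sum_x pA_k(x) pB_l(x) / q(x) )
pp_score_matrix <- function(a, b) {
  q <- a$background
  log(a$match_em %*% diag(1 / q) %*% t(b$match_em))
}

#' Profile-profile comparison of two models
#'
#' Match-state columns of the two models are compared with a co-emission
#' log-odds column score and aligned locally with affine gaps.  The raw
#' score is calibrated against a null of column-shuffled versions of the
#' second model (Gumbel fitted by moments), giving a P-value; the reported
#' probability score is `100 * (1 - P)` and the E-value is `n_lib * P`.
#' The raw score is symmetric in the two models; P-values differ slightly
#' between directions because the shuffle null is re-drawn.
#'
#' @param a,b `profile_hmm` objects
#' @param gap_open,gap_extend gap penalties on the column-score scale
#' @param n_shuffle size of the shuffle null (default 100)
#' @param rng_seed seed for the shuffles
#' @param n_lib library size for the E-value (default 1)
#' @return one-row data.frame: model_a, model_b, score, evalue, prob,
#'   a_start, a_end, b_start, b_end, coverage_a, coverage_b
#' @export
profile_profile_compare <- function(a, b, gap_open = 3, gap_extend = 0.3,
                                    n_shuffle = 100, rng_seed = 1, n_lib = 1) {
  if (a$length == 0 || b$length == 0) stop("model of length 0")
  S <- pp_score_matrix(a, b)
  real <- local_dp_cpp(S, gap_open, gap_extend)
  null_scores <- with_seed(rng_seed, {
    vapply(seq_len(n_shuffle), function(i) {
      perm <- sample(ncol(S))
      local_dp_cpp(S[, perm, drop = FALSE], gap_open, gap_extend)$score
    }, numeric(1))
  })
  ## moment-fit Gumbel on the shuffle null
  lam <- pi / (max(stats::sd(null_scores), 1e-6) * sqrt(6))
  mu <- mean(null_scores) - 0.5772156649 / lam
  p <- gumbel_pvalue(real$score, mu, lam)
  data.frame(model_a = a$model_id, model_b = b$model_id,
             score = real$score, evalue = n_lib * p,
             prob = 100 * (1 - p),
             a_start = real$a_start, a_end = real$a_end,
             b_start = real$b_start, b_end = real$b_end,
             coverage_a = (real$a_end - real$a_start + 1) / a$length,
             coverage_b = (real$b_end - real$b_start + 1) / b$length)
}

#' All-against-all profile-profile comparison
#'
#' @param models named list of `profile_hmm`
#' @param include_self also compare each model with itself
#' @param rng_seed master seed; each ordered pair gets a derived substream
#' @param ... passed to [profile_profile_compare()]
#' @return row-bound hit data.frame with both directions per pair
#' @export
pp_compare_all <- function(models, include_self = FALSE, rng_seed = 1, ...) {
  ids <- vapply(models, `[[`, "", "model_id")
  names(models) <- ids
  n <- length(models)
  out <- list()
  idx <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j && !include_self) next
    idx <- idx + 1L
    out[[idx]] <- profile_profile_compare(
      models[[i]], models[[j]],
      rng_seed = derive_seed(rng_seed, i * 1000L + j),
      n_lib = n, ...)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge related clusters by profile-profile similarity
#'
#' Clusters whose models are reciprocally linked with probability score
#' above `probability_min` and aligned-column coverage of at least
#' `coverage_min` (on both models, both directions) are merged: their
#' alignments are combined by profile-profile alignment, a new model is
#' built, and the process iterates to a fixed point.
#'
#' @param models named list of `profile_hmm`
#' @param alignments named list of alignments (same names as models)
#' @param probability_min reciprocal probability threshold (default 90)
#' @param coverage_min aligned-column coverage threshold (default 0.9)
#' @param rng_seed seed for shuffle calibration
#' @param max_iter safety bound
#' @param ... passed to [build_profile()]
#' @return list: `models`, `alignments`, `merged_from` (named list of
#'   source model ids per surviving model)
#' @export
merge_clusters <- function(models, alignments, probability_min = 90,
                           coverage_min = 0.9, rng_seed = 1,
                           max_iter = 10, ...) {
  ids <- vapply(models, `[[`, "", "model_id")
  names(models) <- ids
  names(alignments) <- ids
  merged_from <- lapply(ids, function(i) i)
  names(merged_from) <- ids
  for (iter in seq_len(max_iter)) {
    if (length(models) < 2) break
    hits <- pp_compare_all(models, rng_seed = derive_seed(rng_seed, iter))
    pass <- hits[hits$prob > probability_min &
                   pmin(hits$coverage_a, hits$coverage_b) >= coverage_min, ,
                 drop = FALSE]
    key <- paste(pass$model_a, pass$model_b, sep = "\r")
    rev_key <- paste(pass$model_b, pass$model_a, sep = "\r")
    pass <- pass[rev_key %in% key & pass$model_a < pass$model_b, ,
                 drop = FALSE]
    if (!nrow(pass)) break
    g <- igraph::graph_from_data_frame(
      pass[, c("model_a", "model_b")], directed = FALSE,
      vertices = data.frame(name = names(models)))
    comp <- igraph::components(g)$membership
    new_models <- list(); new_aln <- list(); new_from <- list()
    for (cm in sort(unique(comp))) {
      members <- sort(names(comp)[comp == cm])
      if (length(members) == 1) {
        nm <- members
        new_models[[nm]] <- models[[nm]]
        new_aln[[nm]] <- alignments[[nm]]
        new_from[[nm]] <- merged_from[[nm]]
      } else {
        aln <- alignments[[members[1]]]
        for (m in members[-1]) aln <- merge_alignments(aln, alignments[[m]])
        nm <- paste(members, collapse = "+")
        new_aln[[nm]] <- aln
        new_models[[nm]] <- build_profile(aln, model_id = nm, ...)
        new_from[[nm]] <- unlist(merged_from[members], use.names = FALSE)
      }
    }
    models <- new_models; alignments <- new_aln; merged_from <- new_from
  }
  list(models = models, alignments = alignments, merged_from = merged_from)
}
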