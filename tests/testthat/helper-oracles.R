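## Independent oracles used by the tests. These deliberately re-derive the
## quantities by brute force and must stay independent of the package's
## own implementations.

## Exhaustive path-sum of the uni-local profile HMM forward probability:
## enumerates every (start position, entry state, state path, exit) and
## sums the odds ratios. Only feasible for tiny models/sequences.
oracle_forward_bits <- function(model, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  x <- match(aa, names(model$background))
  n <- length(x); L <- model$length
  em_odds <- model$match_em / matrix(model$background, nrow = L, ncol = 20,
                                     byrow = TRUE)
  tr <- model$trans
  total <- 0
  extend <- function(pos, k, w) {
    ## currently in M_k having just emitted position pos
    total <<- total + w * model$exit[k]
    if (k < L) {
      ## M_k -> M_{k+1}
      if (pos < n)
        extend(pos + 1, k + 1, w * tr$mm[k] * em_odds[k + 1, x[pos + 1]])
      ## M_k -> I_k -> ... -> M_{k+1}
      if (pos < n) {
        wi <- w * tr$mi[k]
        p <- pos + 1
        while (p <= n) {
          ## I emits background (odds 1); after the insert run, I -> M
          if (p < n)
            extend(p + 1, k + 1, wi * tr$im[k] * em_odds[k + 1, x[p + 1]])
          wi <- wi * tr$ii[k]
          p <- p + 1
        }
      }
      ## M_k -> D_{k+1} -> (D ...) -> M
      wd <- w * tr$md[k]
      kd <- k + 1
      while (kd <= L) {
        if (kd < L && pos < n)
          extend(pos + 1, kd + 1, wd * tr$dm[kd] * em_odds[kd + 1, x[pos + 1]])
        if (kd < L) wd <- wd * tr$dd[kd]
        kd <- kd + 1
      }
    }
  }
  for (i in seq_len(n)) for (k in seq_len(L))
    extend(i, k, model$entry[k] * em_odds[k, x[i]])
  unname(log2(total))
}

## random tiny profile HMM for oracle comparisons
random_toy_model <- function(L, seed) {
  set.seed(seed)
  bg <- cachescan::aa_composition("background")
  em <- matrix(stats::rgamma(L * 20, 0.6) + 1e-4, nrow = L)
  em <- em / rowSums(em)
  colnames(em) <- names(bg)
  t_exit <- stats::runif(1, 0.05, 0.3)
  rdist <- function(k) { v <- stats::rgamma(k, 1) + 0.05; v / sum(v) }
  if (L > 1) {
    m3 <- t(replicate(L - 1, rdist(3) * (1 - t_exit)))
    i2 <- t(replicate(L - 1, rdist(2)))
    d2 <- t(replicate(L - 1, rdist(2)))
    trans <- list(mm = m3[, 1], mi = m3[, 2], md = m3[, 3],
                  im = i2[, 1], ii = i2[, 2], dm = d2[, 1], dd = d2[, 2])
  } else {
    trans <- list(mm = numeric(0), mi = numeric(0), md = numeric(0),
                  im = numeric(0), ii = numeric(0), dm = numeric(0),
                  dd = numeric(0))
  }
  structure(list(model_id = sprintf("toy%d", seed), length = L,
                 match_em = em, insert_em = bg, trans = trans,
                 exit = c(rep(t_exit, L - 1), 1), entry = rep(1 / L, L),
                 background = bg, match_columns = seq_len(L), nseq = 1L,
                 alignment = NULL, mu = NA_real_, lambda_g = NA_real_,
                 calibration = NULL),
            class = "profile_hmm")
}

## Independent greedy maximum-coverage selection (no shared code with the
## package): largest gain, ties by raw set size then lexicographic id.
oracle_greedy_select <- function(sets, universe) {
  covered <- character(0); reps <- character(0)
  avail <- names(sets)
  while (!setequal(covered, universe)) {
    gains <- sapply(avail, function(id) length(setdiff(sets[[id]], covered)))
    g <- max(gains)
    cand <- avail[gains == g]
    if (length(cand) > 1) {
      sz <- sapply(cand, function(id) length(sets[[id]]))
      cand <- cand[sz == max(sz)]
      cand <- sort(cand)
    }
    pick <- cand[1]
    reps <- c(reps, pick)
    covered <- union(covered, sets[[pick]])
    avail <- setdiff(avail, pick)
  }
  reps
}

## connected components by boolean transitive closure
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  rownames(A) <- colnames(A) <- nodes
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- TRUE
    A[edges$b[i], edges$a[i]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[A[i, ] > 0] <- cid
  }
  split(nodes, comp)
}

## naive O(n^3) UPGMA returning the cophenetic (merge-height) matrix
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  labels <- rownames(d)
  while (sum(active) > 1) {
    best <- c(NA, NA); bmin <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) if (a < b && D[a, b] < bmin) {
      bmin <- D[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- bmin; coph[j, i] <- bmin
    }
    for (c in idx) if (c != a && c != b)
      D[a, c] <- D[c, a] <-
        (D[a, c] * sizes[a] + D[b, c] * sizes[b]) / (sizes[a] + sizes[b])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
  }
  dimnames(coph) <- list(labels, labels)
  coph
}

## random background sequence
random_bg_seq <- function(n, seed) {
  set.seed(seed)
  bg <- cachescan::aa_composition("background")
  paste0(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}
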