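#' Build a profile HMM from a multiple alignment
#'
#' Standard profile construction: alignment columns with at least
#' `match_fraction` residues become match states; sequences receive
#' Henikoff position-based weights; match emissions are weighted residue
#' counts blended with background pseudocounts (total pseudocount mass
#' `pseudocount`, so the background's relative weight decays as the
#' effective number of observed sequences grows); transitions come from
#' weighted state-path counts with small prior counts.  Insert states emit
#' the background.  The model is uni-local: entry into any match state is
#' uniform and every match state carries a fixed exit mass.
#'
#' @param alignment named character vector of equal-length aligned rows
#' @param match_fraction minimum non-gap fraction for a match column
#'   (default 0.5, with >= comparison)
#' @param pseudocount total background pseudocount mass per emission
#'   distribution (default 1)
#' @param model_id label
#' @param t_exit per-match-state exit probability (last state exits with 1)
#' @return object of class `profile_hmm`
#' @export
build_profile <- function(alignment, match_fraction = 0.5, pseudocount = 1,
                          model_id = "model", t_exit = 0.1) {
  if (!length(alignment)) stop("empty alignment")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  is_res <- matrix(mat %in% AA_ALPHABET, nrow = nrow(mat))
  match_cols <- which(colMeans(is_res) >= match_fraction)
  if (!length(match_cols)) stop("alignment has zero match columns")
  L <- length(match_cols)
  nseq <- nrow(mat)

  ## Henikoff position-based weights
  w <- numeric(nseq)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col %in% AA_ALPHABET]
    if (!length(res)) next
    r <- length(unique(res))
    cnt <- table(res)
    idx <- which(col %in% AA_ALPHABET)
    w[idx] <- w[idx] + 1 / (r * as.numeric(cnt[col[idx]]))
  }
  if (sum(w) == 0) w <- rep(1, nseq)
  w <- w / sum(w) * nseq

  bg <- AA_BACKGROUND
  em <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    cnt <- setNames(numeric(20), AA_ALPHABET)
    ok <- col %in% AA_ALPHABET
    if (any(ok)) {
      agg <- tapply(w[ok], col[ok], sum)
      cnt[names(agg)] <- agg
    }
    em[k, ] <- (cnt + pseudocount * bg) / (sum(cnt) + pseudocount)
  }

  ## transition counts along each row's match-state path
  prior <- list(mm = 1.0, mi = 0.1, md = 0.1, im = 0.5, ii = 0.5,
                dm = 0.5, dd = 0.5)
  cmm <- rep(prior$mm, max(L - 1, 0)); cmi <- rep(prior$mi, max(L - 1, 0))
  cmd <- rep(prior$md, max(L - 1, 0))
  cim <- rep(prior$im, max(L - 1, 0)); cii <- rep(prior$ii, max(L - 1, 0))
  cdm <- rep(prior$dm, max(L - 1, 0)); cdd <- rep(prior$dd, max(L - 1, 0))
  if (L > 1) {
    for (s in seq_len(nseq)) {
      st <- ifelse(is_res[s, match_cols], "M", "D")
      for (k in seq_len(L - 1)) {
        between <- if (match_cols[k + 1] > match_cols[k] + 1)
          sum(is_res[s, (match_cols[k] + 1):(match_cols[k + 1] - 1)]) else 0L
        if (between > 0 && st[k] == "M" && st[k + 1] == "M") {
          cmi[k] <- cmi[k] + w[s]
          if (between > 1) cii[k] <- cii[k] + w[s] * (between - 1)
          cim[k] <- cim[k] + w[s]
        } else {
          ## inserts adjacent to delete states cannot be represented in a
          ## plan7-style path and are dropped from the counts
          if (st[k] == "M" && st[k + 1] == "M") cmm[k] <- cmm[k] + w[s]
          if (st[k] == "M" && st[k + 1] == "D") cmd[k] <- cmd[k] + w[s]
          if (st[k] == "D" && st[k + 1] == "M") cdm[k] <- cdm[k] + w[s]
          if (st[k] == "D" && st[k + 1] == "D") cdd[k] <- cdd[k] + w[s]
        }
      }
    }
  }
  exit <- c(rep(t_exit, max(L - 1, 0)), 1)
  norm_m <- (cmm + cmi + cmd) / (1 - t_exit)
  trans <- list(
    mm = if (L > 1) cmm / norm_m else numeric(0),
    mi = if (L > 1) cmi / norm_m else numeric(0),
    md = if (L > 1) cmd / norm_m else numeric(0),
    im = if (L > 1) cim / (cim + cii) else numeric(0),
    ii = if (L > 1) cii / (cim + cii) else numeric(0),
    dm = if (L > 1) cdm / (cdm + cdd) else numeric(0),
    dd = if (L > 1) cdd / (cdm + cdd) else numeric(0))

  model <- structure(list(
    model_id = model_id, length = L, match_em = em,
    insert_em = bg, trans = trans, exit = exit, entry = rep(1 / L, L),
    background = bg, match_columns = match_cols, nseq = nseq,
    alignment = alignment, mu = NA_real_, lambda_g = NA_real_,
    calibration = NULL), class = "profile_hmm")
  validate_profile(model)
  model
}

#' Validate a profile HMM's distributions
#'
#' Checks that every emission row and every outgoing transition
#' distribution sums to 1 within 1e-9.
#'
#' @param model a `profile_hmm`
#' @return invisibly TRUE; stops on violation
#' @export
validate_profile <- function(model) {
  stopifnot(inherits(model, "profile_hmm"), model$length >= 1)
  tol <- 1e-9
  if (any(abs(rowSums(model$match_em) - 1) > tol))
    stop("match emission rows do not sum to 1")
  if (abs(sum(model$insert_em) - 1) > tol)
    stop("insert emissions do not sum to 1")
  if (abs(sum(model$entry) - 1) > tol)
    stop("entry distribution does not sum to 1")
  L <- model$length
  if (L > 1) {
    tr <- model$trans
    out_m <- tr$mm + tr$mi + tr$md + model$exit[seq_len(L - 1)]
    if (any(abs(out_m - 1) > tol)) stop("match transitions do not sum to 1")
    if (any(abs(tr$im + tr$ii - 1) > tol)) stop("insert transitions do not sum to 1")
    if (any(abs(tr$dm + tr$dd - 1) > tol)) stop("delete transitions do not sum to 1")
  }
  if (abs(model$exit[L] - 1) > tol) stop("final match state must exit")
  invisible(TRUE)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states, %d training sequences%s\n",
              x$model_id, x$length, x$nseq,
              if (is.na(x$mu)) " (uncalibrated)"
              else sprintf(", Gumbel mu=%.2f lambda=%.3f", x$mu, x$lambda_g)))
  invisible(x)
}

encode_seq <- function(sequence) {
  idx <- match(str_to_chars(sequence), AA_ALPHABET) - 1L
  idx[!is.na(idx)]
}

model_log_params <- function(model) {
  L <- model$length
  list(em_lo = log(model$match_em / rep(model$background, each = L)),
       log_entry = log(model$entry), log_exit = log(model$exit),
       lmm = log(model$trans$mm), lmi = log(model$trans$mi),
       lmd = log(model$trans$md), lim = log(model$trans$im),
       lii = log(model$trans$ii), ldm = log(model$trans$dm),
       ldd = log(model$trans$dd))
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' Sum over all alignments (paths) of the model to any subsequence, in
#' local mode: the domain may start and end anywhere, flanking residues are
#' scored by the background null, inserts emit background.  Returned in
#' bits; an empty sequence has no emitting path and scores `-Inf`.
#'
#' @param model a `profile_hmm`
#' @param sequence character scalar
#' @return bit score
#' @export
forward_score <- function(model, sequence) {
  seq <- encode_seq(sequence)
  if (!length(seq)) return(-Inf)
  p <- model_log_params(model)
  forward_logodds_cpp(p$em_lo, p$log_entry, p$log_exit, p$lmm, p$lmi, p$lmd,
                      p$lim, p$lii, p$ldm, p$ldd, seq) / log(2)
}

#' Viterbi alignment of a profile HMM to a sequence
#'
#' @param model a `profile_hmm`
#' @param sequence character scalar
#' @return list: score (bits), start, end (1-based sequence span of the
#'   aligned domain), k_start, k_end (model span)
#' @export
viterbi_align <- function(model, sequence) {
  seq <- encode_seq(sequence)
  if (!length(seq))
    return(list(score = -Inf, start = NA, end = NA, k_start = NA, k_end = NA))
  p <- model_log_params(model)
  v <- viterbi_cpp(p$em_lo, p$log_entry, p$log_exit, p$lmm, p$lmi, p$lmd,
                   p$lim, p$lii, p$ldm, p$ldd, seq)
  v$score <- v$score / log(2)
  v
}

#' Gumbel tail probability
#'
#' P-value of observing a score of at least `s` under a Gumbel(mu,
#' lambda) score distribution: `1 - exp(-exp(-lambda (s - mu)))`.
#'
#' @param s score
#' @param mu location
#' @param lambda scale (> 0)
#' @return tail probability
#' @export
gumbel_pvalue <- function(s, mu, lambda) {
  -expm1(-exp(-lambda * (s - mu)))
}

#' Fit a Gumbel distribution by maximum likelihood
#'
#' @param x numeric scores
#' @return list(mu, lambda)
#' @export
fit_gumbel <- function(x) {
  if (stats::sd(x) < 1e-8) stop("degenerate score variance; cannot calibrate")
  lambda0 <- pi / (stats::sd(x) * sqrt(6))
  mu0 <- mean(x) - 0.5772156649 / lambda0
  nll <- function(par) {
    lam <- exp(par[2])
    z <- lam * (x - par[1])
    -sum(log(lam) - z - exp(-z))
  }
  fit <- stats::optim(c(mu0, log(lambda0)), nll, method = "BFGS")
  list(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate a profile HMM's score distribution
#'
#' Scores `n_random` i.i.d. background sequences and fits a Gumbel by
#' maximum likelihood; the fitted location/scale turn any scanned score
#' into a P-value, and `E = n_targets * P` into an E-value.
#'
#' @param model a `profile_hmm`
#' @param n_random number of random sequences (>= 200)
#' @param random_length their length
#' @param rng_seed integer seed
#' @param composition residue composition of the null sequences
#' @return the model with `mu`, `lambda_g` and calibration metadata set
#' @export
calibrate <- function(model, n_random = 500, random_length = 150,
                      rng_seed = 1, composition = AA_BACKGROUND) {
  stopifnot(n_random >= 200)
  scores <- with_seed(rng_seed, {
    vapply(seq_len(n_random), function(i)
      forward_score(model,
                    chars_to_str(sample_residues(random_length, composition))),
      numeric(1))
  })
  fit <- fit_gumbel(scores)
  model$mu <- fit$mu
  model$lambda_g <- fit$lambda
  model$calibration <- list(n_random = n_random,
                            random_length = random_length,
                            rng_seed = rng_seed)
  model
}

#' E-value of a bit score under a calibrated model
#' @param model calibrated `profile_hmm`
#' @param bits bit score
#' @param n_targets number of target sequences searched
#' @return E-value
#' @export
model_evalue <- function(model, bits, n_targets = 1) {
  if (is.na(model$mu)) stop("model is not calibrated")
  n_targets * gumbel_pvalue(bits, model$mu, model$lambda_g)
}

## recursively peel domains off a sequence with Viterbi anchoring
find_envelopes <- function(model, sequence, offset, dom_evalue_max,
                           n_targets, min_len = 10) {
  if (nchar(sequence) < min_len) return(NULL)
  v <- viterbi_align(model, sequence)
  if (!is.finite(v$score) || is.na(v$start)) return(NULL)
  dom_seq <- substring(sequence, v$start, v$end)
  dom_bits <- forward_score(model, dom_seq)
  dom_e <- model_evalue(model, dom_bits, n_targets)
  if (dom_e >= dom_evalue_max) return(NULL)
  here <- data.frame(start = offset + v$start, end = offset + v$end,
                     bits = dom_bits, dom_evalue = dom_e)
  left <- if (v$start > 1)
    find_envelopes(model, substring(sequence, 1, v$start - 1), offset,
                   dom_evalue_max, n_targets, min_len) else NULL
  right <- if (v$end < nchar(sequence))
    find_envelopes(model, substring(sequence, v$end + 1, nchar(sequence)),
                   offset + v$end, dom_evalue_max, n_targets, min_len) else NULL
  rbind(here, left, right)
}

#' Scan sequences with a library of calibrated profile HMMs
#'
#' For each model-sequence pair the whole-sequence forward score yields a
#' sequence E-value; passing sequences are segmented into domain envelopes
#' by recursive Viterbi anchoring (the anchor's span is the envelope; the
#' flanks are re-scanned for further domains, so tandem repeats produce
#' multiple non-overlapping envelopes).  A hit is reported when both the
#' sequence and the domain E-value are below their thresholds (default
#' 1e-3).  Overlapping hits from different models are all reported.
#'
#' @param models list of calibrated `profile_hmm`
#' @param sequences named character vector
#' @param seq_evalue_max,dom_evalue_max reporting thresholds (default 1e-3)
#' @param n_targets database size for E-values; defaults to
#'   `length(sequences)`
#' @return data.frame: protein_id, model_id, start, end, bits,
#'   seq_evalue, dom_evalue
#' @export
scan_sequences <- function(models, sequences,
                           seq_evalue_max = 1e-3, dom_evalue_max = 1e-3,
                           n_targets = length(sequences)) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  for (m in models) if (is.na(m$mu))
    stop("model '", m$model_id, "' is not calibrated")
  out <- list()
  for (m in models) {
    for (id in names(sequences)) {
      bits <- forward_score(m, sequences[[id]])
      seq_e <- model_evalue(m, bits, n_targets)
      if (!(seq_e < seq_evalue_max)) next
      env <- find_envelopes(m, sequences[[id]], 0L, dom_evalue_max, n_targets)
      if (is.null(env) || !nrow(env)) next
      env$protein_id <- id
      env$model_id <- m$model_id
      env$seq_evalue <- seq_e
      out[[length(out) + 1L]] <- env
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(0), model_id = character(0),
                      start = integer(0), end = integer(0),
                      bits = numeric(0), seq_evalue = numeric(0),
                      dom_evalue = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[, c("protein_id", "model_id", "start", "end", "bits",
                 "seq_evalue", "dom_evalue")]
  res <- res[order(res$protein_id, res$model_id, res$start), ]
  rownames(res) <- NULL
  res
}
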