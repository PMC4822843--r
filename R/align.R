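## shared cache for lazily loaded data
.cachescan_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.cachescan_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cachescan_env$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .cachescan_env$blosum62
}

## residue-frequency matrix (20 x ncol) of an MSA; counts divided by the
## number of rows, so gappy columns carry proportionally less weight
msa_freq_matrix <- function(msa) {
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  L <- ncol(mat)
  f <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(L)) {
    tab <- table(mat[, j])
    tab <- tab[names(tab) %in% AA_ALPHABET]
    if (length(tab)) f[names(tab), j] <- as.numeric(tab)
  }
  f / nrow(mat)
}

#' Merge two multiple alignments by profile-profile alignment
#'
#' Columns of each alignment are summarised as residue-frequency vectors;
#' the column-pair score is the frequency-weighted BLOSUM62 sum of pairs,
#' and the two alignments are aligned globally with affine gaps.
#'
#' @param msa_a,msa_b named character vectors of equal-length aligned rows
#' @param gap_open,gap_extend gap penalties on the profile score scale
#' @return merged named character vector
#' @export
merge_alignments <- function(msa_a, msa_b, gap_open = 10, gap_extend = 1) {
  fa <- msa_freq_matrix(msa_a)
  fb <- msa_freq_matrix(msa_b)
  S <- t(fa) %*% get_blosum62() %*% fb
  tb <- global_dp_cpp(S, gap_open, gap_extend)
  ncols <- length(tb$a)
  rows_a <- do.call(rbind, strsplit(msa_a, "", fixed = TRUE))
  rows_b <- do.call(rbind, strsplit(msa_b, "", fixed = TRUE))
  out_a <- matrix("-", nrow = nrow(rows_a), ncol = ncols)
  out_b <- matrix("-", nrow = nrow(rows_b), ncol = ncols)
  sel_a <- tb$a > 0
  sel_b <- tb$b > 0
  out_a[, sel_a] <- rows_a[, tb$a[sel_a], drop = FALSE]
  out_b[, sel_b] <- rows_b[, tb$b[sel_b], drop = FALSE]
  merged <- rbind(out_a, out_b)
  setNames(apply(merged, 1, paste0, collapse = ""),
           c(names(msa_a), names(msa_b)))
}

## fraction of shared distinct k-mers, as a similarity in [0,1]
kmer_similarity <- function(a, b, k = 3) {
  ka <- kmer_set(a, k); kb <- kmer_set(b, k)
  if (!length(ka) || !length(kb)) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Progressive multiple sequence alignment
#'
#' A deterministic progressive aligner: a UPGMA guide tree is built from
#' k-mer distances, then profiles are merged bottom-up with affine-gap
#' profile-profile alignment (frequency-weighted BLOSUM62 column scores).
#' Intended for families of diverged but alignable domain sequences;
#' externally computed alignments can be supplied anywhere an alignment is
#' expected.
#'
#' @param sequences named character vector (>= 1)
#' @param gap_open,gap_extend gap penalties
#' @param k k-mer size for the guide-tree distance
#' @return named character vector of aligned rows (equal length)
#' @export
progressive_align <- function(sequences, gap_open = 10, gap_extend = 1, k = 3) {
  n <- length(sequences)
  if (n == 0) stop("no sequences")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_len(n))
  if (n == 1) return(sequences)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 1 - kmer_similarity(sequences[[i]], sequences[[j]], k)
    D[i, j] <- d; D[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(seq_len(n), function(i) sequences[i])
  merged <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) profiles[[-x]] else merged[[x]]
    merged[[s]] <- merge_alignments(pick(hc$merge[s, 1]), pick(hc$merge[s, 2]),
                                    gap_open, gap_extend)
  }
  out <- merged[[n - 1]]
  out[names(sequences)[names(sequences) %in% names(out)]]
}
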