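#' @useDynLib cachescan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Robinson & Robinson amino-acid frequencies, the standard null composition
## used by profile-HMM software. Serves as the single canonical background
## for sampling, pseudocounts and null-model scoring.
AA_BACKGROUND <- c(
  A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
  F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
  K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
  P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
  T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

## Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8, G = -0.4,
  H = -3.2, I =  4.5, K = -3.9, L =  3.8, M =  1.9, N = -3.5,
  P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V =  4.2,
  W = -0.9, Y = -1.3)

## Karlin-Altschul constants for BLOSUM62 (ungapped approximation); used
## only to place raw alignment scores on a bit scale so that E-value
## thresholds are applicable. Recorded in the pipeline config.
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Amino-acid composition tables used by the simulator
#'
#' Returns one of the named residue-frequency vectors the synthetic proteome
#' generator draws from.  `background` is the Robinson-Robinson null;
#' `extracellular` is the null with strongly hydrophobic residues
#' down-weighted (so that sensor domains do not by chance contain
#' transmembrane-like stretches); `loop` is restricted to hydrophilic
#' residues (cytoplasmic tails and linkers); `tm` is the hydrophobic pool
#' used for planted transmembrane helices.
#'
#' @param type one of "background", "extracellular", "loop", "tm"
#' @return named numeric vector over the 20 amino acids, summing to 1
#' @export
aa_composition <- function(type = c("background", "extracellular", "loop", "tm")) {
  type <- match.arg(type)
  if (type == "background") return(AA_BACKGROUND)
  if (type == "extracellular") {
    w <- AA_BACKGROUND
    hydro <- c("A", "C", "F", "I", "L", "M", "V")
    w[hydro] <- w[hydro] * 0.35
    w["W"] <- w["W"] * 0.5
    return(w / sum(w))
  }
  if (type == "loop") {
    keep <- c("D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T", "Y")
    w <- AA_BACKGROUND[keep]
    w <- w / sum(w)
    out <- setNames(numeric(20), AA_ALPHABET)
    out[names(w)] <- w
    return(out)
  }
  ## tm: hydrophobic pool biased towards Leu/Ile/Val so that every drawn
  ## helix is reliably detectable by the hydropathy window
  w <- setNames(numeric(20), AA_ALPHABET)
  w[c("A", "F", "I", "L", "M", "V", "W")] <-
    c(0.08, 0.10, 0.22, 0.30, 0.05, 0.22, 0.03)
  w
}

## Fixed cytoplasmic output-domain consensus (e.g. a histidine-kinase-like
## effector stand-in): a 60-residue hydrophilic consensus used by the
## generator and by the sensor-context filter. Invented sequence, hydrophilic
## by construction so it never reads as a TM helix.
OUTPUT_MOTIF_DEFAULT <- paste0(
  "SDKELRQHTNGESYPDQRKTSHGNEDPYQS",
  "TKRDGENQHSPYTDKERNGQSHDPTYKREG")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive a per-item substream seed from a master seed; keeps all seeds
## within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

## Draw n residues from a composition vector.
sample_residues <- function(n, composition) {
  if (n <= 0) return(character(0))
  sample(AA_ALPHABET, n, replace = TRUE, prob = composition[AA_ALPHABET])
}

str_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_to_str <- function(x) paste0(x, collapse = "")
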