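#' Write sequences to FASTA (wrapped at 60 columns)
#' @param sequences named character vector
#' @param path output file
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path,
                              width = 60)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

## write regions as FASTA with "proteinid/start-end" headers
write_region_fasta <- function(regions, path) {
  write_fasta(setNames(regions$sequence, regions$region_id), path)
}

#' Parse "protein/start-end" region headers
#' @param ids character vector of region ids
#' @return data.frame: protein_id, start, end
#' @export
parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)/(\\d+)-(\\d+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region id: ", ids[bad][1])
  data.frame(protein_id = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)))
}

## TSV with schema validation
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_schema <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", basename(path), "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a truth table TSV
#' @param path TSV with protein_id, taxon_id, class, family_id,
#'   region_start, region_end, topology
#' @export
read_truth_tsv <- function(path) {
  read_tsv_schema(path, c("protein_id", "taxon_id", "class", "family_id",
                          "region_start", "region_end", "topology"))
}

#' Read a topology annotation TSV (protein_id, label, start, end)
#' @param path TSV path
#' @export
read_topology_tsv <- function(path) {
  read_tsv_schema(path, c("protein_id", "label", "start", "end"))
}

#' Serialize a profile HMM to JSON
#' @param model a `profile_hmm`
#' @param path output file
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$match_em <- unname(apply(model$match_em, 1, as.numeric, simplify = FALSE))
  x$alignment <- as.list(x$alignment)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a profile HMM back from JSON
#' @param path JSON written by [write_model_json()]
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- if (is.matrix(x$match_em)) x$match_em else do.call(rbind, x$match_em)
  colnames(em) <- AA_ALPHABET
  model <- structure(list(
    model_id = x$model_id, length = as.integer(x$length), match_em = em,
    insert_em = setNames(as.numeric(x$insert_em), AA_ALPHABET),
    trans = lapply(x$trans, as.numeric),
    exit = as.numeric(x$exit), entry = as.numeric(x$entry),
    background = setNames(as.numeric(x$background), AA_ALPHABET),
    match_columns = as.integer(x$match_columns), nseq = as.integer(x$nseq),
    alignment = unlist(x$alignment),
    mu = if (is.null(x$mu)) NA_real_ else as.numeric(x$mu),
    lambda_g = if (is.null(x$lambda_g)) NA_real_ else as.numeric(x$lambda_g),
    calibration = x$calibration), class = "profile_hmm")
  validate_profile(model)
  model
}

#' Export an alignment in Stockholm format
#' @param alignment named character vector of aligned rows
#' @param path output file
#' @export
write_stockholm <- function(alignment, path) {
  ids <- format(names(alignment))
  lines <- c("# STOCKHOLM 1.0",
             paste(ids, alignment), "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a Stockholm alignment
#' @param path file written by [write_stockholm()] or any single-block
#'   Stockholm file
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  aln <- vapply(parts, `[`, "", 2)
  names(aln) <- vapply(parts, `[`, "", 1)
  ## concatenate multi-block entries
  res <- tapply(aln, names(aln), paste0, collapse = "")
  setNames(as.character(res), names(res))[unique(names(aln))]
}
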