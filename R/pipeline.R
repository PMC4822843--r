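#' Default pipeline configuration
#'
#' One canonical configuration carrying every threshold of the discovery
#' pipeline at its standard value: region length strictly > 50 residues,
#' redundancy at 90% identity, similarity-graph edges at E < 1e-10 with
#' query coverage > 95% reciprocally, clusters of at least 10 members,
#' scanning at sequence/domain E-value 1e-3, clan tiers 1e-3 / 1e-1 /
#' probability 90, heat-map floor 20, merge thresholds probability 90 and
#' coverage 0.9.  Simulation parameters default to the synthetic
#' test-bench (6 families x 40 members at divergence 0.25, ~400 proteins,
#' 8 species); the phyletic protein-count floor is scaled to that proteome.
#'
#' @param rng_seed master seed for the whole run
#' @return nested list of class `pipeline_config`
#' @export
default_config <- function(rng_seed = 1) {
  structure(list(
    rng_seed = as.integer(rng_seed),
    simulate = list(n_proteins = 400L, fraction_sensor_bearing = 0.6,
                    fraction_intracellular_decoys = 0.15,
                    n_members = 40L, divergence = 0.25, n_taxa = 8L,
                    tm_length = 21L, superfamily_divergence = 0.50),
    topology = list(window = 19L, threshold = 1.6, min_tm_run = 1L,
                    n_terminus = "in"),
    extract = list(min_region_length = 50L),
    reduce = list(identity_threshold = 0.90),
    network = list(evalue_max = 1e-10, coverage_min = 0.95),
    cluster = list(min_size = 10L),
    represent = list(evalue_max = 1e-10, coverage_min = 0.95),
    profiles = list(match_fraction = 0.5, pseudocount = 1,
                    calibration_n = 400L, calibration_length = 150L,
                    seq_evalue_max = 1e-3, dom_evalue_max = 1e-3),
    merge = list(probability_min = 90, coverage_min = 0.9),
    clans = list(e_thick = 1e-3, e_thin = 1e-1, prob_dotted = 90),
    census = list(min_proteins = 10L, heatmap_floor = 20,
                  length_centers = c(single = 140, double = 271)),
    alignment = list(gap_open = 11, gap_extend = 1,
                     karlin_lambda = KA_LAMBDA, karlin_K = KA_K)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#' @param config a `pipeline_config`
#' @return invisibly TRUE; stops with the offending key otherwise
#' @export
validate_config <- function(config) {
  chk <- function(ok, key) if (!ok) stop("invalid config value for ", key)
  chk(config$extract$min_region_length >= 0, "extract$min_region_length")
  chk(config$reduce$identity_threshold > 0 &&
        config$reduce$identity_threshold <= 1, "reduce$identity_threshold")
  chk(config$network$evalue_max > 0, "network$evalue_max")
  chk(config$network$coverage_min >= 0 && config$network$coverage_min <= 1,
      "network$coverage_min")
  chk(config$cluster$min_size >= 1, "cluster$min_size")
  chk(config$profiles$seq_evalue_max > 0, "profiles$seq_evalue_max")
  chk(config$merge$probability_min >= 0 && config$merge$probability_min <= 100,
      "merge$probability_min")
  chk(config$simulate$divergence > 0 && config$simulate$divergence < 1,
      "simulate$divergence")
  invisible(TRUE)
}

#' Write / read a configuration as JSON (lossless round trip)
#' @param config a `pipeline_config`
#' @param path JSON path
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$census$length_centers <- as.list(x$census$length_centers)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$census$length_centers <- unlist(x$census$length_centers)
  structure(x, class = "pipeline_config")
}

stage_checksum <- function(files) {
  unname(tools::md5sum(files))
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes simulate, topology prediction, region extraction (with the
#' output-domain context filter), redundancy reduction, similarity network
#' and clustering, representative selection, alignment / profile building /
#' calibration, cluster merging, scanning, clan assignment and the census,
#' checkpointing each stage under `out_dir`.  Re-running with unchanged
#' configuration skips stages whose outputs are present with matching
#' checksums.
#'
#' @param config a `pipeline_config`
#' @param out_dir output directory (created if needed)
#' @param force re-run all stages even if up to date
#' @return the run manifest (list), invisibly written to
#'   `manifest.json`
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         force = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force)
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  cfg_hash <- substr(paste(deparse(unclass(config)), collapse = ""), 1, 1e6)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(cfg_hash) *
                                    seq_along(utf8ToInt(cfg_hash))) %% 2^31)
  state <- new.env(parent = emptyenv())

  up_to_date <- function(stage, files) {
    if (force) return(FALSE)
    rec <- manifest$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    if (!identical(rec$config_hash, cfg_hash)) return(FALSE)
    paths <- file.path(out_dir, rec$files)
    if (!all(file.exists(paths))) return(FALSE)
    identical(unname(unlist(rec$md5)), unname(stage_checksum(paths)))
  }
  record <- function(stage, files, status = "ok") {
    paths <- file.path(out_dir, files)
    manifest$stages[[stage]] <<- list(status = status, files = files,
                                      md5 = stage_checksum(paths),
                                      config_hash = cfg_hash,
                                      time = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  run_stage <- function(stage, files, fn, load_fn) {
    if (up_to_date(stage, files)) {
      log_msg("stage ", stage, ": up to date, skipped")
      manifest$stages[[stage]]$status <<- "skipped"
      load_fn()
    } else {
      log_msg("stage ", stage, ": running")
      fn()
      record(stage, files)
    }
  }

  sim <- config$simulate
  seed <- config$rng_seed

  ## -- simulate ------------------------------------------------------
  fasta_p <- "proteome.fasta"; truth_p <- "truth.tsv"; params_p <- "params.json"
  run_stage("simulate", c(fasta_p, truth_p, params_p), fn = function() {
    arch <- architecture_spec(sim$n_proteins, sim$fraction_sensor_bearing,
                              sim$fraction_intracellular_decoys,
                              tm_length = sim$tm_length)
    fams <- default_family_set(sim$n_members, sim$divergence)
    prot <- generate_proteome(arch, fams, n_taxa = sim$n_taxa,
                              rng_seed = seed,
                              superfamily_divergence = sim$superfamily_divergence)
    state$prot <- prot
    write_fasta(prot$sequences, file.path(out_dir, fasta_p))
    write_tsv(prot$truth, file.path(out_dir, truth_p))
    p <- prot$params; p$presence <- NULL
    jsonlite::write_json(p, file.path(out_dir, params_p), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, load_fn = function() {
    arch <- architecture_spec(sim$n_proteins, sim$fraction_sensor_bearing,
                              sim$fraction_intracellular_decoys,
                              tm_length = sim$tm_length)
    fams <- default_family_set(sim$n_members, sim$divergence)
    state$prot <- generate_proteome(arch, fams, n_taxa = sim$n_taxa,
                                    rng_seed = seed,
                                    superfamily_divergence = sim$superfamily_divergence)
  })
  prot <- state$prot

  ## -- topology ------------------------------------------------------
  topo_p <- "topology.tsv"
  run_stage("topology", topo_p, fn = function() {
    topo <- predict_topology_all(prot$sequences,
                                 window = config$topology$window,
                                 threshold = config$topology$threshold,
                                 min_tm_run = config$topology$min_tm_run,
                                 n_terminus = config$topology$n_terminus)
    state$topo <- topo
    write_tsv(topo, file.path(out_dir, topo_p))
  }, load_fn = function() {
    state$topo <- read_topology_tsv(file.path(out_dir, topo_p))
  })
  topo <- state$topo

  ## -- extract (regions + output-domain context filter) --------------
  regions_p <- "regions.tsv"; regfa_p <- "regions.fasta"
  run_stage("extract", c(regions_p, regfa_p), fn = function() {
    regions <- extract_regions_all(topo, prot$sequences,
                                   min_length = config$extract$min_region_length)
    ## output-domain model from the architecture's motif (single-sequence
    ## profile), calibrated, then scanned over the proteome
    out_model <- build_profile(
      setNames(OUTPUT_MOTIF_DEFAULT, "output_consensus"),
      model_id = "output_domain", pseudocount = 0.5)
    out_model <- calibrate(out_model,
                           n_random = config$profiles$calibration_n,
                           random_length = config$profiles$calibration_length,
                           rng_seed = derive_seed(seed, 71L))
    out_hits <- scan_sequences(list(out_model), prot$sequences,
                               seq_evalue_max = config$profiles$seq_evalue_max,
                               dom_evalue_max = config$profiles$dom_evalue_max)
    regions <- filter_sensor_context(regions, out_hits)
    state$regions <- regions
    write_tsv(regions[, setdiff(names(regions), "sequence")],
              file.path(out_dir, regions_p))
    write_region_fasta(regions, file.path(out_dir, regfa_p))
  }, load_fn = function() {
    seqs <- read_fasta(file.path(out_dir, regfa_p))
    regions <- read_tsv_schema(file.path(out_dir, regions_p),
                               c("protein_id", "region_id", "start", "end",
                                 "length", "tm_pair"))
    regions$sequence <- unname(seqs[regions$region_id])
    state$regions <- regions
  })
  regions <- state$regions

  ## -- reduce --------------------------------------------------------
  nr_p <- "regions_nr.fasta"
  run_stage("reduce", nr_p, fn = function() {
    seqs <- setNames(regions$sequence, regions$region_id)
    red <- reduce_redundancy(seqs, config$reduce$identity_threshold)
    state$nr_seqs <- seqs[red$retained]
    write_fasta(state$nr_seqs, file.path(out_dir, nr_p))
  }, load_fn = function() {
    state$nr_seqs <- read_fasta(file.path(out_dir, nr_p))
  })
  nr_seqs <- state$nr_seqs

  ## -- network -------------------------------------------------------
  hits_p <- "hits.tsv"
  run_stage("network", hits_p, fn = function() {
    state$hits <- align_all(nr_seqs, gap_open = config$alignment$gap_open,
                            gap_extend = config$alignment$gap_extend)
    write_tsv(state$hits, file.path(out_dir, hits_p))
  }, load_fn = function() {
    state$hits <- read_tsv_schema(file.path(out_dir, hits_p),
                                  c("query_id", "subject_id", "bits", "evalue",
                                    "query_coverage", "identity"))
  })
  hits <- state$hits

  ## -- cluster -------------------------------------------------------
  clusters_p <- "clusters.tsv"
  graph <- build_graph(hits, nodes = names(nr_seqs),
                       evalue_max = config$network$evalue_max,
                       coverage_min = config$network$coverage_min)
  comp <- graph_components(graph, min_size = config$cluster$min_size)
  run_stage("cluster", clusters_p, fn = function() {
    df <- data.frame(cluster_id = unname(comp$membership),
                     member_id = names(comp$membership))
    write_tsv(df[order(df$cluster_id, df$member_id), ],
              file.path(out_dir, clusters_p))
  }, load_fn = function() NULL)

  ## -- represent -----------------------------------------------------
  reps_p <- "representatives.tsv"
  kept_clusters <- comp$clusters[comp$filtered]
  run_stage("represent", reps_p, fn = function() {
    reps <- representatives_for_clusters(kept_clusters, hits,
                                         evalue_max = config$represent$evalue_max,
                                         coverage_min = config$represent$coverage_min)
    write_tsv(reps, file.path(out_dir, reps_p))
  }, load_fn = function() NULL)

  ## -- align + build + calibrate -------------------------------------
  models_p <- "models.json"
  run_stage("build", models_p, fn = function() {
    alignments <- lapply(kept_clusters, function(members)
      progressive_align(nr_seqs[members]))
    models <- lapply(names(alignments), function(cid) {
      m <- build_profile(alignments[[cid]],
                         match_fraction = config$profiles$match_fraction,
                         pseudocount = config$profiles$pseudocount,
                         model_id = cid)
      calibrate(m, n_random = config$profiles$calibration_n,
                random_length = config$profiles$calibration_length,
                rng_seed = derive_seed(seed, 100L + match(cid, names(alignments))))
    })
    names(models) <- names(alignments)
    state$alignments <- alignments
    state$models <- models
    save_models(models, file.path(out_dir, models_p))
  }, load_fn = function() {
    state$models <- load_models(file.path(out_dir, models_p))
    state$alignments <- lapply(state$models, `[[`, "alignment")
  })

  ## -- merge ---------------------------------------------------------
  merged_p <- "models_merged.json"
  run_stage("merge", merged_p, fn = function() {
    mg <- merge_clusters(state$models, state$alignments,
                         probability_min = config$merge$probability_min,
                         coverage_min = config$merge$coverage_min,
                         rng_seed = derive_seed(seed, 200L),
                         match_fraction = config$profiles$match_fraction,
                         pseudocount = config$profiles$pseudocount)
    mg$models <- lapply(mg$models, function(m)
      if (is.na(m$mu))
        calibrate(m, n_random = config$profiles$calibration_n,
                  random_length = config$profiles$calibration_length,
                  rng_seed = derive_seed(seed, 300L)) else m)
    state$final_models <- mg$models
    state$merged_from <- mg$merged_from
    save_models(mg$models, file.path(out_dir, merged_p))
  }, load_fn = function() {
    state$final_models <- load_models(file.path(out_dir, merged_p))
    state$merged_from <- lapply(state$final_models, function(m)
      strsplit(m$model_id, "+", fixed = TRUE)[[1]])
  })
  models <- state$final_models

  ## -- scan ----------------------------------------------------------
  scan_p <- "domain_hits.tsv"
  run_stage("scan", scan_p, fn = function() {
    rh <- scan_sequences(models, nr_seqs,
                         seq_evalue_max = config$profiles$seq_evalue_max,
                         dom_evalue_max = config$profiles$dom_evalue_max)
    state$region_hits <- rh
    write_tsv(rh, file.path(out_dir, scan_p))
  }, load_fn = function() {
    state$region_hits <- read_tsv_schema(file.path(out_dir, scan_p),
                                         c("protein_id", "model_id", "start",
                                           "end", "bits", "seq_evalue",
                                           "dom_evalue"))
  })
  region_hits <- state$region_hits

  ## hits in protein coordinates (region offset applied)
  to_protein_coords <- function(h) {
    if (!nrow(h)) return(h)
    loc <- parse_region_ids(h$protein_id)
    h$start <- h$start + loc$start - 1L
    h$end <- h$end + loc$start - 1L
    h$protein_id <- loc$protein_id
    h
  }
  protein_hits <- to_protein_coords(region_hits)
  ## one best model per region: the counting unit of the census
  best_protein_hits <- to_protein_coords(best_hits_per_region(region_hits))

  ## -- clans ---------------------------------------------------------
  clans_p <- "clans.tsv"; ppgraph_p <- "family_graph.tsv"
  truth_majority <- cluster_truth_majority(comp, prot$truth, regions)
  fam_sf <- unlist(prot$params$family_superfamily)
  pp_hits <- if (length(models) >= 2)
    pp_compare_all(models, rng_seed = derive_seed(seed, 400L)) else
      data.frame(model_a = character(0), model_b = character(0),
                 score = numeric(0), evalue = numeric(0), prob = numeric(0),
                 coverage_a = numeric(0), coverage_b = numeric(0))
  fg <- build_family_graph(pp_hits, e_thick = config$clans$e_thick,
                           e_thin = config$clans$e_thin,
                           prob_dotted = config$clans$prob_dotted)
  seed_clans <- seed_clans_from_truth(models, truth_majority, fam_sf)
  clan_assign <- assign_clans(fg, seed_clans, pp_hits)
  ## family similarity matrix (probability scores) for tree and heat map
  sim <- NULL
  if (length(models) >= 3) {
    ids <- names(models)
    sim <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(sim) <- 100
    for (i in seq_len(nrow(pp_hits)))
      sim[pp_hits$model_a[i], pp_hits$model_b[i]] <- pp_hits$prob[i]
  }
  dendro_p <- "family_dendrogram.nwk"; hm_p <- "family_heatmap_order.tsv"
  run_stage("clans", c(clans_p, ppgraph_p, dendro_p, hm_p), fn = function() {
    write_tsv(clan_assign, file.path(out_dir, clans_p))
    write_tsv(fg$edges, file.path(out_dir, ppgraph_p))
    if (!is.null(sim)) {
      dd <- upgma_dendrogram(sim)
      writeLines(dd$newick, file.path(out_dir, dendro_p))
      hm <- family_heatmap(sim, prob_floor = config$census$heatmap_floor)
      write_tsv(data.frame(rank = seq_along(hm$order), model_id = hm$order),
                file.path(out_dir, hm_p))
    } else {
      writeLines(";", file.path(out_dir, dendro_p))
      write_tsv(data.frame(rank = integer(0), model_id = character(0)),
                file.path(out_dir, hm_p))
    }
  }, load_fn = function() NULL)

  ## -- census --------------------------------------------------------
  census_p <- c("census_lengths.tsv", "census_coverage.tsv",
                "census_abundance.tsv", "census_phyletic.tsv")
  model_truth_family <- model_truth_families(models, truth_majority)
  run_stage("census", census_p, fn = function() {
    kinds <- model_kinds(models, model_truth_family, prot$params$families)
    ld <- length_distribution(best_protein_hits, kinds,
                              centers = config$census$length_centers)
    cov <- coverage_table(best_protein_hits, regions)
    clan_map <- setNames(clan_assign$clan_id, clan_assign$model_id)
    ab <- abundance_ranking(region_hits, clan_map)
    taxa <- prot$truth[, c("protein_id", "taxon_id", "species_id")]
    phyl <- phyletic_matrix(best_protein_hits, taxa,
                            min_proteins = config$census$min_proteins)
    state$census <- list(lengths = ld, coverage = cov, abundance = ab,
                         phyletic = phyl)
    write_tsv(ld$summary, file.path(out_dir, census_p[1]))
    write_tsv(cov$freq, file.path(out_dir, census_p[2]))
    write_tsv(ab$per_family, file.path(out_dir, census_p[3]))
    pm <- state$census$phyletic$matrix
    pm <- cbind(species = rownames(pm), pm)
    write_tsv(pm, file.path(out_dir, census_p[4]))
  }, load_fn = function() NULL)

  manifest$config <- unclass(config)
  manifest$out_dir <- out_dir
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, out_dir = out_dir,
                 proteome = prot, topology = topo, regions = regions,
                 nr_seqs = nr_seqs, hits = hits, graph = graph,
                 components = comp, models = models,
                 family_graph = fg, clans = clan_assign,
                 region_hits = region_hits, protein_hits = protein_hits,
                 best_protein_hits = best_protein_hits,
                 census = state$census))
}

## majority planted family per cluster, via region -> protein -> truth
cluster_truth_majority <- function(comp, truth, regions) {
  prot_of <- setNames(regions$protein_id, regions$region_id)
  fam_of <- setNames(truth$family_id, truth$protein_id)
  vapply(comp$clusters, function(members) {
    fams <- fam_of[prot_of[members]]
    fams <- fams[!is.na(fams)]
    if (!length(fams)) return(NA_character_)
    names(sort(table(fams), decreasing = TRUE))[1]
  }, character(1))
}

## map each (possibly merged) model to the truth families of its sources
model_truth_families <- function(models, truth_majority) {
  lapply(models, function(m) {
    src <- strsplit(m$model_id, "+", fixed = TRUE)[[1]]
    unname(stats::na.omit(truth_majority[src]))
  })
}

## seed clans: for each planted superfamily, label the model containing its
## first family (in real use these seeds come from curated annotations)
seed_clans_from_truth <- function(models, truth_majority, fam_sf) {
  seeds <- character(0)
  for (s in unique(fam_sf)) {
    fams <- names(fam_sf)[fam_sf == s]
    for (m in models) {
      src <- strsplit(m$model_id, "+", fixed = TRUE)[[1]]
      if (any(truth_majority[src] %in% fams)) {
        seeds[m$model_id] <- s
        break
      }
    }
  }
  seeds
}

## single/double kind of each model from its planted source families
model_kinds <- function(models, model_truth_family, family_specs) {
  kind_of <- vapply(family_specs, `[[`, "", "kind")
  names(kind_of) <- vapply(family_specs, `[[`, "", "family_id")
  vapply(names(models), function(nm) {
    fams <- model_truth_family[[nm]]
    fams <- fams[fams %in% names(kind_of)]
    if (!length(fams)) return("single")
    names(sort(table(kind_of[fams]), decreasing = TRUE))[1]
  }, character(1))
}

#' Save / load a model library as JSON
#' @param models named list of `profile_hmm`
#' @param path JSON path
#' @export
save_models <- function(models, path) {
  tmp <- lapply(models, function(m) {
    x <- unclass(m)
    x$match_em <- unname(apply(m$match_em, 1, as.numeric, simplify = FALSE))
    x$alignment <- list(ids = names(m$alignment), rows = unname(m$alignment))
    x
  })
  jsonlite::write_json(tmp, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(raw, function(x) {
    em <- if (is.matrix(x$match_em)) x$match_em else do.call(rbind, x$match_em)
    colnames(em) <- AA_ALPHABET
    structure(list(
      model_id = x$model_id, length = as.integer(x$length), match_em = em,
      insert_em = setNames(as.numeric(x$insert_em), AA_ALPHABET),
      trans = lapply(x$trans, as.numeric),
      exit = as.numeric(x$exit), entry = as.numeric(x$entry),
      background = setNames(as.numeric(x$background), AA_ALPHABET),
      match_columns = as.integer(x$match_columns),
      nseq = as.integer(x$nseq),
      alignment = setNames(x$alignment$rows, x$alignment$ids),
      mu = if (is.null(x$mu) || is.na(x$mu)) NA_real_ else as.numeric(x$mu),
      lambda_g = if (is.null(x$lambda_g) || is.na(x$lambda_g)) NA_real_
        else as.numeric(x$lambda_g),
      calibration = x$calibration), class = "profile_hmm")
  })
  names(models) <- vapply(models, `[[`, "", "model_id")
  models
}
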