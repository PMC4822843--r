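#' Specify a planted sensor-domain family
#'
#' A family is defined by a consensus sequence (generated once per run) from
#' which members are sampled at a given divergence.  `kind = "double"` makes
#' the consensus a tandem of two subdomain consensi, mirroring the two-lobed
#' architecture of double sensor domains; the subdomain boundary is recorded
#' so fusion experiments can address the halves.
#'
#' @param family_id character label
#' @param kind "single" or "double"
#' @param domain_length target mean length in residues (single domains
#'   default to 140, double to 271, the mean lengths of known structures)
#' @param n_seed_sequences number of members to emit per proteome
#' @param divergence expected substitutions per site from the consensus,
#'   in (0, 1)
#' @param superfamily_id clan label; families sharing a superfamily are
#'   generated from a common ancestral consensus
#' @return object of class `family_spec`
#' @export
family_spec <- function(family_id, kind = c("single", "double"),
                        domain_length = NULL, n_seed_sequences = 40,
                        divergence = 0.25, superfamily_id = family_id) {
  kind <- match.arg(kind)
  if (is.null(domain_length))
    domain_length <- if (kind == "single") 140 else 271
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (domain_length < 30)
    stop("domain_length must be >= 30")
  if (!(divergence > 0 && divergence < 1))
    stop("divergence must lie strictly in (0, 1)")
  structure(list(family_id = family_id, kind = kind,
                 domain_length = domain_length,
                 n_seed_sequences = as.integer(n_seed_sequences),
                 divergence = divergence,
                 superfamily_id = superfamily_id),
            class = "family_spec")
}

#' Specify the synthetic proteome architecture
#'
#' Controls how many proteins are emitted and in which architecture class:
#' sensor-bearing proteins (TM - planted extracellular domain - TM - linker -
#' output domain), intracellular-sensor decoys (family domain placed
#' cytoplasmically, no TM), and sensor-less decoys (TM - random extracellular
#' region - TM - output domain), the latter providing decoy regions for
#' false-positive measurement.
#'
#' @param n_proteins total proteins
#' @param fraction_sensor_bearing fraction carrying a planted family domain
#'   extracellularly
#' @param fraction_intracellular_decoys fraction carrying a family domain
#'   cytoplasmically
#' @param output_domain_motif consensus of the cytoplasmic output domain
#' @param tm_length transmembrane helix length (>= 15)
#' @param loop_length_range residue interval for tails and linkers
#' @return object of class `architecture_spec`
#' @export
architecture_spec <- function(n_proteins = 300,
                              fraction_sensor_bearing = 0.6,
                              fraction_intracellular_decoys = 0.15,
                              output_domain_motif = OUTPUT_MOTIF_DEFAULT,
                              tm_length = 21,
                              loop_length_range = c(15, 40)) {
  if (fraction_sensor_bearing < 0 || fraction_intracellular_decoys < 0 ||
      fraction_sensor_bearing + fraction_intracellular_decoys > 1)
    stop("architecture fractions must be non-negative and sum to <= 1")
  if (tm_length < 15) stop("tm_length must be >= 15")
  stopifnot(length(loop_length_range) == 2L,
            loop_length_range[1] <= loop_length_range[2])
  structure(list(n_proteins = as.integer(n_proteins),
                 fraction_sensor_bearing = fraction_sensor_bearing,
                 fraction_intracellular_decoys = fraction_intracellular_decoys,
                 output_domain_motif = output_domain_motif,
                 tm_length = as.integer(tm_length),
                 loop_length_range = as.integer(loop_length_range)),
            class = "architecture_spec")
}

#' Generate a family consensus sequence
#'
#' Draws a consensus of length within 10% of the target from the
#' extracellular composition (see [aa_composition()]).  Double-domain
#' consensi are emitted as a tandem of two subdomain consensi; the 1-based
#' start of the second subdomain is recorded in the
#' `"subdomain_boundary"` attribute.
#'
#' @param spec a [family_spec()]
#' @param rng_seed integer seed; the call is deterministic given the seed
#' @return character scalar with attributes `family_id` and (for double
#'   domains) `subdomain_boundary`
#' @export
generate_family_consensus <- function(spec, rng_seed) {
  if (!inherits(spec, "family_spec")) stop("spec must be a family_spec")
  comp <- aa_composition("extracellular")
  with_seed(rng_seed, {
    len <- max(30L, round(spec$domain_length * runif(1, 0.95, 1.05)))
    if (spec$kind == "single") {
      cons <- chars_to_str(sample_residues(len, comp))
      attr(cons, "family_id") <- spec$family_id
      cons
    } else {
      l1 <- round(len / 2)
      part1 <- chars_to_str(sample_residues(l1, comp))
      part2 <- chars_to_str(sample_residues(len - l1, comp))
      cons <- paste0(part1, part2)
      attr(cons, "family_id") <- spec$family_id
      attr(cons, "subdomain_boundary") <- l1 + 1L
      cons
    }
  })
}

#' Sample a diverged family member from a consensus
#'
#' Each site is substituted with probability `divergence`; the replacement
#' is drawn from the background composition renormalised over the 19
#' non-identical residues, so the expected identity to the consensus is
#' exactly `1 - divergence` (before indels).  Small indels are applied at
#' rate `indel_rate` per site with geometric lengths of mean 2.
#'
#' @param consensus character scalar
#' @param divergence substitution probability per site, in (0, 1)
#' @param rng_seed integer seed
#' @param indel_rate per-site indel probability (default 0.01)
#' @param composition residue frequencies the substitution kernel and
#'   inserted residues are drawn from (default the background null);
#'   sequences evolved under a given composition keep that composition
#' @return character scalar
#' @export
sample_family_member <- function(consensus, divergence, rng_seed,
                                 indel_rate = 0.01,
                                 composition = aa_composition("background")) {
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  if (!(divergence > 0 && divergence < 1) && divergence != 0)
    stop("divergence must lie in [0, 1)")
  bg <- composition
  with_seed(rng_seed, {
    res <- str_to_chars(consensus)
    n <- length(res)
    sub_mask <- runif(n) < divergence
    if (any(sub_mask)) {
      for (i in which(sub_mask)) {
        w <- bg
        w[res[i]] <- 0
        res[i] <- sample(AA_ALPHABET, 1, prob = w[AA_ALPHABET])
      }
    }
    if (indel_rate > 0) {
      ev <- runif(n) < indel_rate
      if (any(ev)) {
        out <- vector("list", n)
        for (i in seq_len(n)) {
          if (!ev[i]) { out[[i]] <- res[i]; next }
          if (runif(1) < 0.5) {
            out[[i]] <- character(0)          # deletion
          } else {                            # insertion after site i
            k <- stats::rgeom(1, 0.5) + 1L
            out[[i]] <- c(res[i], sample_residues(k, bg))
          }
        }
        res <- unlist(out)
      }
    }
    chars_to_str(res)
  })
}

## Sample a loop/tail of random length from the hydrophilic composition.
random_loop <- function(range) {
  n <- sample(seq(range[1], range[2]), 1)
  chars_to_str(sample_residues(n, aa_composition("loop")))
}

random_tm <- function(len) chars_to_str(sample_residues(len, aa_composition("tm")))

topology_string <- function(segments) {
  paste(sprintf("%s:%d-%d", segments$label, segments$start, segments$end),
        collapse = ";")
}

#' Generate a synthetic proteome with planted sensor families
#'
#' Emits `arch$n_proteins` proteins across `n_taxa` species (each with 1-2
#' strains) together with a ground-truth table.  Sensor-bearing proteins have
#' layout N-tail - TM - planted family domain - TM - linker - output domain -
#' C-tail; the planted domain occupies the entire extracellular region
#' between the two TM helices.  Families sharing a `superfamily_id` descend
#' from a common ancestral consensus (divergence `superfamily_divergence`),
#' giving the library a two-level homology structure.  Each family is present
#' in a random subset of species (recorded), providing phyletic structure.
#'
#' @param arch an [architecture_spec()]
#' @param families list of [family_spec()]
#' @param n_taxa number of species
#' @param rng_seed integer master seed; all randomness derives from it
#' @param superfamily_divergence divergence of each family consensus from
#'   its superfamily ancestor (default 0.50)
#' @param taxon_presence_prob probability a family is present in a species
#' @return list with `sequences` (named character), `truth` (data.frame with
#'   columns protein_id, taxon_id, species_id, class, family_id,
#'   region_start, region_end, topology), `consensus` (named character),
#'   and `params`
#' @export
generate_proteome <- function(arch, families, n_taxa = 8, rng_seed = 1,
                              superfamily_divergence = 0.50,
                              taxon_presence_prob = 0.7) {
  if (!inherits(arch, "architecture_spec")) stop("arch must be an architecture_spec")
  if (length(families) < 1) stop("at least one family is required")
  fam_ids <- vapply(families, `[[`, "", "family_id")
  names(families) <- fam_ids

  ## family consensi: one ancestor per superfamily; single families diverge
  ## from it, double families are fusions of two single-family consensi
  sf <- vapply(families, `[[`, "", "superfamily_id")
  cg <- build_family_consensi(families, rng_seed, superfamily_divergence)
  consensus <- cg$consensus
  boundary <- cg$boundary

  ## taxa: species sp01..spN with 1-2 strains each
  species <- sprintf("sp%02d", seq_len(n_taxa))
  strains <- with_seed(derive_seed(rng_seed, 17L), {
    lapply(species, function(s)
      paste0(s, "_s", seq_len(sample(1:2, 1))))
  })
  names(strains) <- species
  presence <- with_seed(derive_seed(rng_seed, 23L), {
    m <- matrix(stats::runif(length(families) * n_taxa) < taxon_presence_prob,
                nrow = length(families),
                dimnames = list(fam_ids, species))
    ## guarantee every family occurs somewhere
    for (i in seq_len(nrow(m))) if (!any(m[i, ])) m[i, sample(n_taxa, 1)] <- TRUE
    m
  })

  n <- arch$n_proteins
  n_sensor <- round(n * arch$fraction_sensor_bearing)
  n_intra <- round(n * arch$fraction_intracellular_decoys)
  n_plain <- n - n_sensor - n_intra
  classes <- c(rep("sensor", n_sensor), rep("intracellular", n_intra),
               rep("sensorless", n_plain))
  ## sensors apportioned to families in proportion to n_seed_sequences
  pool <- rep(fam_ids, vapply(families, `[[`, 1L, "n_seed_sequences"))
  fam_of <- c(rep_len(pool, n_sensor), rep_len(fam_ids, n_intra),
              rep(NA_character_, n_plain))

  rows <- vector("list", n)
  seqs <- setNames(character(n), sprintf("prot%04d", seq_len(n)))
  for (i in seq_len(n)) {
    pid <- names(seqs)[i]
    seed_i <- derive_seed(rng_seed, i)
    rec <- with_seed(seed_i, {
      cls <- classes[i]
      fam <- fam_of[i]
      if (!is.na(fam)) {
        sp_ok <- species[presence[fam, ]]
      } else sp_ok <- species
      sp <- sample(sp_ok, 1)
      tax <- sample(strains[[sp]], 1)
      lr <- arch$loop_length_range
      if (cls == "sensor" || cls == "sensorless") {
        ntail <- random_loop(lr)
        tm1 <- random_tm(arch$tm_length)
        if (cls == "sensor") {
          dom <- sample_family_member(consensus[fam], families[[fam]]$divergence,
                                      derive_seed(seed_i, 2L),
                                      composition = aa_composition("extracellular"))
        } else {
          dlen <- max(60L, round(stats::rnorm(1, 140, 25)))
          dom <- chars_to_str(sample_residues(dlen, aa_composition("extracellular")))
        }
        tm2 <- random_tm(arch$tm_length)
        linker <- random_loop(lr)
        outd <- sample_family_member(arch$output_domain_motif, 0.1,
                                     derive_seed(seed_i, 3L), indel_rate = 0,
                                     composition = aa_composition("loop"))
        ctail <- random_loop(lr)
        seq <- paste0(ntail, tm1, dom, tm2, linker, outd, ctail)
        p1 <- nchar(ntail); p2 <- p1 + nchar(tm1)
        p3 <- p2 + nchar(dom); p4 <- p3 + nchar(tm2)
        segs <- data.frame(
          label = c("inside", "membrane", "outside", "membrane", "inside"),
          start = c(1L, p1 + 1L, p2 + 1L, p3 + 1L, p4 + 1L),
          end = c(p1, p2, p3, p4, nchar(seq)))
        list(seq = seq, taxon = tax, sp = sp, class = cls,
             family = if (cls == "sensor") fam else NA_character_,
             rs = p2 + 1L, re = p3, topo = topology_string(segs))
      } else {
        ## intracellular decoy: family-like domain, no TM at all
        ntail <- random_loop(lr)
        dom <- sample_family_member(consensus[fam], families[[fam]]$divergence,
                                    derive_seed(seed_i, 2L),
                                    composition = aa_composition("extracellular"))
        linker <- random_loop(lr)
        outd <- sample_family_member(arch$output_domain_motif, 0.1,
                                     derive_seed(seed_i, 3L), indel_rate = 0,
                                     composition = aa_composition("loop"))
        seq <- paste0(ntail, dom, linker, outd)
        segs <- data.frame(label = "inside", start = 1L, end = nchar(seq))
        list(seq = seq, taxon = tax, sp = sp, class = cls, family = fam,
             rs = nchar(ntail) + 1L, re = nchar(ntail) + nchar(dom),
             topo = topology_string(segs))
      }
    })
    seqs[i] <- rec$seq
    rows[[i]] <- data.frame(protein_id = pid, taxon_id = rec$taxon,
                            species_id = rec$sp, class = rec$class,
                            family_id = rec$family,
                            region_start = rec$rs, region_end = rec$re,
                            topology = rec$topo)
  }
  truth <- do.call(rbind, rows)
  fam_sf <- setNames(sf, fam_ids)
  list(sequences = seqs, truth = truth, consensus = consensus,
       subdomain_boundary = boundary, subdomain_sources = cg$sources,
       params = list(arch = unclass(arch),
                     families = lapply(families, unclass),
                     n_taxa = n_taxa, rng_seed = rng_seed,
                     superfamily_divergence = superfamily_divergence,
                     taxon_presence_prob = taxon_presence_prob,
                     family_superfamily = as.list(fam_sf),
                     presence = presence))
}

#' Generate related consensus sequences for a family set
#'
#' Families sharing a `superfamily_id` are tied together by a common
#' ancestral consensus: each single-domain family consensus is the ancestor
#' diverged by `superfamily_divergence` substitutions per site, and each
#' double-domain family consensus is a tandem fusion of two (diverged
#' copies of) single-family consensi from the same superfamily — the first
#' two singles, recycled when fewer exist — so that the membrane-distal
#' half of a double family genuinely descends from one single family and
#' the membrane-proximal half from another.  Superfamilies are mutually
#' unrelated by construction.
#'
#' @param families list of [family_spec()]
#' @param rng_seed integer seed
#' @param superfamily_divergence divergence of each family consensus from
#'   the superfamily ancestor (and of fusion halves from their sources)
#' @return list: `consensus` (named character), `boundary` (named integer,
#'   NA for singles), `sources` (named list c(N, C) per double family)
#' @export
build_family_consensi <- function(families, rng_seed,
                                  superfamily_divergence = 0.50) {
  fam_ids <- vapply(families, `[[`, "", "family_id")
  names(families) <- fam_ids
  sf <- vapply(families, `[[`, "", "superfamily_id")
  kind <- vapply(families, `[[`, "", "kind")
  consensus <- setNames(character(length(families)), fam_ids)
  boundary <- setNames(rep(NA_integer_, length(families)), fam_ids)
  sources <- list()
  comp <- aa_composition("extracellular")
  for (si in seq_along(unique(sf))) {
    s <- unique(sf)[si]
    members <- fam_ids[sf == s]
    singles <- members[kind[members] == "single"]
    pseudo <- character(0)
    anc_len <- if (length(singles))
      families[[singles[1]]]$domain_length else
        round(families[[members[1]]]$domain_length / 2)
    anc <- with_seed(derive_seed(rng_seed, 900L + si),
                     chars_to_str(sample_residues(anc_len, comp)))
    derive <- function(from, idx)
      sample_family_member(from, superfamily_divergence,
                           derive_seed(rng_seed, 1000L + idx), indel_rate = 0,
                           composition = aa_composition("extracellular"))
    for (f in singles)
      consensus[f] <- derive(anc, match(f, fam_ids))
    if (!length(singles) && any(kind[members] == "double")) {
      ## no single family to fuse from: derive two pseudo-sources
      pseudo <- c("..src1", "..src2")
      consensus[pseudo] <- c(derive(anc, 500L + 2L * si),
                             derive(anc, 501L + 2L * si))
    }
    srcs <- c(singles, pseudo)
    for (f in members[kind[members] == "double"]) {
      pick <- rep_len(srcs, 2)
      n_len <- families[[f]]$domain_length %/% 2L
      c_len <- families[[f]]$domain_length - n_len
      idx <- match(f, fam_ids)
      npart <- derive(consensus[pick[1]], 2000L + idx)
      cpart <- derive(consensus[pick[2]], 3000L + idx)
      npart <- substr(npart, 1, min(nchar(npart), n_len))
      cpart <- substr(cpart, 1, min(nchar(cpart), c_len))
      consensus[f] <- paste0(npart, cpart)
      boundary[f] <- nchar(npart) + 1L
      sources[[f]] <- c(N = pick[1], C = pick[2])
    }
    consensus <- consensus[setdiff(names(consensus), pseudo)]
  }
  list(consensus = consensus[fam_ids], boundary = boundary,
       sources = sources)
}

#' Default planted family set
#'
#' Six families in two superfamilies (four single-domain families around
#' 140 aa, two double-domain families around 271 aa), 40 members each at
#' divergence 0.25 — the study conditions used throughout the test-bench.
#'
#' @param n_members members per family
#' @param divergence member divergence from the family consensus
#' @return list of [family_spec()]
#' @export
default_family_set <- function(n_members = 40, divergence = 0.25) {
  list(
    family_spec("sA1", "single", 140, n_members, divergence, superfamily_id = "SFA"),
    family_spec("sA2", "single", 140, n_members, divergence, superfamily_id = "SFA"),
    family_spec("sA3", "single", 140, n_members, divergence, superfamily_id = "SFA"),
    family_spec("sB1", "single", 130, n_members, divergence, superfamily_id = "SFB"),
    family_spec("dA1", "double", 271, n_members, divergence, superfamily_id = "SFA"),
    family_spec("dB1", "double", 271, n_members, divergence, superfamily_id = "SFB"))
}
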