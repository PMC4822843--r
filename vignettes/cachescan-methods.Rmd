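---
title: "Discovering extracellular sensory domain families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering extracellular sensory domain families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Prokaryotic signal-transduction receptors — sensor histidine kinases,
chemoreceptors, c-di-GMP cyclases and phosphodiesterases — typically sense
their ligands through a periplasmic module held between two transmembrane
(TM) helices, and act through a cytoplasmic output module.  The Cache
superfamily is the dominant family of such extracellular sensors, yet its
families are so divergent at the sequence level that generic database
searches fragment them.  `cachescan` implements, as a reusable and fully
testable pipeline, the discovery strategy that works in this regime:

1. restrict the universe to proteins carrying a recognised output
   signalling domain;
2. predict membrane topology and cut out every extracytoplasmic region
   longer than 50 residues that lies between two TM helices;
3. remove redundancy at 90% identity, compare all remaining regions
   all-against-all, and keep reciprocal links with E-value < 1e-10 and
   query coverage > 95%; each connected component of the resulting graph
   is a cluster, and clusters with at least ten members are retained;
4. select representative sequences per cluster by a greedy
   maximum-coverage algorithm;
5. align each cluster, build a profile hidden Markov model (HMM),
   calibrate its score distribution, and merge models that are
   near-duplicates of one another;
6. scan sequences with the calibrated models at sequence and domain
   E-value 1e-3;
7. relate models to each other by profile–profile comparison, and assign
   families to superfamilies (clans) by a three-rule cascade
   (reciprocal E < 1e-3; closest superfamily; mutual best hit);
8. summarise the result as a census: domain-length distributions, model
   coverage of regions, abundance ranking, and phyletic presence/absence.

Because the natural inputs are whole database releases, every stage here
is exercised instead on a synthetic proteome generator that plants sensor
families with full ground truth.  The package is aimed at method
developers and comparative genomicists who want the pipeline's logic —
thresholds, tie-breaks, calibration — explicit, tested and reusable.

# The synthetic proteome generator

The generator is a first-class module, not a test fixture.  It emits
proteins in three architecture classes:

* **sensor-bearing** — N-tail, TM helix, planted family domain (the domain
  occupies the *entire* extracellular region), TM helix, linker, output
  domain, C-tail;
* **intracellular decoys** — the same family domains placed cytoplasmically
  in TM-less proteins, exercising the localization census;
* **sensor-less decoys** — the TM–region–TM architecture with a random
  extracellular region, providing decoys for false-positive measurement.

Each protein carries a taxon label (species with one or two strains);
each family is planted in a random subset of species, recorded in the
truth table, so phyletic aggregation can be checked against ground truth.

**Compositions.** All sampling flows from one canonical background (the
Robinson–Robinson frequencies, also used as the null model and for
pseudocounts).  Extracellular domains are drawn from that background with
strongly hydrophobic residues down-weighted, loops from a hydrophilic
subset, and TM helices from a hydrophobic pool biased towards Leu/Ile/Val.
These choices make the planted architecture *detectable by construction*
by a sliding hydropathy window, which is the stated role of the topology
stand-in; the generator does not attempt real membrane physics, signal
peptides, or TM grammar.

**Family structure.** A family is a consensus sequence plus members
sampled at an expected divergence of 0.25 substitutions per site (the
substitution kernel re-draws from the composition excluding the original
residue, so expected identity is exactly `1 - divergence`; indels occur at
0.01/site with geometric mean length 2).  Single-domain families target
140 residues and double-domain families 271 residues — the mean lengths
of single and double sensory domains of known structure.  Families that
share a superfamily descend from a common ancestral consensus; double
families are built as tandem fusions of two single-family consensi of the
same superfamily, so each half has a genuine single-family origin (this
carries the membrane-distal/membrane-proximal subdomain experiment).

**Why superfamily divergence defaults to 0.50.** The value controls the
two-level homology structure and was fixed from measured score
distributions, not tuned to any test: at ancestor divergence 0.30–0.40 the
upper tail of cross-family member pairs crosses the clustering edge
threshold (E < 1e-10 with > 95% reciprocal coverage), and single spurious
edges chain related families into one connected component.  At 0.50,
cross-family sequence pairs sit orders of magnitude away from the edge
threshold while profile–profile comparisons still link the families
decisively (E far below 1e-3).  This reproduces the regime the pipeline
is designed for: divergent sensor families that separate into distinct
clusters at these thresholds yet are clearly homologous at the
profile–profile level.  Superfamilies themselves are mutually unrelated by
construction.

**What passing tests do and do not show.** The generator produces
alignable, globular-composition domains with clean TM boundaries, i.i.d.
sites and no phylogenetic correlation between members.  Success on it
demonstrates that the pipeline's logic and thresholds behave as specified
— not that the stand-in topology predictor or the simple progressive
aligner match TMHMM or MAFFT on real proteomes.  For real data the module
boundaries accept imported topology TSVs and externally computed
alignments.

# Topology and region extraction

The built-in stand-in computes mean Kyte–Doolittle hydropathy in a
19-residue window (threshold 1.6, classic settings).  Runs of
above-threshold windows become membrane segments spanning the window
*centres* — empirically this tracks helix boundaries within 2–3 residues,
whereas using whole-window extents biases each boundary by half a window.
Membrane segments separated by at most 6 residues are bridged: genuine
inter-helix loops are much longer, and 1–2-residue dips below threshold
inside one helix would otherwise split it and flip the inside/outside
alternation.  Orientation is assigned by alternation from an N-in default
(configurable); the orientation models of dedicated TM predictors are out of
scope.

Region extraction is exact and literal: an outside segment qualifies only
if it lies strictly between two membrane segments and is *longer than* 50
residues — length 50 is rejected, 51 kept.  Coordinates are 1-based
inclusive throughout.

# Pairwise comparison and the similarity network

Pairwise alignment is exact Smith–Waterman under BLOSUM62 with affine gap
penalties 11/1 (via Biostrings); no word-indexed heuristics are used at
this scale.  Raw scores are converted to bits with the standard BLOSUM62
ungapped-approximation constants (λ = 0.3176, K = 0.134) and to E-values
by E = m·n·2^(−bits); only threshold behaviour matters, and the constants
are recorded in the configuration.  Identity uses alignment columns for
network hits and the shorter-sequence length for redundancy reduction,
mirroring the conventions of the tools each step stands in for.  The
CD-HIT-style redundancy pass sorts by length (ties lexicographic), joins
each sequence to the first retained sequence at ≥ 90% identity, and uses a
shared-k-mer prefilter only to skip pairs that provably cannot reach the
threshold — the decision itself is always made by exact alignment.

Edges of the similarity graph require both directional hits to pass
E < 1e-10 (strict) and query coverage > 95% (strict), and clusters are
connected components, validated in the tests against a transitive-closure
oracle.

# Representative selection

Each query represents the set of subjects whose hits pass the thresholds,
plus itself (self-membership is enforced even if the aligner omits
self-hits, since otherwise coverage can be impossible).  Sets identical to
or subsets of another are discarded once, before selection.  Selection is
greedy maximum coverage: first the largest set, then whichever set most
enlarges the working set, until the working set equals the input.  The
procedure as usually described leaves tie-breaks open; this implementation breaks
ties by larger raw set size, then lexicographically smaller representative
id, and records the rule in its output so runs are reproducible across
platforms.  The suite checks the selection against an independently coded
brute-force greedy on random set systems.

# Profile HMMs

Profiles are built with the standard conventions: alignment columns with
at least 50% residues become match states; sequences receive Henikoff
position-based weights; match emissions are weighted counts blended with
background pseudocounts (total pseudocount mass 1, so the background's
relative weight decays as the effective sequence number grows);
transitions come from weighted path counts with small priors (inserts
adjacent to delete states cannot be expressed in this architecture and
are dropped from the counts).  The model is uni-local: entry into any
match state is uniformly 1/L, every match state carries a fixed exit mass
(0.1; the final state exits with probability 1), inserts emit background,
and flanking residues are scored by the null — so a domain can sit
anywhere inside a larger protein.  The forward and Viterbi recurrences are
implemented in C++ and the forward score is verified against an exhaustive
path-enumeration oracle on toy models to 1e-9 relative accuracy.

**Calibration.** Each model's forward-score distribution on i.i.d.
background sequences (default 400 draws of length 150) is fitted with a
maximum-likelihood Gumbel; a scanned score s then has
P = 1 − exp(−exp(−λ_g (s − μ))) and E = N·P.  Scanning applies the
sequence-level and domain-level thresholds of 1e-3 strictly.  Domain
envelopes are defined operationally as the span of the best Viterbi
alignment; after removing an envelope the flanks are re-scanned, so
tandem domains yield multiple non-overlapping envelopes.  This is a
simple, testable stand-in for posterior-decoded envelopes.

# Profile–profile comparison and the probability score

Model–model similarity scores column pairs by the co-emission log-odds
log Σ_x p_a(x) p_b(x) / q(x) and aligns match-state columns locally with
affine gaps (3 / 0.3 on the column-score scale).  Significance comes from
a column-shuffle null: the columns of the second model are permuted (100
shuffles), a Gumbel is moment-fitted to the null scores, and the real
score's tail probability P yields E = n_lib · P and an operational
**probability score** = 100·(1 − P).  This is deliberately *not* the
posterior probability of the original HMM–HMM search tools — that scoring
is far more elaborate — but it is monotone in the same evidence, lives on
the same 0–100 scale, and the conventional thresholds (> 90 for remote
links, > 20 for the heat map) are applied to this artifact-defined score.
This substitution is the package's most consequential stand-in and is
flagged wherever the score is consumed.

**Cluster merging.** Models reciprocally linked with probability > 90 and
aligned-column coverage ≥ 0.9 on both models are merged by
profile–profile alignment of their MSAs, iterated to a fixed point.  The
coverage default is deliberately high: near-full-length agreement is the
signature of one family split into subfamilies, which is what merging is
for; at the 0.6 sometimes suggested for such steps, distinct families of
one superfamily (which align partially with high probability) would
collapse into a single model.

# Clans, dendrograms, heat maps

The family graph has three independent reciprocal tiers: thick
(E < 1e-3 both directions), thin (E < 1e-1), dotted (probability > 90).
Clan assignment iterates a three-rule cascade to a fixed point with
synchronous updates (each iteration reads the previous iteration's state,
so the result is independent of node order): (1) thick edge to a clan
member — a model with thick edges into two clans is flagged ambiguous
rather than forced; (2) unique closest superfamily by highest probability
among clan-labelled hits, where only hits with probability above 70 count
as potentially homologous (without this floor the rule fires on
noise-level hits before a model's true relatives are labelled); (3)
mutual best hit with an assigned model.
The rule precedence is this package's reading of the original narrative
order, and every assignment records which rule produced it.

Dendrograms use UPGMA on distance 100 − probability (asymmetric matrices
are symmetrised by the arithmetic mean and the fact recorded); the
agglomeration is delegated to `hclust(method = "average")` and checked
against a naive O(n³) oracle; trees are ultrametric by construction and
exported as Newick.  Heat maps floor probabilities below 20 at 0 and
cluster rows by Ward linkage on Euclidean distances
(`hclust(method = "ward.D2")`).

The subdomain experiment slices a double-domain model's alignment at a
supplied match-state column (secondary-structure-guided slicing is out of
scope), rebuilds half-profiles, and compares them with the single-domain
models; on synthetic fusions each half's best match is its source family,
structurally mirroring the relationship reported between double sensor
domains and their single-domain relatives.

# Census

Coverage of a region by a model is domain length / region length, clamped
to (0, 1], binned at 10 percentage points with the top bin closed; the
binned table conserves 100% of records.  Abundance counts one best-scoring
model per region (ties by lower E-value, then id; a count-all switch
exists).  Length summaries flag hits outside configurable reference bands
centred at 140 (single) and 271 (double) residues; no canonical band
edges exist, so the half-widths (50 / 90) are artifact
choices.  Phyletic presence is species-level with the any-strain rule, and
species at or below the protein-count floor are excluded ("more than
1000 proteins" in the original; the synthetic default scales this floor to
10 because synthetic species carry tens of proteins, keeping the rule's
logic — excluding under-sampled genomes — at the synthetic problem size).

# Problem sizes and determinism

The default study conditions are 6 planted families (4 single, 2 double)
× 40 members at divergence 0.25 in a ~400-protein, 8-species proteome;
the full pipeline on one CPU completes in a few minutes.  All randomness
descends from one integer seed through fixed per-stage substreams, so
integer-valued outputs are bit-reproducible for a given platform and
seed.  Stage outputs are checkpointed with MD5 manifests: re-running an
up-to-date directory is a no-op, and corrupting one intermediate re-runs
only that stage.

# Known limitations

* The topology stand-in has no signal-peptide model and a fixed N-in
  default; real predictor output should be imported for real data.
* The probability score is calibration-based, not a true alignment
  posterior; absolute values are not comparable with HHsearch
  probabilities even though the same thresholds are applied.
* Gumbel tail extrapolation far beyond the calibration sample (needed for
  E ≪ 1e-3) is approximate; the held-out benchmark measures the realised
  false-hit rate directly rather than trusting the tail.
* The generator's i.i.d. sites overstate alignability relative to real
  divergent families; clustering and detection rates on synthetic data
  are therefore upper bounds on real-data behaviour.
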