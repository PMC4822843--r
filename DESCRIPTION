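Package: cachescan
Title: Discovery and Census of Extracellular Sensory Domain Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for discovering and classifying families of
    extracellular sensory domains (the Cache superfamily and its relatives)
    in signal-transduction proteins. Candidate periplasmic regions flanked by
    two transmembrane helices are extracted from membrane topology, clustered
    through a reciprocal similarity network, reduced to representative
    sequences by greedy maximum coverage, turned into calibrated profile
    hidden Markov models, compared profile-against-profile to assign families
    to superfamilies (clans), and summarised in census statistics (length
    distributions, model coverage of regions, abundance ranking, phyletic
    presence/absence).  A synthetic proteome generator with planted domain
    families and a machine-readable ground truth makes every stage testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mclust,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
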