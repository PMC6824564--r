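Package: plastoflip
Title: Comparative Plastome Analysis of Small Inversions, Repeats and
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genomes: detection
    of the quadripartite structure (LSC, IRb, SSC, IRa) via exact
    inverted-repeat search, discovery of stem-loop (hairpin) structures
    and nearest-neighbour free-energy scoring, cross-species calling of
    small inversions (flip-flop hairpin loop orientation changes),
    perfect microsatellite (SSR) scanning with motif-class thresholds,
    sliding-window nucleotide diversity, and Fitch parsimony mapping of
    binary characters on a rooted phylogeny with ACCTRAN-style change
    placement.  Includes a synthetic plastome simulator with planted,
    fully known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
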