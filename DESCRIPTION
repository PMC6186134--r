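Package: nepan
Title: Effective Population Size, Pan-Genome Size and Gene Turnover in
    Prokaryote Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates effective population size (Ne) across prokaryotic
    species from multi-strain genome collections and relates it to
    pan-genome size, recombination and per-branch gene turnover.  Implements
    NG86 counting of synonymous and nonsynonymous divergence with a
    divergence-window species average, Watterson's theta on four-fold
    degenerate sites, a nearly-neutral inversion of dN/dS into absolute Ne,
    harmonic-normalized pan-genome statistics from best-reciprocal-hit
    protein families, a parsimony homoplasy ratio (h/m) as a recombination
    proxy, a two-state gain/loss model with per-branch event calls and
    turnover T = G/L, and phylogenetically corrected comparative statistics.
    A coalescent-based synthetic-data generator with known ground truth
    makes every stage testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
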