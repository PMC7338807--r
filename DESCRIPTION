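Package: nodprofiler
Title: Profiling Oxygenic Denitrifiers from Long-Read nod Gene Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Community profiling of putative oxygenic denitrifiers from
    long-read (ca. 1 kb) nitric oxide dismutase (nod) gene amplicons.
    Implements abundance-sorted greedy centroid OTU clustering at 90%
    nucleotide identity, frame recovery and translation of OTU
    representatives, signature-residue classification against a reference
    quinol-dependent NO reductase (qNor) numbering, bootstrapped
    neighbor-joining phylogeny with clade-based cluster assignment, a joint
    phylogeny-plus-signature decision rule, qPCR copy-number normalisation
    and community ordination. Ships a seeded synthetic-community generator
    (reads, reference panels, signature tables, qPCR tables with planted
    ground truth) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
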