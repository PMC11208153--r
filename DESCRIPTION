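Package: ancestryscan
Title: Windowed Competitive Alignment Scanning for Interspecific
    Introgressions and Chromosome Features
Version: 0.1.0
Authors@R:
    person("Ancestryscan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects donor-species introgression blocks in recipient-species
    genome assemblies by competitive mapping of overlapping fixed-length
    sequence windows against a concatenated two-species reference, with
    low-divergence masking, seed-block calling, sliding-interval smoothing
    and synteny-anchor coordinate projection. Also provides diagnostic
    k-mer centromere identification, telomere motif detection, hierarchical
    base-composition profiling, permutation tests for genomic interval
    overlap, presence-absence pattern counting over orthogroups, and a
    synthetic trio-genome simulator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
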