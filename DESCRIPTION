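Package: intregnet
Title: Integrated TF-miRNA Regulatory Network Construction and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds integrated transcription-factor and microRNA regulatory
    networks from ChIP-seq peak calls, genome annotation, expression profiles,
    miRNA seed-site tables and protein-protein interactions. Calls TF targets
    through strand-aware promoter windows with detection and exclusion of
    highly occupied target (HOT) regions, classifies each TF as an activator
    or repressor from binned binding-signal versus expression correlations,
    assembles the typed and signed regulatory network, layers the TF core
    hierarchy and the surrounding miRNA layers, performs an exact census of
    2- and 3-node typed and signed network motifs against edge-type- and
    sign-stratified degree-preserving rewiring nulls, and analyses intronic
    miRNA host-gene regulation including strand-bias tests. A seeded
    synthetic-data generator emulates the statistical structure of all the
    inputs so that every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
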