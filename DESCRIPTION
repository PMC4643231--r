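Package: paleoamp
Title: Taxonomic Bias from DNA Degradation in 16S rRNA Amplicon Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study why 16S rRNA hypervariable-region amplicon
    sequencing systematically distorts taxonomic profiles of degraded
    (ancient) microbiome samples. Implements in-silico PCR primer
    evaluation with a weighted mismatch/gap penalty scheme, primer
    inclusive amplicon extraction and the derived quality metrics
    (length variation, taxonomic coverage, taxonomic resolution); a
    random-degradation survival model exp(-lambda*x) that predicts how
    community profiles skew with thermal age; amplicon-versus-shotgun
    community comparison metrics; and a synthetic 16S database and aDNA
    fragmentation simulator that exercises the whole pipeline without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
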