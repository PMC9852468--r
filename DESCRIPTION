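Package: penquant
Title: Design and Quantification of Nuclease Prime Editing Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for nuclease prime editing (PEn/uPEn) amplicon experiments:
    design of homologous-region pegRNAs (HR-pegRNAs) encoding insertions,
    deletions, replacements and substitutions; demultiplexing and consensus
    merging of paired-end amplicon reads; per-read classification of editing
    outcomes (accurate, imprecise RT-driven, direct indel, unedited) within
    quantification windows, with summary metrics including editing purity;
    allele tabulation with repair-signature annotation (partial-HR blunt
    joins, microhomology-mediated junction alleles); a seeded simulator of
    editing-outcome read sets for validation; and replicate/site aggregation
    statistics (means, medians, fold changes, t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
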