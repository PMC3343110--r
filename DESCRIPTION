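Package: retroarray
Title: Repeat-Annotation and Repeat Expression Analysis for Gene Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Re-annotates gene expression microarray probes against a genome
    and its RepeatMasker repeat annotation to identify probes reporting on
    transposable-element transcripts, and quantifies genome-wide repeat
    expression changes at probe level. Provides an exact ungapped probe
    aligner with mismatch tolerance, sense-orientation repeat classification,
    probe-level preprocessing (background correction, log2 transform,
    quantile normalisation, present/absent filtering), empirical-Bayes
    moderated two-group differential expression with Benjamini-Hochberg
    correction, population-level rank-sum comparisons of repeat probe groups,
    assembly of RepeatMasker genomic hits into per-locus contigs with
    LTR-flank detection, consensus coverage, recurrent-deletion clustering
    and probe-to-locus matching, and a fully deterministic synthetic-data
    generator (genome with planted repeat copies, probe sets, two-condition
    expression matrices) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
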