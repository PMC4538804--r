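Package: slbs
Title: Single-Cell Locus-Specific Bisulfite Sequencing: Simulation,
    Methylation Calling and Epimutation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying epimutations -- stochastic, cell-specific
    changes in CpG methylation -- with targeted bisulfite amplicon
    sequencing of single cells. Simulates diploid single-cell bisulfite
    reads under a realistic chemistry and amplification error model
    (incomplete conversion, over-conversion of 5-methylcytosine, allelic
    dropout of whole-genome amplification, amplicon dropout), renders
    Sanger-style consensus sequences with IUPAC ambiguity codes, calls
    per-CpG methylation states against conversion-specific amplicon
    references, computes non-CpG cytosine conversion quality control, and
    estimates demethylating and methylating epimutation rates relative to
    a bulk tissue baseline, testing methylating events against the
    non-conversion background with an exact two-sided test. Includes a
    deterministic single-hepatocyte benchmark fixture and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
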