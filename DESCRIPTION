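Package: cgiturnover
Title: CpG Island Methylation and Substitution-Rate Turnover Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how CpG islands (CGIs) that are methylated in the
    germ line retain their CpG-rich sequence. Classifies CGIs into four
    positional categories against a transcript catalogue (5', 3', intragenic,
    intergenic) with a coding/non-coding flag; computes per-CGI DNA methylation
    and hydroxymethylation levels from per-site bisulfite call counts under
    three estimator variants with coverage-based exclusion filters; estimates
    six context-dependent substitution rates (CpG to TpG/CpA, TpG/CpA to CpG,
    CpG to other, other to CpG, A/T to G/C, G/C to A/T) per CGI from three-way
    human/chimpanzee/ancestor alignments; learns a CpG-to-TpG/CpA rate
    threshold separating sperm-methylated from sperm-hypomethylated CGIs with
    a single Gini decision stump; and assembles grouped mean and standard-error
    summaries. A seeded synthetic-data generator emulates the statistical
    structure of all inputs (CpG-rich islands, binomial bisulfite calls,
    two lineages diverged from an ancestor under context-dependent
    substitution probabilities) and records exact ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
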