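Package: lofkit
Title: Loss-of-Function Constraint Toolkit (LOEUF, MAPS and pLoF Annotation)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying gene-level intolerance to loss-of-function
    (LoF) variation from cohort allele-count data. Implements rule-based
    high-confidence predicted LoF (pLoF) annotation with nonsense-mediated
    decay and splice-rescue filters, a trinucleotide-context mutational
    expectation model incorporating CpG methylation and base-level coverage
    correction, observed/expected constraint with a Poisson-likelihood
    confidence interval whose 90% upper bound is the LOEUF score, the
    mutability-adjusted proportion of singletons (MAPS), aggregate pLoF
    carrier-frequency summaries, and allele-frequency-aware variant discovery
    curves. A synthetic-cohort generator produces internally consistent
    reference, transcript, methylation, coverage, mutation-rate and VCF
    inputs under an explicit mutation-selection model with known per-gene
    depletion, so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
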