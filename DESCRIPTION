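Package: cgiscreen
Title: Screening CpG-Island Hypermethylation-Silenced Tumor-Suppressor Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A paired tumor/normal pipeline for prioritizing candidate tumor
    suppressor genes silenced by CpG-island (CGI) promoter hypermethylation.
    Implements region-level differential methylation screening of Illumina
    450K-style beta-values (per-sample probe medians, per-pair beta-differences,
    paired t-tests with Benjamini-Hochberg correction, effect-size and FDR
    threshold filtering, ranking), a four-criterion expression evidence funnel
    (normal-lung expression, tumor downregulation, cell-line silencing,
    pharmacologic re-expression after 5-aza-2'-deoxycytidine), downstream
    validation analyses (site-level paired percent-methylation comparisons,
    methylation-expression inverse correlation, smoking-status stratification),
    and a seeded synthetic-cohort generator with ground-truth labels so every
    stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
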