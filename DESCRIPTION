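Package: introscan
Title: Detection of Wild-Species Introgressions from Whole-Genome SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for detecting chromosomal introgressions from wild
    relatives in resequenced inbred crop genomes. SNP calls against a single
    reference genome are binned into fixed-width windows; candidate
    introgressions are called as SNP-density peaks under configurable density,
    size and gap rules, with the per-window SNP threshold calibrated by a
    two-sample t-test between genome-wide and non-peak window counts. Peaks
    are assigned an origin (wild donor, reference-genome introgression, or
    unknown) from SNPs shared with a panel of wild and heirloom genomes, and
    introgression breakpoints are refined with depth- and allele-
    fraction-filtered donor-unique SNPs. Includes a sparse array-marker scan,
    a synthetic multi-accession panel simulator with planted introgressions
    and truth sets, and a reproducible command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
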