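Package: vintsim
Title: Simulation of Viral and Vector Integration Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates ground-truth benchmark data for viral and vector
    integration detection. Simulates integration of a viral genome into a
    host reference, reproducing complex features of real integrations:
    sub-genomic fragments, rearrangement and deletion of the integrated
    sequence, gap/overlap/clean host-virus junctions, deletions from the
    host at the integration site, and episomal (non-integrated) viral
    sequences. From the modified reference it simulates paired-end short
    reads with a position-dependent substitution error model, identifies
    reads crossing each integration junction, and writes ground-truth
    tables (TSV), junction locations (BED3) and reads (FASTQ) suitable
    for benchmarking integration-detection tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
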