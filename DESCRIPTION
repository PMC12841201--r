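Package: cholscreen
Title: Candidate-Gene Screening Funnel for Maternal Liver Choline Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a sequential candidate-gene prioritization funnel for
    maternal liver choline-metabolism genes in a BXD recombinant-inbred mouse
    panel: a percent-reduction-in-ethanol-induced-cell-death statistic
    aggregated from litter-level observations, a haplotype-variability filter,
    liver-proteome background and coefficient-of-variation filters, a Pearson
    correlation screen with a 3-of-4 selection rule, and an ordered-rule
    categorizer for GWAS SNP-phenotype association rows.  Ships the published
    strain tables as plain-text fixtures and a seeded synthetic-data generator
    with a planted protein-phenotype link so every stage can be exercised and
    validated end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
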