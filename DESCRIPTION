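Package: scaffscore
Title: Reference-Based Quality Scoring of De Novo Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes per-scaffold and whole-assembly quality scores for a
    de novo genome assembly evaluated against a trusted reference genome.
    Scaffold alignments (PAF) are reduced to a longest consistent chain,
    breakpoints between adjacent alignments are classified into relocation,
    translocation and inversion events, and an expected-artifact linear model
    calibrated by self-aligning reference fragments discounts aligner noise.
    Each scaffold receives a score combining its aligned fraction, a
    logarithmic misassembly penalty and a length scaling factor; the assembly
    score is the geometric mean of the area under the cumulative
    quality-distribution curve, the area under the cumulative genome-coverage
    curve and the inverted redundancy ratio. A seeded synthetic-assembly
    generator produces toy references and assemblies with known ground truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
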