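Package: translocatr
Title: Detection and Genetic Analysis of Reciprocal Chromosomal
    Translocations from Assembly Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates chromosome-scale genomes carrying reciprocal or
    chained inter-chromosomal translocations with known NHEJ-style junction
    edits (deletions, insertions, micro-homology), detects translocation
    breakpoints by comparing a wild-type and a mutant assembly with a
    unique k-mer anchor aligner, refines breakpoints to base resolution and
    characterizes junction sequences, designs codominant breakpoint-spanning
    PCR markers and genotypes populations in silico, and models meiosis in
    translocation heterozygotes (multivalent configurations, alternate
    versus adjacent segregation, pollen semi-sterility, and F2 segregation
    ratios with chi-square goodness-of-fit tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
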