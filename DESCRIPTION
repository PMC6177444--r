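Package: lamacnv
Title: Base-Pair Resolution of Intragenic Copy-Number Variants from
    Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composite pipeline for resolving intragenic copy-number
    variants (CNVs) to base-pair precision from targeted paired-end
    sequencing of a single gene region: read-depth ratio CNV detection
    against a control sample, soft-clipped-read clustering and consensus
    contig assembly, contig remapping to locate partner breakpoints,
    sequence-level junction characterization (microhomology, insertion,
    blunt ends, near-breakpoint errors, repeat overlap), and rule-based
    classification of the underlying mutational mechanism (NHEJ, MMBIR,
    FoSTeS, repeat-mediated rearrangement). Includes a deterministic
    synthetic-data generator (reference, engineered deletions and
    duplications with specified junction signatures, 150-bp paired-end
    reads, analytic alignments) and cohort-level CNV-spectrum statistics
    with curated fixtures from a published LAMA2 muscular dystrophy
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
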