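Package: nhejseq
Title: Repair-Junction Analysis of End-Joining Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing deep-sequenced repair junctions at a
    site-specific chromosomal double-strand break repaired by
    non-homologous end joining (NHEJ). Enumerates all candidate
    end-joining products (religation, microhomology-mediated, deletion
    and short-insertion joints) supported by a staggered cut, encodes
    them in a D/M/L/R/I joint nomenclature, demultiplexes and classifies
    indexed amplicon reads against the enumerated joint space, summarises
    per-sample joint fractions and colony-assay outcomes, and tests for
    differential joint frequency between strains with a conditional
    negative-binomial exact test. A seeded synthetic-read generator with
    ground-truth tables makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
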