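Package: FvBuilder
Title: Antibody Fv Homology Modelling with Data-Driven Confidence Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A template-based modelling pipeline for antibody variable
    fragments (paired Fv, heavy-only VHH nanobodies, and light-only domains).
    Builds models by framework template selection with an 80% sequence-identity
    global/hybrid rule, VH-VL orientation transplant, fragment-database CDR
    loop grafting ranked by anchor RMSD with a staged fallback cascade,
    and partial side-chain completion with van der Waals clash control.
    Model quality is annotated as a data-driven conditional probability that
    each region (framework or CDR loop) is modelled within a given backbone
    RMSD, conditioned on template sequence identity or loop length, and
    developability sequence liabilities are flagged and gated on solvent
    exposure. Includes a synthetic fixture generator so the whole pipeline is
    testable without any external structure database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
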