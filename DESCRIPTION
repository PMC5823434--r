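Package: specon
Title: Specific Conservation Analysis of Protein Domain Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how each member of a protein domain family differs
    from its siblings by contrasting two multiple sequence alignments: a
    paralog alignment of every family member within a reference species and
    one ortholog alignment per member across related species. Positional
    conservation is scored as the exponential Shannon entropy of amino-acid
    equivalency-group frequencies, and the paralog/ortholog entropy ratio
    (the specific conservation, SC, value) flags positions that are unique
    to one member yet conserved across its orthologs. The package maps
    alignment columns onto a canonical domain numbering, averages SC over
    user-defined binding surfaces, counts conserved loop insertions, builds
    equivalency-group position-specific scoring matrices and clusters family
    members by binding-surface profiles, and scores peptide-array binding
    specificity through per-species binding fractions. A synthetic-family
    generator with planted position classes and planted specific peptides
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
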