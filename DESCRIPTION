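Package: hfactor
Title: H-Factor Quality Assessment for Homology Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the H-factor, a composite 0-100 percent quality
    indicator for ensembles of homology models, modelled after the
    crystallographic R-factor. Four sub-scores on a common 0-10 scale are
    combined: agreement between the target's predicted secondary structure
    and the template's assigned secondary structure, target-template
    sequence identity over the alignment, structural heterogeneity of the
    model ensemble around its average structure, and structural integrity
    of Pfam functional domains against reference structures. Includes
    readers for PDB C-alpha traces, aligned FASTA and Clustal alignments,
    PSIPRED ss2/horiz predictions, STRIDE assignments and HMMER domtblout
    tables, Kabsch superposition and cRMS over C-alpha atoms, an iterative
    average-model builder, a deterministic synthetic fixture generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
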