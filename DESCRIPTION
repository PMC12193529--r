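Package: mitocomp
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative mitogenome analysis for insects: parsing of
    annotated circular mitochondrial genomes from GenBank flat files,
    strand-asymmetry statistics (AT and GC skew) at the whole-genome,
    protein-coding-gene, rRNA and tRNA levels, codon-usage bias via
    relative synonymous codon usage (RSCU) and the codon adaptation
    index (CAI) with sliding windows against a reference usage table,
    selection inference from pairwise Ka/Ks by the Nei-Gojobori (1986)
    counting method and from the GC12-on-GC3 neutrality plot, gene-order
    comparison against the ancestral insect arrangement, and a fully
    seeded synthetic annotated-mitogenome generator so that every stage
    of the pipeline is testable without downloading records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'mitocomp-package.R'
    'genetic-code.R'
    'gene-names.R'
    'Mitogenome-class.R'
    'genbank.R'
    'gene-extract.R'
    'gene-order.R'
    'composition.R'
    'codon-usage.R'
    'selection.R'
    'simulate.R'
    'pipeline.R'
    'plots.R'
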