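Package: codonbias
Title: Organism-Scale Codon Usage Bias Profiling for Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-gene codon usage bias measures (Codon Adaptation
    Index and Wright's effective number of codons) and organism-scale
    summaries (mean CAI over all genes, coefficient of variation of CAI,
    the relative difference between the mean Nc of ribosomal and
    non-ribosomal genes, and the ribosomal-versus-rest codon frequency
    difference) from coding-sequence sets. Includes readers for CDS FASTA,
    GenBank flat files, phenotype annotation tables and newick trees;
    nonparametric phenotype-group comparisons, partial correlations, and
    patristic-distance analyses of bias divergence; and a mutation-selection
    codon-choice simulator that generates prokaryote-like genomes with known
    translational-selection strength, GC pressure and per-gene expression
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
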