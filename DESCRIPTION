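Package: mitoprofile
Title: Descriptive Profiling of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("EMHAU", "Bioinformatics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the descriptive stage of an insect mitogenome study:
    circular-genome gene-organization arithmetic (overlaps, intergenic
    spacers, strand partition, length audits), nucleotide composition with
    AT/GC skew broken down by feature class and codon position, codon usage
    and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, and pairwise ka/ks in the Nei-Gojobori (1986)
    counting framework with Jukes-Cantor correction. Includes readers and
    writers for gene-coordinate tables, a GenBank flat-file subset and FASTA,
    a seeded synthetic-mitogenome and codon-evolution generator for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
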