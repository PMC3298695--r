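Package: synmotif
Title: Exact Motif Count Statistics over Synonymous Codon Re-Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact, non-parametric assessment of nucleotide motif over- and
    under-representation in protein-coding sequences. For a motif (a k-mer or a
    set of equal-length k-mers) and a set of in-frame coding sequences, the
    package computes the full probability distribution of the motif copy number
    over every synonymous re-encoding of the amino-acid sequences, weighted by
    a codon-usage null estimated from a reference set of coding sequences.
    Two nulls are available: an independent codon model (ICM) and a
    dinucleotide-corrected codon Markov model (DCM) that conditions each codon
    on the first base of its 3' neighbour, preserving reference dinucleotide
    usage across codon boundaries (the CpG effect in particular). A dynamic
    program over codons with sparse-region decomposition makes the computation
    exact and fast; distributions are combined by polynomial convolution.
    Includes exact p-values, z-scores and count ratios, a brute-force
    enumeration oracle, null-model sequence samplers, a synthetic
    motif-insertion benchmark generator, FASTA/motif-file I/O and a
    command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
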