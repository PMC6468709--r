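Package: ciscover
Title: Discovery of Conserved Intronic Sequences in Orthologous Vertebrate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved intronic sequences (CISs) in orthologous genes
    with superimposable exon-intron arrangements. Provides gene-model input and
    output (GFF3/FASTA/BED), a seeded local nucleotide aligner with DUST-style
    low-complexity masking and Karlin-Altschul E-values, intron correspondence
    and order-consistent HSP chaining, multi-species intersection of conserved
    intervals with conservation accounting, exonization and codon-level
    analyses (reading frames, stop-codon skipping, frameshift indels), the
    associated proportion statistics, and a sequence-evolution simulator that
    generates orthologous gene families with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
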