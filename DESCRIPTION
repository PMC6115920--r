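Package: nlrscan
Title: Identification, Classification and Evolutionary Analysis of
    NBS-LRR Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for genome-wide surveys of plant NBS-LRR (NLR) disease
    resistance genes. Builds ordered domain architectures from Pfam-style
    domain evidence and classifies proteins into the CNL/TNL/RNL/NL groups
    and their letter-code subgroups; counts LxxLxxLxx leucine-rich-repeat
    signatures; discovers conserved NLR motifs (P-loop, Kinase-2, GLPL,
    MHDL, RNBS) by ZOOPS expectation-maximization and extracts Kinase-2 and
    RNBS-B signature residues; scores coiled-coil propensity by a heptad
    register scan and decodes nuclear localization signals with a two-state
    hidden Markov model (Viterbi and posterior); calls physical gene
    clusters from GFF3 annotation; estimates pairwise Ka and Ks by the
    Nei-Gojobori method with Jukes-Cantor correction; normalizes tissue
    expression matrices by median-of-ratios size factors and clusters them
    with seeded K-means; and generates synthetic proteomes, genomes, codon
    alignments and expression matrices with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
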