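Package: ampliconr
Title: Amplicon Sequence Processing: Alignment Search, Clustering,
    Dereplication, Chimera Detection and Paired-End Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for nucleotide amplicon processing built around
    heuristic global-alignment search: k-mer word-count candidate
    filtering followed by optimal global alignment with affine gap
    penalties (with a linear-memory divide-and-conquer variant for long
    pairs), greedy centroid clustering (distance- or abundance-based),
    full-length and prefix dereplication with abundance accumulation,
    UCHIME-style de novo and reference-based chimera detection, DUST
    low-complexity masking, quality-aware merging of paired-end reads
    with posterior quality scores, FASTQ inspection, filtering and
    quality-encoding conversion, and abundance-aware sorting, shuffling
    and hypergeometric subsampling. Reads and writes FASTA and FASTQ
    (optionally gzip-compressed) with 'size=' abundance annotations, and
    provides a USEARCH-compatible command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    digest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
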