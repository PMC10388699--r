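Package: fastkit
Title: Partitioned Parallel Toolkit for FASTA/FASTQ Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A FASTA/FASTQ manipulation toolkit built on a small deterministic
    partitioned-dataset engine. Files are split into byte ranges that are
    resynchronized to record boundaries, so every command can run over many
    partitions and workers while producing byte-identical output to a
    sequential run. Provides the classic sequence-toolkit command set (seq,
    subseq, stats, faidx, grep, locate, sample, rmdup, sort, shuffle, pair,
    concat, common, rename, head, range, head-genome, duplicate, replace,
    translate, fq2fa, fa2fq), samtools-dialect FAI indexing for both FASTA and
    FASTQ, exactly uniform distributed sampling without replacement via
    sequential hypergeometric splitting, a parallel sample merge-sort,
    collision-checked deduplication, and three storage tiers (in-memory,
    compressed, on-disk). Includes a command-line interface and a
    deterministic synthetic data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    Biostrings,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
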