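Package: seqveil
Title: Privacy-Preserving Sequence Similarity Search with Encrypted k-mer Sketches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-party protocol for searching a privately held collection of DNA
    sequences with a secret query. The query is sketched as a fixed-length
    locality-sensitive hash (LSH) of its k-mers, encrypted element-wise under the
    Paillier additive homomorphic cryptosystem, and scanned against every database
    entry; the database owner returns, per entry, an encrypted set-intersection
    count and the entry's plaintext sketch magnitude, from which the querier
    decrypts intersection-over-union (IoU), intersection-over-query (IoQ) and
    intersection-over-database-entry (IoD) similarity scores. Neither party sees
    the other's sequences. Includes in-silico mutation models, alignment-based
    average nucleotide identity (ANI) ground truth, ROC/AUC evaluation, and
    synthetic-genome generators so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: OpenSSL (libcrypto)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    withr,
    Biostrings,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
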