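Package: qsarc
Title: Lossless Quality-Score Compression with Line-Range Random Access
Version: 0.1.0
Authors@R:
    person("Jordan", "Fall", email = "jfall@example.org", role = c("aut", "cre"))
Description: Compresses FASTQ quality-score lines losslessly into a single
    self-indexed container file.  Lines are split into two streams by a
    k-mer-frequency line weight, buffered into independently compressed
    blocks carrying a light-weight embedded index, transformed by an
    adaptive bijective packing of value groups anchored on the modal
    quality value, and entropy-coded by a context-mixing binary arithmetic
    coder.  Any contiguous line range can be restored by decoding at most a
    handful of blocks, with no sidecar index file.  Includes a synthetic
    quality-line generator for testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++11
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
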