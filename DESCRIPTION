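Package: offtargetr
Title: Exhaustive Enumeration of CRISPR/Cas Guide RNA Off-Target Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive, index-accelerated enumeration of potential CRISPR/Cas
    off-target sites for 20-nt guide RNAs. A genome is preprocessed once into a
    prefix-hash index (16-mer prefix table pointing into a flat array of
    bit-packed PAM-adjacent site records); queries then enumerate the Hamming
    neighborhood of the guide prefix under a user-defined seed constraint and
    report every genomic site within a chosen mismatch budget that is
    immediately followed by the protospacer adjacent motif (PAM). Includes a
    brute-force reference scanner used as ground truth in tests, a synthetic
    genome / planted-site fixture generator, optional GTF/BED annotation of
    hits, and a command-line interface for index building and querying.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
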