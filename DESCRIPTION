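Package: trfcall
Title: Identification, Classification and Quantification of tRNA-Derived Fragments
Version: 0.1.0
Authors@R: person("trfcall", "maintainers", email = "trfcall@example.org", role = c("aut", "cre"))
Description: Calls tRNA-derived small RNA fragments (tRF-5, tRF-3, tRF-1) from
    pre-trimmed small RNA sequencing libraries. Builds a species reference of
    mature tRNA sequences (with the post-transcriptional CCA appended) plus
    50-nt 3' trailers, maps collapsed reads by exact full-length matching,
    removes reads that also occur in the genome outside tRNA loci, filters
    random degradation products with a dominant-read enrichment rule, assigns
    field-standard identifiers (5001/3001/1001 series with a/b/c length
    subclasses), quantifies fragments in reads per million, and compares
    fragment abundance between library groups. Includes a synthetic small RNA
    library generator with planted ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
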