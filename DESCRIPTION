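Package: kircn
Title: Copy-Number Calling and Haplotype Inference for Multi-Copy Immune
    Gene Families from Multiplex qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integer copy-number calling for multi-copy gene families
    (KIR, LILR) from multiplex real-time qPCR Cq data using comparative
    Cq (delta-delta-Cq) relative quantification with replicate quality
    control, outlier filtering, zero-copy detection, confidence and
    z-score metrics, and cluster-dispersion diagnostics. Resolves
    unphased per-locus copy numbers into candidate haplotype pairs by
    regular-expression matching against a gene-content haplotype library
    and matrix subtraction, ranked by combined frequency. A synthetic
    data module generates haplotype-structured genotypes and realistic
    384-well quadruplicate Cq plates (Gaussian Cq noise, DNA
    concentration offsets, zero-copy non-amplification, allele dropout)
    so the whole stack runs end-to-end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
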