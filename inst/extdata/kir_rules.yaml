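# Default KIR haplotype consistency rules. Framework genes are present on
# essentially all haplotypes and expected at two copies per diploid genome;
# the co-duplication group ties loci that expand or contract together on
# structural-variant haplotypes. All entries are user-overridable.
framework: [3DL3, 3DP1, 2DL4, 3DL2]
framework_copies: 2
locus_totals:
  3DL1/S1: [3DL1, 3DS1]
coduplication_groups:
  - [3DP1, 2DL4, 3DL1/S1]
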