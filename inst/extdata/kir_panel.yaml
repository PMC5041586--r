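# Bundled KIR copy-number panel: 20 target markers over the KIR loci, run as
# ten triplex reactions, each sharing the STAT6 reference assay (two copies in
# a diploid genome, on another chromosome). Channel names are labels only.
# The pairing of targets into reactions is a fixed convention of this package.
name: kir20
reference_copy_number: 2
replicates: 4
markers:
  - {id: STAT6,   gene: STAT6,    region: exon 1,  channel: Cy5, reference: true}
  - {id: 3DL3,    gene: KIR3DL3,  region: exon 4,  channel: FAM}
  - {id: 2DS2,    gene: KIR2DS2,  region: exon 4,  channel: Orange}
  - {id: 2DL2,    gene: KIR2DL2,  region: exon 5,  channel: FAM}
  - {id: 2DL3,    gene: KIR2DL3,  region: exon 5,  channel: Orange}
  - {id: 2DP1,    gene: KIR2DP1,  region: exon 4,  channel: FAM}
  - {id: 2DL1,    gene: KIR2DL1,  region: exon 5,  channel: Orange}
  - {id: 3DP1,    gene: KIR3DP1,  region: exon 2,  channel: FAM}
  - {id: 2DL4,    gene: KIR2DL4,  region: exon 7,  channel: Orange}
  - {id: 3DL1e4,  gene: KIR3DL1,  region: exon 4,  channel: FAM}
  - {id: 3DS1,    gene: KIR3DS1,  region: exon 4,  channel: Orange}
  - {id: 3DL1e9,  gene: KIR3DL1,  region: exon 9,  channel: FAM}
  - {id: 2DL5,    gene: KIR2DL5,  region: exon 4,  channel: Orange}
  - {id: 2DS3,    gene: KIR2DS3,  region: exon 5,  channel: FAM}
  - {id: 2DS5,    gene: KIR2DS5,  region: exon 5,  channel: Orange}
  - {id: 2DS1,    gene: KIR2DS1,  region: exon 5,  channel: FAM}
  - {id: 2DS4,    gene: KIR2DS4,  region: exon 5,  channel: Orange}
  - {id: 2DS4FL,  gene: KIR2DS4,  region: exon 5 full-length, channel: FAM}
  - {id: 2DS4del, gene: KIR2DS4,  region: exon 5 deletion variant, channel: Orange}
  - {id: 3DL2e4,  gene: KIR3DL2,  region: exon 4,  channel: FAM}
  - {id: 3DL2e9,  gene: KIR3DL2,  region: exon 9,  channel: Orange}
reactions:
  - {id: R01, targets: [3DL3,    2DS2],    reference: STAT6}
  - {id: R02, targets: [2DL2,    2DL3],    reference: STAT6}
  - {id: R03, targets: [2DP1,    2DL1],    reference: STAT6}
  - {id: R04, targets: [3DP1,    2DL4],    reference: STAT6}
  - {id: R05, targets: [3DL1e4,  3DS1],    reference: STAT6}
  - {id: R06, targets: [3DL1e9,  2DL5],    reference: STAT6}
  - {id: R07, targets: [2DS3,    2DS5],    reference: STAT6}
  - {id: R08, targets: [2DS1,    2DS4],    reference: STAT6}
  - {id: R09, targets: [2DS4FL,  2DS4del], reference: STAT6}
  - {id: R10, targets: [3DL2e4,  3DL2e9],  reference: STAT6}
paired_assays:
  - [3DL1e4, 3DL1e9]
  - [3DL2e4, 3DL2e9]
sum_rules:
  2DS4: [2DS4FL, 2DS4del]
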