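# Minimal duplex panel for the copy-number-variable LILR loci: one target
# plus the STAT6 reference assay per well.
name: lilr_duplex
reference_copy_number: 2
replicates: 4
markers:
  - {id: STAT6,  gene: STAT6,   region: exon 1, channel: Cy5, reference: true}
  - {id: LILRA3, gene: LILRA3,  region: exon 2, channel: FAM}
  - {id: LILRA6, gene: LILRA6,  region: exon 3, channel: FAM}
reactions:
  - {id: L01, targets: [LILRA3], reference: STAT6}
  - {id: L02, targets: [LILRA6], reference: STAT6}
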