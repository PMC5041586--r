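# Bundled KIR gene-content haplotype library (synthetic). Signatures follow
# common European-origin A/B haplotype gene-content patterns plus one
# extended haplotype (duplication of 3DP1, 2DL4 and the 3DL1/S1 locus) and
# one contracted haplotype (deletion from 3DL1 to 3DL2). Counts and
# frequencies are documented placeholders, not population estimates.
# markers: 3DL3,2DS2,2DL2,2DL3,2DP1,2DL1,3DP1,2DL4,3DL1,3DS1,2DL5,2DS3,2DS5,2DS1,2DS4FL,2DS4del,3DL2
haplotype_id,signature,count,frequency,cen_motif,tel_motif
A01,1-0-0-1-1-1-1-1-1-0-0-0-0-0-0-1-1,565,0.565,cA01,tA01
B01,1-1-1-0-1-1-1-1-0-1-1-1-0-1-0-0-1,100,0.100,cB01,tB01
B02,1-0-0-1-1-1-1-1-0-1-1-0-1-1-0-0-1,120,0.120,cA01,tB01
B03,1-1-1-0-1-1-1-1-1-0-1-0-1-0-1-0-1,130,0.130,cB01,tA01
B04,1-1-1-0-0-0-1-1-0-1-2-1-1-1-0-0-1,50,0.050,cB02,tB01
DUP01,1-0-0-1-1-1-2-2-1-1-1-0-1-1-1-0-1,15,0.015,cA01,tB01
DEL01,1-1-1-0-1-1-1-1-0-0-0-0-0-0-0-0-1,20,0.020,cB01,tDEL
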