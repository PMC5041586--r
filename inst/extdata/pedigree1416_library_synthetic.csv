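# Synthetic stand-in for the eight haplotypes (a, b, c, d, w, x, y, z) of a
# two-generation reference pedigree resolved by segregation analysis.
# Haplotype c carries the duplication of 3DP1, 2DL4 and the 3DL1/S1 locus.
# Gene contents and frequencies are illustrative placeholders only.
# markers: 3DL3,2DS2,2DL2,2DL3,2DP1,2DL1,3DP1,2DL4,3DL1,3DS1,2DL5,2DS3,2DS5,2DS1,2DS4FL,2DS4del,3DL2
haplotype_id,signature,count,frequency,cen_motif,tel_motif
a,1-0-0-1-1-1-1-1-1-0-0-0-0-0-0-1-1,1,0.125,cA01,tA01
b,1-1-1-0-1-1-1-1-0-1-1-1-0-1-0-0-1,1,0.125,cB01,tB01
c,1-1-1-0-1-1-2-2-1-1-1-1-0-1-1-0-1,1,0.125,cB01,tB01
d,1-0-0-1-1-1-1-1-1-0-0-0-0-0-1-0-1,1,0.125,cA01,tA01
w,1-0-0-1-1-1-1-1-0-1-1-0-1-1-0-0-1,1,0.125,cA01,tB01
x,1-1-1-0-1-1-1-1-1-0-1-0-1-0-1-0-1,1,0.125,cB01,tA01
y,1-0-0-1-1-1-1-1-1-0-0-0-0-0-0-1-1,1,0.125,cA01,tA01
z,1-1-1-0-0-0-1-1-0-1-2-1-1-1-0-0-1,1,0.125,cB02,tB01
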