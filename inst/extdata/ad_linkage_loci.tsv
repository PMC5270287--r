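# AD linkage loci, coordinates in Mb (1-based inclusive)
chr3	122.2	129.5	3q21
chr5	131.2	160.5	5q31-33
chr1	143.2	155.1	1q21
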