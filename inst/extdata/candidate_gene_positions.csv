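gene,chrom,pos_mb
COL6A6,chr3,130.2
CDX1,chr5,149.5
ANKRD35,chr1,145.5
TUFT1,chr1,151.5
FLG,chr1,152.2
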