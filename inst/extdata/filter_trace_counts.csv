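stage,FamA,FamB,FamC
raw,7523,3564,3227
effect,2799,2489,2198
impact,502,516,443
deleteriousness,278,258,231
phylop,234,225,206
phastcons,200,173,156
af_global,33,60,53
af_korean,31,54,49
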