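snp,group,hom_ref,het,hom_alt,ref_allele,alt_allele
rs16830494,case,79,29,3,G,A
rs16830494,control,39,21,1,G,A
rs59021909,case,89,21,2,C,T
rs59021909,control,47,14,0,C,T
rs200963433,case,108,4,0,C,T
rs200963433,control,60,1,0,C,T
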