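sseqid	genome
wrat_ctg_07	R_wratislaviensis_NBRC100605
pd630_chr	R_opacus_PD630
jvh1_ctg_12	R_JVH1
rha1_chr	R_RHA1
split_ctg_01	R_splitcontig
split_ctg_02	R_splitcontig
ery_ctg_03	R_erythropolis_CCM2595
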