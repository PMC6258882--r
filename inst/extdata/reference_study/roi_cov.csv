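roi,mean_cov_percent
splenium_corpus_callosum,4.47
superior_longitudinal_fasciculus,10.86
minor_forceps,12.71
major_forceps,6.63
genu_corpus_callosum,17.89
global_white_matter,2.77
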