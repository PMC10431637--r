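method,mean_rank
NSCT,6.67
PCNN-NSCT,6.36
NSCT-SR,6.08
m-PCNN,5.92
SCM-F,5.44
SCM-M,4.64
Nabla-PCA,3.53
Nabla-weighted,3.28
Nabla-max,3.08
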