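table,chi2_reported,N,k
hybrid_exp5_8,81.75,36,8
known_exp1_12,261.48,108,10
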