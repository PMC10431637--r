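table,method,mean_rank,N,k
hybrid_exp1_4,NSCT,6.67,36,9
hybrid_exp1_4,PCNN-NSCT,6.36,36,9
hybrid_exp1_4,NSCT-SR,6.08,36,9
hybrid_exp1_4,m-PCNN,5.92,36,9
hybrid_exp1_4,SCM-F,5.44,36,9
hybrid_exp1_4,SCM-M,4.64,36,9
hybrid_exp1_4,Nabla-PCA,3.53,36,9
hybrid_exp1_4,Nabla-weighted,3.28,36,9
hybrid_exp1_4,Nabla-max,3.08,36,9
hybrid_exp5_8,CST,5.86,36,8
hybrid_exp5_8,NNSST,5.75,36,8
hybrid_exp5_8,MFDF-NSST,5.72,36,8
hybrid_exp5_8,ST-NSST,5.027,36,8
hybrid_exp5_8,FMSAP,4.97,36,8
hybrid_exp5_8,Nabla-PCA,3.22,36,8
hybrid_exp5_8,Nabla-max,3.08,36,8
hybrid_exp5_8,Nabla-weighted,2.36,36,8
known_exp1_12,DWT,7.75,108,10
known_exp1_12,FSD,7.08,108,10
known_exp1_12,RP,6.78,108,10
known_exp1_12,MDP,6.29,108,10
known_exp1_12,GP,6.24,108,10
known_exp1_12,LP,5.2,108,10
known_exp1_12,SIDWT,4.96,108,10
known_exp1_12,Nabla-PCA,3.9,108,10
known_exp1_12,Nabla-max,3.53,108,10
known_exp1_12,Nabla-weighted,3.26,108,10
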