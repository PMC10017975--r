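marker,class,n_individuals,Forli,Maribor,Murcia,Nimes,Toulenne
KASP_LG1_50.880,A:A,41,94.0,93.4,87.1,86.2,90.7
KASP_LG1_50.880,A:T,57,93.6,93.6,87.0,86.0,90.2
KASP_LG1_50.880,T:T,20,92.6,92.6,85.4,85.1,89.1
KASP_LG1_52.362,A:A,38,94.0,94.1,87.9,86.2,90.7
KASP_LG1_52.362,A:G,63,93.5,93.0,86.5,85.8,90.0
KASP_LG1_52.362,G:G,17,92.8,93.0,85.2,85.7,89.5
KASP_9.936,A:A,57,92.7,91.6,86.5,84.9,89.0
KASP_9.936,G:A,60,94.4,95.1,87.2,86.8,91.4
KASP_9.958,C:C,57,92.6,91.4,86.4,84.9,88.9
KASP_9.958,T:C,61,94.4,95.1,87.1,86.9,91.4
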