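sample_id,locus,allele1,allele2
S1,D8S1179,12,17
S1,D21S11,29,31
S1,D7S820,8,11
S1,CSF1PO,12,13
S1,D3S1358,15,17
S1,TH01,9,9
S1,D13S317,10,11
S1,D16S539,12,12
S1,D2S1338,20,20
S1,D19S433,13,15
S1,VWA,14,17
S1,TPOX,11,11
S1,D18S51,13,15
S1,D5S818,7,12
S1,FGA,21,21
S1,AMEL,X,Y
S2,D8S1179,13,15
S2,D21S11,29,30.2
S2,D7S820,8,11
S2,CSF1PO,9,11
S2,D3S1358,15,15
S2,TH01,9,9
S2,D13S317,10,12
S2,D16S539,11,12
S2,D2S1338,22,25
S2,D19S433,13,13
S2,VWA,17,18
S2,TPOX,8,11
S2,D18S51,15,19
S2,D5S818,11,12
S2,FGA,21,22
S2,AMEL,X,X
S3,D8S1179,12,15
S3,D21S11,30.2,31
S3,D7S820,8,11
S3,CSF1PO,9,11
S3,D3S1358,17,17
S3,TH01,9,9
S3,D13S317,10,11
S3,D16S539,9,12
S3,D2S1338,20,25
S3,D19S433,13,15
S3,VWA,14,17
S3,TPOX,8,11
S3,D18S51,13,15
S3,D5S818,11,12
S3,FGA,19,22
S3,AMEL,X,X
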