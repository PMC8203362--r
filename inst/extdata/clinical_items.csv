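subject,n_tic_areas_clinician,n_tic_areas_model,tic_frequency_clinician,tic_frequency_model
1,2,2,6,5
2,2,2,6,7
3,1,2,2,1
4,1,1,40,37
5,1,1,3,1
6,1,1,9,12
7,1,1,15,14
8,1,1,0,0
9,1,1,1,1
10,1,1,11,8
11,2,2,3,3
12,1,0,0,0
13,1,2,4,2
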