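patient_id,dose_index,dlt,moderate_tox,cohort_id
1,1,0,0,1
2,1,0,0,1
3,1,0,0,1
4,3,1,0,2
5,3,0,0,2
6,3,0,0,2
7,4,1,0,3
8,4,0,0,3
9,4,0,0,3
10,4,1,0,4
11,4,0,0,4
12,4,0,0,4
13,4,1,0,5
14,4,0,0,5
15,4,0,0,5
16,4,1,0,6
17,4,0,0,6
18,4,0,0,6
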