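patient_id,enrollment_order,dose_level,dlt,evaluable
1,1,1,0,1
2,2,1,0,1
3,3,1,0,1
4,4,2,0,1
5,5,2,0,1
6,6,2,0,1
7,7,3,0,1
8,8,3,0,1
9,9,3,0,1
10,10,3,0,1
11,11,3,0,1
12,12,3,0,1
13,13,3,0,0
14,14,3,1,1
15,15,3,0,1
16,16,3,0,1
17,17,3,0,1
18,18,3,0,1
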