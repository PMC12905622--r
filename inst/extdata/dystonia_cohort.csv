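patient_id,dystonia_type,syndrome,side,disease_duration_years,dbs_duration_months,aims_item7,twstrs_pre,twstrs_off,twstrs_bipolar_on,twstrs_monopolar_on
1,CD,"torti-, latero-, antecollis",right,24,186,0,25,17,13,4
2,CD,"torticollis, head tremor",left,24,154,0,14,8,9,11
3,SD,"torticollis, left upper extremity",left,18,181,1,24,14,4,7
4,CD,"torticollis, head tremor",right,10,92,1,14,12,8,10
5,CD,"torti-, latero-, antecollis",right,23,167,0,18,10,5,7
6,CD,"torticollis, laterocollis",right,4,140,1,19,17,18,15
7,SD,"torticollis, right shoulder girdle",right,21,91,3,15,18,13,12
8,SD,"torticollis, left upper extremity",left,16,154,2,9,8,9,9
9,CD,"torticollis, laterocollis",left,25,195,0,22,13,7,15
10,SD,"torticollis, left upper extremity",left,30,133,0,20,19,11,10
11,CD,"torticollis, antecollis",right,21,9,4,25,21,20,16
12,CD,"torticollis, oro-mandibular",left,9,41,1,20,25,3,4
13,CD,"torticollis, laterocollis",left,14,11,1,17,14,11,13
14,CD,"torticollis, head tremor",left,18,13,3,16,13,9,10
15,CD,"torticollis",left,6,16,2,7,12,11,6
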