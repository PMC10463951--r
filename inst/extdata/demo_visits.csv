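"animal_id","group","corner","start","end","np_count","np_correct_count","first_np_s","door_opened","lick_count","lick_duration_s"
"a1","control",4,175,200,2,0,1.5,TRUE,7,1.75
"a1","control",2,434,459,1,0,1.5,TRUE,5,1.25
"a1","control",2,1005,1030,1,0,1.5,TRUE,7,1.75
"a1","control",4,1498,1523,2,0,1.5,TRUE,8,2
"a1","control",1,1760,1785,0,0,NA,FALSE,5,1.25
"a1","control",4,2290,2315,2,0,1.5,TRUE,8,2
"a1","control",2,2601,2626,3,0,1.5,TRUE,4,1
"a1","control",4,2888,2913,3,0,1.5,TRUE,4,1
"a1","control",2,3308,3333,2,0,1.5,TRUE,5,1.25
"a1","control",1,3653,3678,5,0,1.5,TRUE,2,0.5
"a2","treated",3,165,195,5,0,1.5,TRUE,4,1
"a2","treated",2,552,582,2,0,1.5,TRUE,9,2.25
"a2","treated",3,858,888,4,0,1.5,TRUE,7,1.75
"a2","treated",2,1391,1421,4,0,1.5,TRUE,7,1.75
"a2","treated",3,1806,1836,3,0,1.5,TRUE,8,2
"a2","treated",3,2192,2222,5,0,1.5,TRUE,4,1
"a2","treated",4,2507,2537,3,0,1.5,TRUE,8,2
"a2","treated",4,2831,2861,6,0,1.5,TRUE,5,1.25
"a2","treated",1,3229,3259,0,0,NA,FALSE,9,2.25
"a2","treated",3,3655,3685,5,0,1.5,TRUE,10,2.5
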