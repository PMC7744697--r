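"subject_id","mj_1","mj_2","mj_3","mj_4","mj_5","ss_1","ss_2","ss_3","ss_4","comp_1","comp_2","comp_3","comp_4"
"s01",4,4,5,4,5,4,4,4,4,3,3,3,4
"s02",1,1,3,1,2,2,2,2,3,1,3,2,3
"s03",2,4,3,2,2,4,4,3,4,3,2,1,2
"s04",3,3,3,4,3,3,4,4,3,5,5,4,5
"s05",3,3,2,3,3,2,1,1,2,2,2,4,3
"s06",2,3,1,2,1,2,3,3,3,4,2,3,2
"s07",5,4,4,5,4,4,3,3,2,4,4,4,4
"s08",2,2,2,2,2,2,2,3,3,4,3,4,4
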