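"expert_id","1","1.1","1.1.1","1.1.2","1.2","1.2.1","1.3","1.3.1","2","2.1","2.1.1","2.1.2","2.2","2.2.1","2.2.2","2.2.3","2.3","2.3.1","2.3.2","3","3.1","3.1.1","3.1.2","3.1.3","3.2","3.2.1","3.2.2","3.3","3.3.1","3.3.2","3.3.3"
"E1",5,5,5,4,5,4,5,4,5,5,5,4,5,5,5,5,3,4,3,4,3,5,4,5,3,5,4,5,5,5,4
"E2",5,5,5,4,5,4,5,4,5,5,5,4,5,5,5,5,5,4,3,4,3,5,4,4,3,4,4,5,4,5,4
"E3",5,5,5,5,5,4,5,4,5,5,5,4,5,5,5,5,5,4,5,4,3,4,4,4,3,4,3,5,4,5,4
"E4",5,5,5,5,5,5,5,4,5,5,5,4,5,5,5,5,4,4,5,4,5,4,4,4,3,4,3,5,4,5,4
"E5",5,5,5,5,5,5,5,5,5,4,5,3,5,5,5,5,4,4,4,4,5,4,5,4,3,4,3,5,4,5,4
"E6",5,5,5,5,5,5,5,5,5,5,4,3,5,4,5,5,4,4,4,4,5,4,5,4,5,4,3,5,4,5,4
"E7",5,5,5,5,5,5,5,5,5,5,4,5,5,4,5,4,4,4,4,4,5,4,5,4,5,4,5,5,4,5,4
"E8",5,5,5,5,5,5,5,5,5,5,4,5,5,5,5,4,4,3,4,4,5,4,4,4,4,4,4,5,5,4,4
"E9",5,5,5,5,4,5,4,5,5,5,4,5,5,5,5,5,4,3,4,4,5,4,4,4,4,4,4,5,5,4,5
"E10",5,5,5,5,4,5,4,5,5,5,4,5,5,5,5,5,4,5,4,4,4,3,4,4,4,4,4,5,5,4,5
"E11",5,5,5,5,5,5,4,5,5,5,4,5,5,5,5,5,4,5,4,5,4,3,4,3,4,3,4,5,5,4,5
"E12",5,5,5,5,5,5,5,5,5,5,4,4,5,5,5,5,4,5,4,5,4,5,4,3,4,3,4,4,5,4,4
"E13",5,5,5,5,5,5,5,5,5,5,3,4,5,5,5,5,4,4,4,5,4,5,4,5,4,3,4,4,5,4,4
"E14",5,5,5,5,5,5,5,5,5,5,5,4,4,5,5,5,4,4,4,5,4,5,4,5,4,5,4,3,5,4,4
"E15",5,5,5,5,5,5,5,4,5,5,5,4,5,5,4,5,3,4,4,5,3,5,4,5,4,5,4,5,5,4,4
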