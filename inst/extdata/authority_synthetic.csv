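"expert_id","theory","practice","reference","intuition","familiarity"
"E1","large","large","medium","medium",5
"E2","large","medium","medium","medium",4
"E3","large","large","medium","medium",5
"E4","medium","large","medium","medium",4
"E5","large","large","medium","medium",5
"E6","medium","large","medium","medium",4
"E7","large","medium","medium","medium",4
"E8","large","large","medium","medium",5
"E9","medium","large","medium","medium",3
"E10","large","medium","medium","medium",4
"E11","small","large","medium","medium",4
"E12","large","large","medium","medium",5
"E13","medium","large","medium","medium",4
"E14","large","medium","medium","medium",4
"E15","medium","large","medium","medium",5
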