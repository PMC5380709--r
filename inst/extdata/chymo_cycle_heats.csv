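"id","description","charge","dhf","role","reactant_id","product_id"
"step1","substrate docked, triad poised",-1,"0.00","intermediate","",""
"step2","first tetrahedral intermediate, His57(+)",-1,"-2.54","intermediate","",""
"step3","proton on peptide nitrogen, zwitterionic",-1,"-4.83","intermediate","",""
"step4","acyl-enzyme intermediate, water in site",-1,"4.29","intermediate","",""
"step5","second tetrahedral intermediate, His57(+)",-1,"4.60","intermediate","",""
"step6","products formed, Ser195 regenerated",-1,"-5.70","intermediate","",""
"ts_1_2","O-gamma attacks peptide C, proton to His57",-1,"17.93","transition_state","step1","step2"
"ts_2_3","proton migrates His57 -> peptide N",-1,"17.58","transition_state","step2","step3"
"ts_1_3","hypothetical one-step proton transfer",-1,"35.86","transition_state","step1","step3"
"ts_4_5","water splits: OH- to acyl C, H+ to His57",-1,"13.97","transition_state","step4","step5"
"ts_5_6","proton His57 -> Ser195, ester breaks",-1,"20.36","transition_state","step5","step6"
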