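"id","description","charge","dhf","role","reactant_id","product_id"
"step1","Met192 side-chain replaced by -CH2-CH3",-1,"0.00","intermediate","",""
"step2","Met192 side-chain replaced by -CH2-CH3",-1,"2.48","intermediate","",""
"step3","Met192 side-chain replaced by -CH2-CH3",-1,"-1.19","intermediate","",""
"step4","Met192 side-chain replaced by -CH2-CH3",-1,"5.59","intermediate","",""
"step5","Met192 side-chain replaced by -CH2-CH3",-1,"1.59","intermediate","",""
"step6","Met192 side-chain replaced by -CH2-CH3",-1,"-2.51","intermediate","",""
"ts_1_2","Met192 side-chain replaced by -CH2-CH3",-1,"18.42","transition_state","step1","step2"
"ts_2_3","Met192 side-chain replaced by -CH2-CH3",-1,"20.35","transition_state","step2","step3"
"ts_1_3","Met192 side-chain replaced by -CH2-CH3",-1,"39.40","transition_state","step1","step3"
"ts_4_5","Met192 side-chain replaced by -CH2-CH3",-1,"14.39","transition_state","step4","step5"
"ts_5_6","Met192 side-chain replaced by -CH2-CH3",-1,"24.35","transition_state","step5","step6"
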