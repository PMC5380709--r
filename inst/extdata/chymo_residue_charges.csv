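"residue","site","step1","step2","delta"
"Gly43","cationic","0.067","0.089","0.022"
"His57","cationic","0.059","0.947","0.888"
"Asp102","cationic","-0.816","-0.789","0.027"
"Ser214","cationic","-0.095","-0.060","0.035"
"Met192","oxyanion","-0.007","-0.049","-0.042"
"Asp194","oxyanion","-0.922","-0.960","-0.038"
"Ser195","oxyanion","0.018","-0.267","-0.285"
"Gly196","oxyanion","-0.009","-0.039","-0.030"
"Ile212","oxyanion","-0.014","-0.024","-0.010"
"Trp215","oxyanion","0.098","0.041","-0.057"
"Trp252","oxyanion","0.045","-0.233","-0.278"
"Thr253","oxyanion","0.000","-0.281","-0.281"
"Leu254","oxyanion","0.003","-0.011","-0.014"
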