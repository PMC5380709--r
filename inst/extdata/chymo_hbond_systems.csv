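"bond","system","description","dhf"
"Gly193","H_A","step 1 unmodified","0.00"
"Gly193","H_B","step 2 unmodified","-2.54"
"Gly193","X_A","step 1, -NH on Gly193 replaced with -O","-32.35"
"Gly193","X_B","step 2, -NH on Gly193 replaced with -O","-21.29"
"Ser195","H_A","step 1 unmodified","0.00"
"Ser195","H_B","step 2 unmodified","-2.54"
"Ser195","X_A","step 1, -NH on Ser195 replaced with -O","-26.56"
"Ser195","X_B","step 2, -NH on Ser195 replaced with -O","-15.84"
"Thr253","H_A","step 1 unmodified","0.00"
"Thr253","H_B","step 2 unmodified","-2.54"
"Thr253","X_A","step 1, -OH on Thr253 replaced with -F","6.97"
"Thr253","X_B","step 2, -OH on Thr253 replaced with -F","11.56"
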