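"cycle","system","description","charge","step","dhf"
"asp102_oxyanion","A","unmodified",-1,"step1","0.00"
"asp102_oxyanion","B","Asp102 replaced by Ala102",0,"step1","245.14"
"asp102_oxyanion","C","Trp252 O replaced by F",0,"step1","172.22"
"asp102_oxyanion","D","Asp102->Ala102 and Trp252 O->F",1,"step1","423.29"
"asp102_oxyanion","A","unmodified",-1,"step2","-2.54"
"asp102_oxyanion","B","Asp102 replaced by Ala102",0,"step2","253.90"
"asp102_oxyanion","C","Trp252 O replaced by F",0,"step2","160.84"
"asp102_oxyanion","D","Asp102->Ala102 and Trp252 O->F",1,"step2","423.45"
"asp102_his57","A","unmodified",-1,"step2","-2.54"
"asp102_his57","B","Asp102 replaced by Ala102",0,"step2","253.90"
"asp102_his57","C","His57 proton on N-epsilon2 deleted",-2,"step2","-69.41"
"asp102_his57","D","Asp102->Ala102 and His57 proton deleted",-1,"step2","166.38"
"his57_oxyanion","A","unmodified",-1,"step2","-2.54"
"his57_oxyanion","B","proton deleted from His57",-2,"step2","-69.41"
"his57_oxyanion","C","Trp252 O replaced by F",0,"step2","160.84"
"his57_oxyanion","D","His57 proton deleted and Trp252 O->F",-1,"step2","75.76"
"his57_oxyanion_d102a","A","D102A mutation",0,"step2","253.90"
"his57_oxyanion_d102a","B","D102A with proton deleted from His57",-1,"step2","166.38"
"his57_oxyanion_d102a","C","D102A with Trp252 O replaced by F",1,"step2","423.45"
"his57_oxyanion_d102a","D","D102A, His57 neutral, Trp252 O->F",0,"step2","317.88"
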