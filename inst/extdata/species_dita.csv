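name,formula,dfH_kJ_mol,u_dfH,dfS_J_molK,S_abs_J_molK
TMA,C9H4O5,-757.7,,,
"3,4-DABA",C7H8N2O2,-292.0,1.8,,
"3,5-DABA",C7H8N2O2,-289.0,1.8,,
"3,4-DITA",C25H12N2O10,-1406.6,,-1303.8,839.8
"3,5-DITA",C25H12N2O10,-1410.1,,-1295.6,848.0
H2O,H2O,-241.826,0.040,,
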