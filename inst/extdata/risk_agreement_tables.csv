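table,row,c1,c2,c3,c4,c5
ctac_rest_manual_vs_auto,1,17,0,0,0,0
ctac_rest_manual_vs_auto,2,3,2,1,0,0
ctac_rest_manual_vs_auto,3,2,0,14,1,1
ctac_rest_manual_vs_auto,4,2,0,4,30,1
ctac_rest_manual_vs_auto,5,0,0,0,7,43
ctac_stress_manual_vs_auto,1,18,0,2,0,0
ctac_stress_manual_vs_auto,2,0,2,0,0,0
ctac_stress_manual_vs_auto,3,1,1,22,0,0
ctac_stress_manual_vs_auto,4,1,0,3,28,2
ctac_stress_manual_vs_auto,5,0,0,0,5,43
csct_vs_ctac_rest_manual,1,12,1,0,0,0
csct_vs_ctac_rest_manual,2,5,0,1,0,0
csct_vs_ctac_rest_manual,3,0,2,6,4,0
csct_vs_ctac_rest_manual,4,0,0,3,25,7
csct_vs_ctac_rest_manual,5,0,0,1,6,55
csct_vs_ctac_rest_auto,1,13,0,0,0,0
csct_vs_ctac_rest_auto,2,5,0,1,0,0
csct_vs_ctac_rest_auto,3,4,0,3,5,0
csct_vs_ctac_rest_auto,4,2,0,2,22,9
csct_vs_ctac_rest_auto,5,0,0,1,8,53
csct_vs_ctac_stress_manual,1,13,0,0,0,0
csct_vs_ctac_stress_manual,2,5,0,1,0,0
csct_vs_ctac_stress_manual,3,1,0,6,5,0
csct_vs_ctac_stress_manual,4,0,0,3,24,8
csct_vs_ctac_stress_manual,5,1,0,1,6,54
csct_vs_ctac_stress_auto,1,11,0,1,1,0
csct_vs_ctac_stress_auto,2,5,0,1,0,0
csct_vs_ctac_stress_auto,3,1,0,6,5,0
csct_vs_ctac_stress_auto,4,2,0,3,20,10
csct_vs_ctac_stress_auto,5,1,0,2,7,52
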