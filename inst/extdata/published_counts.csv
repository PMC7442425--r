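comparison,outcome,tar,database,users_t,users_c,events_t,events_c,rate_t,rate_c
hcq_ssz,cv_mortality,30d,Clinformatics,51280,17389,16,<5,3.85,<3.54
hcq_ssz,cv_mortality,30d,VA,32028,14349,9,<5,3.43,<4.25
hcq_ssz,cv_mortality,on_treatment,Clinformatics,51280,17389,234,25,4.39,2.00
hcq_ssz,cv_mortality,on_treatment,CPRD,9127,11398,7,25,0.39,0.94
hcq_ssz,cv_mortality,on_treatment,VA,32028,14349,315,65,5.69,3.71
hcq_ssz,all_cause_mortality,30d,Clinformatics,51280,17389,20,10,4.81,7.09
hcq_ssz,all_cause_mortality,30d,CPRD,9127,11398,6,5,8.03,5.35
hcq_ssz,all_cause_mortality,30d,IMRD,8851,8460,<5,6,<6.91,8.66
hcq_ssz,all_cause_mortality,30d,VA,32028,14349,45,17,17.13,14.45
hcq_azm_amx,cv_mortality,30d,Clinformatics,23597,24521,9,6,4.70,3.02
hcq_azm_amx,cv_mortality,30d,VA,6234,8005,46,18,90.60,27.49
hcq_azm_amx,heart_failure,30d,AmbEMR,13152,12053,16,16,14.83,16.18
hcq_azm_amx,heart_failure,30d,CCAE,32586,32496,30,23,11.36,8.73
hcq_azm_amx,heart_failure,30d,Clinformatics,23541,24468,65,49,34.08,24.73
hcq_azm_amx,heart_failure,30d,MDCD,3796,3795,16,9,52.08,29.21
hcq_azm_amx,heart_failure,30d,MDCR,8085,9239,45,33,68.88,43.97
hcq_azm_amx,heart_failure,30d,OpenClaims,215732,232725,472,370,26.68,19.38
hcq_azm_amx,heart_failure,30d,OptumEHR,18054,16298,99,60,67.77,45.45
hcq_azm_amx,heart_failure,30d,VA,6164,7959,79,31,158.53,47.73
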