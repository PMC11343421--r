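"event","rate_epg","rate_soc","disutility","duration_months","unit_cost","include"
"uti",0.00423333333333333,0.003775,-0.04,1,213,TRUE
"genital_infection",0.000683333333333333,0.000325,-0.038,1,320,TRUE
"acute_renal_failure",0.005875,0.00605,-0.013,1,3185,TRUE
"hepatic_injury",0.002025,0.00236666666666667,-0.042,1,3230,TRUE
"volume_depletion",0.00510833333333333,0.00448333333333333,-0.026,1,984,TRUE
"hypotension",0.00448333333333333,0.004,-0.025,1,1282,TRUE
"hypoglycaemia",0.00113333333333333,0.001175,-0.002,1,693,TRUE
"bone_fracture",0.001975,0.00191666666666667,-0.156,1,3523,TRUE
"ketoacidosis",5e-04,0.000166666666666667,-0.05,1,2500,FALSE
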