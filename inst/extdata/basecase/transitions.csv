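"arm","period","from","Q1","Q2","Q3","Q4"
"EPG_SOC","m1_3","Q1",0.45907673530739,0.387773924018486,0.110101186995461,0.0430481536786628
"EPG_SOC","m1_3","Q2",0.138290817522893,0.570111143273257,0.23575446755827,0.0558435716455803
"EPG_SOC","m1_3","Q3",0.0480467849064113,0.185508324240776,0.535000645680222,0.231444245172591
"EPG_SOC","m1_3","Q4",0.00816848426696195,0.0720583161221857,0.325001948484385,0.594771251126467
"EPG_SOC","m4_8","Q1",0.60195054857864,0.302034470001132,0.0590182173086782,0.0369967641115501
"EPG_SOC","m4_8","Q2",0.120746166548571,0.617186108090177,0.221972424326246,0.0400953010350064
"EPG_SOC","m4_8","Q3",0.0273972201570945,0.112857158016417,0.654091909856577,0.205653711969911
"EPG_SOC","m4_8","Q4",0.00677429461924343,0.0762320756112499,0.257088719596322,0.659904910173185
"EPG_SOC","m9plus","Q1",0.713497458801432,0.232054537713945,0.0404290868462453,0.0140189166383778
"EPG_SOC","m9plus","Q2",0.0976051334305607,0.70323774181087,0.170438326699546,0.0287187980590238
"EPG_SOC","m9plus","Q3",0.0433183707929241,0.112482533518639,0.73959749333192,0.104601602356516
"EPG_SOC","m9plus","Q4",0.00551964667849186,0.0520802046945983,0.190240198857072,0.752159949769838
"SOC","m1_3","Q1",0.525266915397128,0.36325739786785,0.0844440337973274,0.0270316529376954
"SOC","m1_3","Q2",0.174227529487625,0.588063287926685,0.199097392859426,0.0386117897262637
"SOC","m1_3","Q3",0.0700830658804033,0.221540568864331,0.523100667267659,0.185275697987606
"SOC","m1_3","Q4",0.0133594743912897,0.0964879562901705,0.356300200590294,0.533852368728246
"SOC","m4_8","Q1",0.638967038070191,0.284353653608502,0.049280266984041,0.0273990413372658
"SOC","m4_8","Q2",0.138673235813209,0.628666186906453,0.20053382956328,0.0321267477170585
"SOC","m4_8","Q3",0.034878737797907,0.127428928799515,0.65503176707138,0.182660566331198
"SOC","m4_8","Q4",0.00919147565957164,0.0917367959833137,0.274393302415614,0.624678425941501
"SOC","m9plus","Q1",0.733153403096554,0.220114641033843,0.0354004872156113,0.0113314686539922
"SOC","m9plus","Q2",0.10671842172953,0.709782596443843,0.1587986766843,0.0247003051423271
"SOC","m9plus","Q3",0.0503890194125065,0.120782864074711,0.73311500072109,0.0957131157916926
"SOC","m9plus","Q4",0.00683651109177919,0.0595459691349539,0.200788307134044,0.732829212639223
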