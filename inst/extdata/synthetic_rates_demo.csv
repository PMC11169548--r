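location,sex,age,incidence,prevalence,cause_mortality,all_cause_mortality
synthetic,female,0,0.00010457289,0.00026146956,0,0.001
synthetic,female,5,0.00010451306,0.00078418428,0,0.001
synthetic,female,10,0.00010445328,0.0013066,0,0.001
synthetic,female,15,0.00010439353,0.0018287169,0,0.001
synthetic,female,20,0.0010406596,0.0046950263,0,0.001
synthetic,female,25,0.0010347257,0.0098834538,0,0.001
synthetic,female,30,0.0010288288,0.015042305,0,0.001
synthetic,female,35,0.0010229686,0.020171763,0,0.001
synthetic,female,40,0.0040341812,0.032868016,0,0.005
synthetic,female,45,0.0039432897,0.05280933,0,0.005
synthetic,female,50,0.0038546329,0.072301835,0,0.005
synthetic,female,55,0.0037681509,0.091356553,0,0.005
synthetic,female,60,0.0072876664,0.11914117,0,0.02
synthetic,female,65,0.0069662985,0.1547528,0,0.02
synthetic,female,70,0.0066603492,0.1887973,0,0.02
synthetic,female,75,0.0063690142,0.22134968,0,0.02
synthetic,male,0,0.00010457289,0.00026146956,0,0.001
synthetic,male,5,0.00010451306,0.00078418428,0,0.001
synthetic,male,10,0.00010445328,0.0013066,0,0.001
synthetic,male,15,0.00010439353,0.0018287169,0,0.001
synthetic,male,20,0.0010406596,0.0046950263,0,0.001
synthetic,male,25,0.0010347257,0.0098834538,0,0.001
synthetic,male,30,0.0010288288,0.015042305,0,0.001
synthetic,male,35,0.0010229686,0.020171763,0,0.001
synthetic,male,40,0.0040341812,0.032868016,0,0.005
synthetic,male,45,0.0039432897,0.05280933,0,0.005
synthetic,male,50,0.0038546329,0.072301835,0,0.005
synthetic,male,55,0.0037681509,0.091356553,0,0.005
synthetic,male,60,0.0072876664,0.11914117,0,0.02
synthetic,male,65,0.0069662985,0.1547528,0,0.02
synthetic,male,70,0.0066603492,0.1887973,0,0.02
synthetic,male,75,0.0063690142,0.22134968,0,0.02
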