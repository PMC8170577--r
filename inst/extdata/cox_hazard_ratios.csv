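outcome,bmi_low,bmi_high,hr,ci_low,ci_high
acs,18.5,25,1.0,NA,NA
acs,25,30,1.03,1.02,1.04
acs,30,35,1.11,1.09,1.12
acs,35,40,1.14,1.12,1.17
acs,40,45,1.18,1.14,1.23
stroke,18.5,25,1.0,NA,NA
stroke,25,30,0.92,0.91,0.94
stroke,30,35,0.94,0.92,0.95
stroke,35,40,0.98,0.95,1.00
stroke,40,45,1.02,0.98,1.06
t2d,18.5,25,1.0,NA,NA
t2d,25,30,2.30,2.27,2.34
t2d,30,35,4.73,4.65,4.80
t2d,35,40,7.81,7.67,7.96
t2d,40,45,10.8,10.5,11.0
mortality,18.5,25,1.0,NA,NA
mortality,25,30,0.77,0.76,0.77
mortality,30,35,0.81,0.80,0.82
mortality,35,40,0.95,0.94,0.97
mortality,40,45,1.21,1.18,1.24
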