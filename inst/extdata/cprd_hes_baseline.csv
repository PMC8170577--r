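variable,bmi_18_5_24_9,bmi_25_29_9,bmi_30_34_9,bmi_35_39_9,bmi_40_44_9
n,1099106,1074953,507425,176237,67231
age_mean,48.5,53.1,52.1,49.3,47.4
age_sd,19.2,16.9,15.9,15.4,14.6
bmi_mean,22.5,27.3,32.1,37.0,42.3
bmi_sd,1.7,1.4,1.4,1.4,1.5
height_m_mean,1.68,1.69,1.68,1.66,1.65
height_m_sd,0.09,0.10,0.10,0.10,0.10
smoking_ever_pct,49.3,50.2,50.6,48.8,47.3
women_pct,64.6,49.7,53.1,62.9,70.9
antihypertensive_pct,14.7,22.3,26.1,26.7,28.5
lipid_lowering_pct,8.3,13.9,15.7,14.6,14.9
sbp_mean,128.2,135.4,138.3,139.4,140.0
sbp_sd,71.4,73.8,54.2,56.7,57.7
total_chol_mean,203.7,207.8,208.0,206.2,201.2
total_chol_sd,41.5,42.0,42.2,41.7,40.9
hdl_mean,61.0,53.9,50.4,48.8,47.5
hdl_sd,18.1,16.5,15.3,14.4,14.2
hba1c_mean,7.5,7.6,7.7,7.8,7.8
hba1c_sd,1.6,1.5,1.5,1.5,1.6
triglycerides_mean,118.9,152.2,175.0,180.1,177.0
triglycerides_sd,69.0,87.9,98.1,99.4,94.6
tg_ge_150_pct,22.4,40.0,51.7,54.3,53.8
no_dysglycemia_pct,95.3,90.2,85.5,82.5,78.8
prediabetes_pct,2.0,4.1,5.9,6.9,6.7
t2d_pct,2.7,5.7,8.6,10.6,14.5
t2d_duration_mean,5.9,5.0,4.5,4.3,4.1
t2d_duration_sd,6.9,6.1,5.6,5.4,5.1
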