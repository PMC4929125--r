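panel,group,ratio,pct_printed,baseline_mean,baseline_sd,change_printed,note
single,VPA,0.931,-6.9,12.97,12.64,-7.85,
single,MPA,0.940,-6.0,41.32,17.46,-22.83,
adjusted,VPA,0.989,-1.1,NA,NA,NA,
adjusted,MPA,1.036,3.6,NA,NA,NA,
sex,male,0.971,-2.9,15.16,15.03,-4.82,
sex,female,0.893,-10.7,10.98,9.56,-8.46,
ethnicity,white,0.939,-6.1,10.58,8.43,NA,no printed extrapolation
ethnicity,black,0.871,-12.9,NA,NA,NA,baseline mean not printed (n<10)
ethnicity,hispanic,0.906,-9.4,NA,NA,NA,baseline mean not printed (n<10)
ethnicity,other,0.906,-9.4,NA,NA,NA,baseline mean not printed (n<10)
maternal_education,high school,0.980,-2.0,17.91,14.9,-4.14,
maternal_education,college,0.979,NA,NA,NA,NA,not significant; no printed percent
maternal_education,university,1.004,NA,NA,NA,NA,not significant; no printed percent
weight_status,normal,0.939,-6.1,12.85,12.34,-7.18,
weight_status,overweight/obese,0.919,-8.1,11.71,10.16,-7.80,
region,UK,1.065,6.5,13.60,12.45,17.24,
region,Europe,1.016,NA,NA,NA,NA,not significant; no printed percent
region,North America,0.885,-11.5,11.18,8.31,-8.90,
region,Brazil,0.673,NA,NA,NA,NA,not significant; no printed percent
region,Australia,0.979,-2.1,19.78,16.06,-4.78,printed change reflects the unrounded ratio (3-dp ratio gives -4.77)
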