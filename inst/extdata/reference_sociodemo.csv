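variable,category,cluster_1,cluster_2,cluster_3,cluster_4,all
age_band,lt_16,0.87,0.26,0.92,0.32,0.80
age_band,17_24,1.92,3.08,1.07,0.61,1.0
age_band,25_44,9.74,26.77,7.70,4.73,7.22
age_band,45_64,26.2,47.58,32.13,22.24,30.1
age_band,65_84,50.39,21.83,49.78,59.39,51.58
age_band,gt_85,10.88,0.5,8.41,12.72,9.29
sex,male,52.85,24.44,45.84,43.84,45.48
sex,female,47.15,75.56,54.16,56.16,54.52
family_type,registered_partnership,0.1,0.2,0.14,0.11,0.13
family_type,cohabiting_couple,2.47,4.86,2.75,1.92,2.6
family_type,co_residing_couple,4.18,8.76,5.41,4.71,5.26
family_type,married_couple,40.07,43.08,52.09,50.67,51.52
family_type,single,53.22,43.1,39.62,42.59,40.49
region,north_denmark,8.68,12.69,11.37,11.53,11.35
region,central_denmark,18.95,23.65,23.09,22.79,22.95
region,southern_denmark,23.49,24.56,23.91,24.91,24.10
region,capital,32.19,23.85,25.72,25.72,25.84
region,zealand,16.7,15.25,15.9,15.05,15.74
employment,self_employed,1.4,2.74,2.39,1.56,2.21
employment,employee,12.66,42.36,27.7,15.19,24.96
employment,unemployed,1.93,5.69,1.2,1.05,1.20
employment,in_education,1.12,4.4,1.24,0.64,1.13
employment,early_retirement,15.4,10.46,7.7,8.24,7.99
employment,retired,57.41,35.42,53.2,67.77,56.13
employment,social_assistance,8.2,13.05,4.67,4.57,4.75
employment,unknown,1.88,1.97,1.91,0.95,1.72
education,none,29.65,9.05,24.81,30.38,25.95
education,short,36.39,44.52,38.39,36.56,38.0
education,medium,18.95,16.64,19.45,18.47,19.22
education,long,11.65,28.57,14.65,12.33,14.27
education,unknown,3.36,1.21,2.7,2.27,2.62
income_quartile,q1,25.29,21.03,22.66,25.08,23.17
income_quartile,q2,53.01,44.88,46.77,50.54,47.65
income_quartile,q3,8.81,14.44,11.58,10.32,11.29
income_quartile,q4,12.87,19.64,18.99,14.06,17.89
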