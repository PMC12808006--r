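condition,cluster_1,cluster_2,cluster_3,cluster_4,all,oe_1,oe_2,oe_3,oe_4
ischemic_heart_disease,24.60,10.54,15.21,21.94,16.72,1.47,0.63,0.91,1.31
atrial_fibrillation,22.78,5.14,9.87,17.65,11.66,1.95,0.44,0.85,1.51
heart_failure,14.79,2.56,4.51,7.83,5.37,2.75,0.48,0.84,1.46
peripheral_artery_occlusive_disease,14.03,3.08,5.89,8.98,6.66,2.11,0.46,0.88,1.35
hypertension,70.70,46.07,68.11,78.56,70.15,1.01,0.66,0.97,1.12
stroke,17.90,5.72,8.49,10.36,9.04,1.98,0.63,0.94,1.15
high_cholesterol,37.71,25.10,43.88,51.78,45.25,0.83,0.55,0.97,1.14
diabetes_i,9.18,3.81,4.04,5.07,4.35,2.11,0.88,0.93,1.17
diabetes_ii,21.10,10.74,16.53,24.99,18.29,1.15,0.59,0.90,1.37
obesity,12.64,19.62,10.37,11.16,10.61,1.19,1.85,0.98,1.051
copd,22.09,19.18,17.06,22.80,18.31,1.21,1.05,0.93,1.25
allergies,9.08,20.35,12.39,14.76,12.83,0.71,1.59,0.97,1.15
joint_disease,2.98,2.30,2.57,3.12,2.69,1.11,0.86,0.96,1.16
osteoporosis,17.15,11.64,14.19,18.12,15.02,1.14,0.77,0.94,1.21
osteoarthritis,21.65,17.97,22.08,27.29,23.10,0.94,0.78,0.96,1.18
cancer_digestive,8.39,1.53,1.86,2.25,2.07,4.06,0.74,0.90,1.09
cancer_respiratory,5.03,0.66,0.79,1.25,0.96,5.21,0.68,0.81,1.30
cancer_skin,0.99,0.87,0.80,0.89,0.84,1.20,1.06,0.98,1.07
cancer_breast,4.07,4.31,2.83,2.82,2.86,1.42,1.50,0.99,0.99
cancer_genital,5.86,1.59,2.61,3.18,2.79,2.10,0.57,0.94,1.14
cancer_other,11.52,2.20,2.57,3.11,2.85,4.04,0.77,0.90,1.09
epilepsy,13.54,10.15,5.81,5.98,6.02,2.25,1.69,0.97,0.99
parkinsons_disease,1.82,0.36,0.66,1.06,0.77,2.38,0.47,0.87,1.39
multiple_sclerosis,1.13,1.45,0.85,0.68,0.82,1.37,1.76,1.03,0.82
dementia,3.56,0.62,2.78,2.98,2.83,1.26,0.22,0.98,1.05
schizophrenia,4.35,0.54,0.50,0.53,0.59,7.41,0.91,0.86,0.90
depression,33.14,53.69,19.34,23.26,20.55,1.61,2.61,0.94,1.13
anxiety,4.54,5.10,0.94,1.01,1.05,4.34,4.88,0.90,0.96
addictive_disorder,7.15,1.05,1.03,0.98,1.14,6.27,0.92,0.90,0.86
personality_disorder,2.00,0.75,0.28,0.27,0.32,6.30,2.37,0.89,0.87
kidney_disease,11.07,1.65,2.63,3.74,3.02,3.67,0.55,0.87,1.24
liver_disease,6.00,1.33,1.72,1.63,1.79,3.35,0.74,0.96,0.91
bowel_disease,8.35,6.61,4.50,4.92,4.67,1.79,1.42,0.96,1.05
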