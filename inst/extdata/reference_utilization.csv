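variable,cluster_1,cluster_2,cluster_3,cluster_4,all
hospitalizations,4.15,0.40,0.048,0.52,0.23
bed_days,29.49,1.67,0.14,1.61,1.03
medication_usage,9.30,5.97,5.57,8.09,6.15
outpatient_visits,16.13,3.55,0.47,3.64,1.43
gp_visits,21.74,16.59,3.19,23.10,7.59
specialist_visits,2.46,4.33,0.46,6.08,1.64
psychologist_visits,0.039,8.84,0.0062,0.024,0.048
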