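variable,mean_osa,sd_osa,mean_gs,sd_gs,n_osa,n_gs,t_published
BMI,27.52,3.30,23.09,1.96,46,46,7.827
AHI,58.26,20.37,2.51,1.21,46,46,18.529
total_sleep_time,372.26,83.88,398.30,18.94,46,46,-2.054
stage1_pct,31.28,17.38,10.22,3.72,46,46,8.037
stage2_pct,39.12,14.78,40.74,7.05,46,46,-0.672
stage34_pct,22.49,18.21,21.15,4.54,46,46,0.483
REM_pct,7.29,7.96,21.89,7.48,46,46,-9.070
arousal_index,40.36,23.63,11.93,2.79,46,46,8.102
SaO2_below90_pct,31.15,21.34,0.27,0.17,46,46,9.813
average_SaO2,90.69,4.46,95.59,2.41,46,46,-6.547
oxygen_desaturation_index,54.42,25.51,2.84,1.40,46,46,14.897
nadir_SaO2,66.26,12.46,90.33,2.88,46,46,-12.765
MoCA,25.17,2.11,27.74,1.39,46,46,-6.883
visuospatial_executive,4.07,0.83,4.67,0.63,46,46,-3.960
delayed_memory,3.20,1.17,4.85,0.36,46,46,-9.172
attention,5.33,0.99,5.83,0.38,46,46,-3.194
language,2.04,0.56,2.83,0.38,46,46,-7.860
abstraction,1.50,0.51,1.85,0.36,46,46,-3.790
orientation,5.72,0.66,5.93,0.25,46,46,-2.102
ESS,12.11,3.84,3.39,2.18,46,46,13.405
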