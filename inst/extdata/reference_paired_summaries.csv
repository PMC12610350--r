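task,measure,n,comfortable_mean,comfortable_sd,fast_mean,fast_sd,diff_mean,diff_sd,t_printed,exact_2dp
letter,duration_s,24,39.40,12.04,29.54,7.39,-9.85,12.08,-4.00,FALSE
shoe,duration_s,24,87.88,18.42,78.97,25.17,-8.91,19.52,-2.24,TRUE
cup,duration_s,23,35.67,6.76,23.95,6.76,-11.72,7.29,-7.71,TRUE
writing,duration_s,23,53.26,6.87,45.71,8.87,-7.54,9.75,-3.71,TRUE
letter,avg_total_ang_vel_dps,24,147.52,37.95,185.73,37.62,38.22,37.77,4.96,TRUE
shoe,avg_total_ang_vel_dps,24,155.52,31.37,179.43,35.74,23.91,28.04,4.18,TRUE
cup,avg_total_ang_vel_dps,23,108.46,22.82,147.54,27.27,39.08,22.58,8.30,TRUE
writing,avg_total_ang_vel_dps,23,36.93,9.04,42.90,15.53,5.97,11.58,2.47,TRUE
letter,total_sd_accel_ms2,24,1.56,0.65,1.65,0.12,0.09,0.09,4.82,FALSE
shoe,total_sd_accel_ms2,24,1.47,0.04,1.51,0.05,0.04,0.03,5.35,FALSE
cup,total_sd_accel_ms2,23,1.55,0.05,1.61,0.03,0.06,0.05,5.79,FALSE
writing,total_sd_accel_ms2,23,1.46,0.04,1.47,0.04,0.01,0.03,1.81,FALSE
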