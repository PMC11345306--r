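feature_id,display_name,feature_set,p_printed,mean_healthy,sd_healthy,mean_hd,sd_hd,n_healthy,n_hd
extension_r,Extension,primary,0.0031,2.03,0.74,2.91,1.10,30,14
step_length_r,Step length,primary,0.0033,0.03,0.01,0.06,0.03,30,14
max_acc_amp_r,MaxAccAmp,primary,0.0022,2.16,1.07,3.41,1.31,30,14
ventral_acc_r,Peak vertical force,primary,0.0038,144.39,69.52,230.61,107.51,30,14
max_gyr_amp_r,MaxGyrAmp,primary,0.0067,0.57,0.25,0.83,0.32,30,14
acc_sd_r,Standard deviation,primary,0.0052,0.43,0.16,0.61,0.22,30,14
ext_sym_fl_hr,Extension Symmetry Femur L - Humerus R,additional,0.010,12.06,4.41,16.86,7.07,30,14
maxacc_sym_fr_fl,MaxAccAmp Symmetry Femur R - Femur L,additional,0.044,3.95,1.25,5.19,2.06,30,14
maxacc_sym_fr_hl,MaxAccAmp Symmetry Femur R - Humerus L,additional,0.099,10.40,4.4,14.34,4.42,30,14
maxacc_sym_fl_hr,MaxAccAmp Symmetry Femur L - Humerus R,additional,0.014,9.58,3.61,13.02,4.48,30,14
norm_sl_sym_fr_hl,Normalised step length Symmetry Femur R - Humerus L,additional,0.010,3.26,2.72,8.60,9.93,30,14
sl_sym_fr_hl,Step length Symmetry Femur R - Humerus L,additional,0.010,3.26,2.72,8.6,9.93,30,14
sym_pr_lumbar,Symmetry PR Lumbar,additional,0.011,2.21,0.90,2.98,1.13,30,14
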