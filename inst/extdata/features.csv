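feature_id,display_name,unit,exclusion_category,laterality,symmetry_pair
extension_r,Extension (right),deg,none,right,extension_l
extension_l,Extension (left),deg,none,left,extension_r
step_length_r,Step length (right),m,step_length,right,step_length_l
step_length_l,Step length (left),m,step_length,left,step_length_r
max_acc_amp_r,MaxAccAmp (right),m/s^2,none,right,max_acc_amp_l
max_acc_amp_l,MaxAccAmp (left),m/s^2,none,left,max_acc_amp_r
ventral_acc_r,Ventral acceleration (right),m/s^2,none,right,ventral_acc_l
ventral_acc_l,Ventral acceleration (left),m/s^2,none,left,ventral_acc_r
max_gyr_amp_r,MaxGyrAmp (right),rad/s,none,right,max_gyr_amp_l
max_gyr_amp_l,MaxGyrAmp (left),rad/s,none,left,max_gyr_amp_r
acc_sd_r,Standard deviation (right),m/s^2,none,right,acc_sd_l
acc_sd_l,Standard deviation (left),m/s^2,none,left,acc_sd_r
ext_sym_fl_hr,Extension Symmetry Femur L - Humerus R,%,none,left,ext_sym_fr_hl
ext_sym_fr_hl,Extension Symmetry Femur R - Humerus L,%,none,right,ext_sym_fl_hr
maxacc_sym_fr_fl,MaxAccAmp Symmetry Femur R - Femur L,%,none,right,maxacc_sym_fl_fr
maxacc_sym_fl_fr,MaxAccAmp Symmetry Femur L - Femur R,%,none,left,maxacc_sym_fr_fl
maxacc_sym_fr_hl,MaxAccAmp Symmetry Femur R - Humerus L,%,none,right,maxacc_sym_fl_hr
maxacc_sym_fl_hr,MaxAccAmp Symmetry Femur L - Humerus R,%,none,left,maxacc_sym_fr_hl
norm_sl_sym_fr_hl,Normalised step length Symmetry Femur R - Humerus L,%,none,right,norm_sl_sym_fl_hr
norm_sl_sym_fl_hr,Normalised step length Symmetry Femur L - Humerus R,%,none,left,norm_sl_sym_fr_hl
sl_sym_fr_hl,Step length Symmetry Femur R - Humerus L,%,none,right,sl_sym_fl_hr
sl_sym_fl_hr,Step length Symmetry Femur L - Humerus R,%,none,left,sl_sym_fr_hl
sym_pr_lumbar,Symmetry PR Lumbar,%,none,axial,
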