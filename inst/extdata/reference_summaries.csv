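comparison,units,label_a,mean_a,sd_a,n_a,label_b,mean_b,sd_b,n_b
wall_pred_vs_measured,mm,predicted wall jet length,0.92,0.21,5,measured wall length,0.72,0.10,5
alar_pred_vs_measured,mm,predicted alar jet length,0.46,0.11,5,measured alar length,0.72,0.10,5
cavity_pred_vs_measured,mm,predicted cavity length,0.46,0.13,5,measured cavity length,0.65,0.06,5
rat_min_fp_pouch,kHz,rat min f_p empty pouch,34,13,7,rat min f_p filled pouch,35,14,6
rat_avg_fp_pouch,kHz,rat mean f_p empty pouch,39,12,7,rat mean f_p filled pouch,38,14,6
rat_max_fp_pouch,kHz,rat max f_p empty pouch,43,11,7,rat max f_p filled pouch,41,15,6
mouse_min_fp_pouch,kHz,mouse min f_p empty pouch,29,9,6,mouse min f_p filled pouch,37,16,6
mouse_avg_fp_pouch,kHz,mouse mean f_p empty pouch,34,8,6,mouse mean f_p filled pouch,43,13,6
mouse_max_fp_pouch,kHz,mouse max f_p empty pouch,42,9,6,mouse max f_p filled pouch,49,11,6
slope_fixation,kHz/(ml/s),freq-flow slope pre-fixation,5.94,3.08,5,freq-flow slope post-fixation,5.30,3.16,5
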