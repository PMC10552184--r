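cell_id,serum_id,specificity,pct_labs,mean_mfi,sd_mfi,cv_pct,consensus_call,consensus_pct,pct_vxm_pos_t,pct_vxm_pos_b,pct_fcxm_pos_t,pct_fcxm_pos_b
AC-153,AC-531,B*14:02,36,918,218,24,none,35,32,28,81,79
AC-153,AC-531,B*18:01,75,1820,524,29,none,71,32,28,81,79
AC-153,AC-532,DRB1*12:01,100,2560,735,29,DR12,99,0,100,3,100
AC-153,AC-532,DRB1*13:04,93,4577,1881,41,DR13,100,0,100,3,100
AC-153,AC-532,DRB3*01:01,46,1135,697,61,DR52,94,0,100,3,100
AC-153,AC-532,DRB3*02:02,82,1390,562,40,DR52,94,0,100,3,100
AC-153,AC-532,DQA1*01:04/DQB1*05:01,82,10939,2104,19,DQ5,99,0,100,3,100
AC-153,AC-534,C*02:02,75,2122,934,44,none,68,17,86,7,100
AC-153,AC-534,DQA1*01:04/DQB1*05:01,86,15164,6603,44,DQ5,100,17,86,7,100
AC-170,AC-540,A2,19,1377,600,44,none,34,NA,NA,42,NA
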