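year,challenge,component,n_labs,n_vxm
2018,VXM-1,combinations,84,840
2018,VXM-2,combinations,63,315
2019,VXM-1,combinations,65,325
2019,VXM-2,combinations,49,245
2020,VXM-1,combinations,54,270
2020,VXM-2,combinations,51,255
2021,VXM-1,combinations,58,174
2021,VXM-2,combinations,44,132
2022,VXM-1,combinations,38,76
2022,VXM-2,combinations,53,50
2022,VXM-1,case_study,38,152
2022,VXM-2,case_study,47,141
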