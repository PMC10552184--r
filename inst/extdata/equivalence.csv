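allele,antigen_split,antigen_broad,bw
A*01:01,A1,A1,
A*02:01,A2,A2,
A*02:02,A2,A2,
A*02:05,A2,A2,
A*03:01,A3,A3,
A*23:01,A23,A9,Bw4
A*24:02,A24,A9,Bw4
B*07:02,B7,B7,Bw6
B*08:01,B8,B8,Bw6
B*14:01,B64,B14,Bw6
B*14:02,B65,B14,Bw6
B*18:01,B18,B18,Bw6
B*27:05,B27,B27,Bw4
B*38:01,B38,B16,Bw4
B*44:02,B44,B12,Bw4
C*02:02,Cw2,Cw2,
C*05:01,Cw5,Cw5,
C*06:02,Cw6,Cw6,
C*07:01,Cw7,Cw7,
C*07:02,Cw7,Cw7,
DRB1*01:01,DR1,DR1,
DRB1*03:01,DR17,DR17,
DRB1*03:02,DR18,DR18,
DRB1*04:01,DR4,DR4,
DRB1*07:01,DR7,DR7,
DRB1*08:01,DR8,DR8,
DRB1*11:01,DR11,DR11,
DRB1*12:01,DR12,DR12,
DRB1*12:02,DR12,DR12,
DRB1*13:01,DR13,DR13,
DRB1*13:02,DR13,DR13,
DRB1*13:03,DR13,DR13,
DRB1*13:04,DR13,DR13,
DRB1*14:01,DR14,DR14,
DRB1*15:01,DR15,DR15,
DRB3*01:01,DR52,DR52,
DRB3*02:02,DR52,DR52,
DRB3*03:01,DR52,DR52,
DRB4*01:01,DR53,DR53,
DRB5*01:01,DR51,DR51,
DQB1*02:01,DQ2,DQ2,
DQB1*03:01,DQ7,DQ7,
DQB1*05:01,DQ5,DQ5,
DQB1*06:02,DQ6,DQ6,
DPB1*04:01,DP4,DP4,
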