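eplet,carrier,status
96HK,DR8,confirmed
96HK,DR11,confirmed
96HK,DR12,confirmed
96HK,DR13,confirmed
96HK,DR14,confirmed
96HK,DR17,confirmed
96HK,DR18,confirmed
11STS,DR11,confirmed
11STS,DR13,confirmed
11STS,DR14,confirmed
11STS,DR17,confirmed
11STS,DR18,confirmed
16Y,DR8,confirmed
16Y,DR12,unverified
16Y,DR14,unverified
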