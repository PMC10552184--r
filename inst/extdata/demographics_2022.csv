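country,ac1,ac2
Argentina,2,2
Australia,4,4
Brazil,4,4
Canada,16,16
Chile,1,1
China,2,1
Colombia,2,2
Costa Rica,NA,1
Guatemala,1,1
Hong Kong SAR China,1,1
Italy,1,1
Mexico,6,6
New Zealand,1,1
Panama,1,1
Peru,1,1
Poland,1,1
Puerto Rico,1,1
Qatar,1,1
Saudi Arabia,1,1
Singapore,1,1
Thailand,1,1
United States,106,107
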