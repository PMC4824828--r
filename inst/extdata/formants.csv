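ipa,F1,F2,F3,B1,B2,B3
i:,310,2790,3310,90,110,170
ɪ,430,2480,3070,90,110,170
eɪ,470,2330,2990,90,110,170
ɛ,610,2330,2990,90,110,170
ɔ,590,920,2710,90,110,170
oʊ,460,1100,2680,90,110,170
u:,370,950,2670,90,110,170
ə,500,1500,2500,90,110,170
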